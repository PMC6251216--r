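#' Synthetic splice-donor-loss gene fixture
#'
#' Builds a fully synthetic gene model engineered to exercise the whole
#' consequence chain on a realistic scale: six exons and five introns, a
#' 440-residue wild-type protein, and a 20-nt -> 6-nt replacement event that
#' straddles the end of exon 2 and the GT donor of intron 2. Applying the
#' event retains intron 2, shifts the reading frame at CDS position 883
#' (codon 295), substitutes five residues and introduces a premature TAA at
#' residue 300, truncating the protein to 299 residues inside the supplied
#' MYB-like domain (residues 271-323).
#'
#' The fixture is generated in code (seeded random filler around the
#' engineered positions); it is a structural stand-in, not any real gene
#' sequence.
#'
#' @param seed Integer seed for the random filler sequence.
#' @return A list: `model` (wild [gene_model()]), `event` (list `start`,
#'   `end`, `replacement`), `domains` (tibble with the MYB-like domain).
#' @examples
#' fx <- splice_loss_fixture()
#' rep <- consequence_report(fx$model, fx$event$start, fx$event$end,
#'                           fx$event$replacement, domains = fx$domains)
#' glance(rep)
#' @export
splice_loss_fixture <- function(seed = 101L) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    stop_codons <- c("TAA", "TAG", "TGA")
    all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    sense_codons <- setdiff(all_codons, stop_codons)
    rand_nt <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    rand_codons <- function(n) paste(sample(sense_codons, n, replace = TRUE), collapse = "")

    codons <- character(441)
    codons[1] <- "ATG"
    codons[2:294] <- strsplit(rand_codons(293), "(?<=.{3})", perl = TRUE)[[1]]
    codons[295] <- "CAG" # last 3 nt of exon 2, first 3 nt of the replaced span
    # residues 296-299 chosen to differ from the frameshift products so the
    # substituted run spans exactly residues 295-299
    codons[296:299] <- c("AAA", "GAT", "GAA", "AAG")
    codons[300:440] <- strsplit(rand_codons(141), "(?<=.{3})", perl = TRUE)[[1]]
    codons[441] <- "TAA"
    cds <- paste(codons, collapse = "")

    utr5 <- rand_nt(100)
    utr3 <- rand_nt(279)
    intron1 <- paste0("GT", rand_nt(144), "AG")
    # intron 2: the 17 intronic nt of the replaced span, then the sequence
    # that enters the mutant reading frame (9 sense nt + the premature TAA)
    intron2 <- paste0("GTAGCTATGTATATGCA", "AATGGTTGTTAA", rand_nt(169), "AG")
    stopifnot(nchar(intron2) == 200)
    intron3 <- paste0("GT", rand_nt(146), "AG")
    intron4 <- paste0("GT", rand_nt(146), "AG")
    intron5 <- paste0("GT", rand_nt(146), "AG")

    seq <- paste0(
      utr5,
      substr(cds, 1, 300),      # exon 1 CDS part   (gene 101-400)
      intron1,                  # gene 401-548
      substr(cds, 301, 885),    # exon 2            (gene 549-1133)
      intron2,                  # gene 1134-1333
      substr(cds, 886, 1085),   # exon 3            (gene 1334-1533)
      intron3,                  # gene 1534-1683
      substr(cds, 1086, 1235),  # exon 4            (gene 1684-1833)
      intron4,                  # gene 1834-1983
      substr(cds, 1236, 1315),  # exon 5            (gene 1984-2063)
      intron5,                  # gene 2064-2213
      substr(cds, 1316, 1323),  # exon 6 CDS tail   (gene 2214-2221)
      utr3
    )
    stopifnot(nchar(seq) == 2500)

    model <- gene_model(
      gene_id = "synthCL1",
      seq = seq,
      exons = tibble(
        start = c(1L, 549L, 1334L, 1684L, 1984L, 2214L),
        end = c(400L, 1133L, 1533L, 1833L, 2063L, 2500L)
      ),
      cds_start = 101L
    )
    list(
      model = model,
      event = list(start = 1131L, end = 1150L, replacement = "TCTTTG"),
      domains = tibble(domain = "MYB-like", start = 271L, end = 323L)
    )
  })
}

#' Synthetic screening-funnel fixture
#'
#' Builds interval-scale inputs whose screening cardinalities match the
#' canonical funnel this package is designed around: 90 interval variants on
#' scaffold C29 of which 84 have at least one germplasm-panel carrier (6
#' panel-retained), 42 are (near-)fixed in the recessive BSA pool, the panel
#' survivors are a subset of the pool survivors (intersection of 6), and 5
#' of the 6 final candidates fall in or near one gene while the sixth is
#' intergenic. All genotypes, read counts and p-values are synthetic.
#'
#' @param seed Integer seed.
#' @param n_accessions Panel size (default 822).
#' @return A list: `scan` (tibble `variant_id`, `chrom`, `pos`, `p_value`),
#'   `panel`, `pool`, `annotation` (a [gene_annotation()]), and the expected
#'   outcomes `candidate_ids` (the 6), `hosted_ids` (the 5 in the gene) and
#'   `gene_id`.
#' @export
screening_funnel_fixture <- function(seed = 202L, n_accessions = 822L) {
  withr::with_seed(seed, {
    six <- c(6674693L, 6717525L, 6721553L, 6721558L, 6721563L, 6721565L)
    peak_pos <- 6721563L
    lo <- 6522236L
    hi <- 6918901L
    other <- sample(setdiff(seq(lo + 1L, hi - 1L), six), 82L)
    pos <- sort(unique(c(six, lo, hi, other)))
    stopifnot(length(pos) == 90L)
    ids <- marker_id("C29", pos)
    peak_id <- marker_id("C29", peak_pos)

    p <- 10^(-stats::runif(length(pos), 19, 90))
    p[ids == peak_id] <- 1e-94
    scan <- tibble(variant_id = ids, chrom = "C29", pos = pos, p_value = p)

    # panel: the six candidates carrier-free, every other variant carried by
    # at least one accession
    six_ids <- marker_id("C29", six)
    carrier <- matrix(rbinom(length(pos) * n_accessions, 1L, 0.3), nrow = length(pos))
    carrier[, 1L] <- 1L # guarantee >= 1 carrier per non-candidate variant
    g <- carrier * (1L + matrix(rbinom(length(pos) * n_accessions, 1L, 0.5),
                                nrow = length(pos)))
    g[ids %in% six_ids, ] <- 0L
    panel <- bind_cols(
      tibble(variant_id = ids),
      as_tibble(matrix(g, nrow = length(pos),
                       dimnames = list(NULL, sprintf("M%03d", seq_len(n_accessions)))))
    )

    # pool: the 42 variants nearest the peak (always including the six) are
    # fixed for the mutant allele; the rest float around 0.5
    dist_rank <- rank(abs(pos - peak_pos), ties.method = "first")
    fixed_ids <- ids[order(!(ids %in% six_ids), dist_rank)][1:42]
    fixed <- ids %in% fixed_ids
    depth <- rpois(length(pos), 30) + 10L
    alt <- ifelse(fixed, depth, pmin(rbinom(length(pos), depth, 0.5),
                                     as.integer(floor(depth * 0.8))))
    pool <- tibble(
      variant_id = ids, chrom = "C29", pos = pos,
      ref_count = depth - alt, alt_count = alt
    )

    genes <- tibble(
      gene_id = c("C29.450", "C29.460"),
      chrom = "C29",
      strand = c("+", "+"),
      start = c(6550000L, 6719000L),
      end = c(6555000L, 6726000L)
    )
    exons <- tibble(
      gene_id = c("C29.450", "C29.450", "C29.460", "C29.460", "C29.460"),
      start = c(6550000L, 6553000L, 6719000L, 6721560L, 6723000L),
      end = c(6551500L, 6555000L, 6721554L, 6721600L, 6726000L)
    )

    list(
      scan = scan,
      panel = panel,
      pool = pool,
      annotation = gene_annotation(genes, exons),
      candidate_ids = six_ids,
      hosted_ids = marker_id("C29", setdiff(six, 6674693L)),
      gene_id = "C29.460"
    )
  })
}
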