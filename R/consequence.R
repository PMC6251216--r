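#' Gene model on its coding strand
#'
#' A gene model is the substrate of consequence prediction: the gene's
#' genomic sequence written 5'->3' on the coding strand, its ordered exon
#' intervals in gene-relative 1-based coordinates, and the gene-relative
#' position of the CDS start (the A of the ATG, which must fall inside an
#' exon). Introns are the gaps between consecutive exons and are expected to
#' carry the canonical GT donor and AG acceptor dinucleotides unless
#' `check_splice = FALSE`.
#'
#' @param gene_id Gene identifier.
#' @param seq Gene sequence (single character string over A/C/G/T).
#' @param exons Tibble or data frame with `start` and `end` (gene-relative,
#'   1-based inclusive), ordered 5'->3', non-overlapping.
#' @param cds_start Gene-relative position of the CDS start codon.
#' @param strand `"+"` or `"-"` (genomic orientation bookkeeping only; the
#'   model itself always reads 5'->3').
#' @param chrom Optional chromosome/scaffold name.
#' @param check_splice Verify GT/AG at every intron (default `TRUE`).
#' @return An object of class `gene_model`.
#' @examples
#' toy <- gene_model(
#'   "toy", paste0("ATGAAA", "GTCCAG", "TTTTAA"),
#'   exons = tibble::tibble(start = c(1, 13), end = c(6, 18)),
#'   cds_start = 1
#' )
#' mature_transcript(toy)
#' @export
gene_model <- function(gene_id, seq, exons, cds_start, strand = "+",
                       chrom = NA_character_, check_splice = TRUE) {
  seq <- toupper(seq)
  if (length(seq) != 1 || !grepl("^[ACGT]+$", seq)) {
    abort("`seq` must be a single A/C/G/T string.")
  }
  exons <- as_tibble(exons)[, c("start", "end")]
  n <- nrow(exons)
  if (n < 1) abort("At least one exon is required.")
  if (any(exons$start > exons$end)) abort("Exon start must not exceed end.")
  if (exons$start[1] < 1 || exons$end[n] > nchar(seq)) {
    abort("Exons must lie within the gene sequence.")
  }
  if (n > 1 && any(exons$start[-1] <= exons$end[-n])) {
    abort("Exons must be ordered 5'->3' and non-overlapping.")
  }
  model <- structure(
    list(
      gene_id = gene_id, seq = seq,
      exons = mutate(exons, start = as.integer(.data$start), end = as.integer(.data$end)),
      cds_start = as.integer(cds_start),
      strand = strand, chrom = chrom
    ),
    class = "gene_model"
  )
  if (!any(cds_start >= exons$start & cds_start <= exons$end)) {
    abort("`cds_start` must fall inside an exon.")
  }
  if (check_splice) {
    intr <- gene_introns(model)
    if (nrow(intr) > 0) {
      donors <- substr_vec(seq, intr$start, intr$start + 1L)
      acceptors <- substr_vec(seq, intr$end - 1L, intr$end)
      bad <- donors != "GT" | acceptors != "AG"
      if (any(bad)) {
        abort(sprintf(
          "Non-canonical splice motifs at intron(s) %s (use check_splice = FALSE to allow).",
          paste(which(bad), collapse = ", ")
        ))
      }
    }
  }
  model
}

substr_vec <- function(x, start, end) {
  vapply(seq_along(start), function(i) substr(x, start[i], end[i]), character(1))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s: %d bp, %d exons / %d introns, CDS start at %d\n",
    x$gene_id, nchar(x$seq), nrow(x$exons), max(nrow(x$exons) - 1L, 0L), x$cds_start
  ))
  invisible(x)
}

#' Introns of a gene model
#'
#' @param model A [gene_model()].
#' @return Tibble `intron`, `start`, `end` (gene-relative); `n` exons yield
#'   `n - 1` introns.
#' @export
gene_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2) return(tibble(intron = integer(), start = integer(), end = integer()))
  tibble(
    intron = seq_len(n - 1L),
    start = ex$end[-n] + 1L,
    end = ex$start[-1] - 1L
  )
}

#' Mature transcript of a gene model
#'
#' Concatenates the exon sequences 5'->3'.
#'
#' @param model A [gene_model()].
#' @return A character string.
#' @export
mature_transcript <- function(model) {
  paste(substr_vec(model$seq, model$exons$start, model$exons$end), collapse = "")
}

# transcript coordinate of an exonic gene position
gene_to_tx <- function(model, gpos) {
  ex <- model$exons
  hit <- which(gpos >= ex$start & gpos <= ex$end)
  if (length(hit) != 1) abort("Position is not exonic; no transcript coordinate.")
  before <- if (hit > 1) sum(ex$end[seq_len(hit - 1)] - ex$start[seq_len(hit - 1)] + 1L) else 0L
  before + (gpos - ex$start[hit] + 1L)
}

#' Apply a replacement event to a gene model
#'
#' Replaces the gene-relative span `start..end` with `replacement` (possibly
#' empty, i.e. a pure deletion) and recomputes the exon/intron structure. An
#' intron whose GT donor dinucleotide is deleted or disrupted by the event
#' can no longer be spliced at its 5' end; under the default
#' `splice_policy = "retain"` that intron is retained into the mature
#' transcript up to the unchanged acceptor's exon boundary (the affected
#' exons and the intron merge into one exonic block). Under `"cryptic-gt"`
#' splicing instead resumes at the first GT found at or downstream of the
#' lost donor position (falling back to retention, with a warning, when none
#' exists before the acceptor). Introns whose donors are untouched are
#' spliced normally.
#'
#' Unsupported events raise an error: a span swallowing an entire intron, a
#' span disrupting an acceptor whose donor is intact, and events overlapping
#' the CDS start.
#'
#' @param model A [gene_model()].
#' @param start,end Gene-relative 1-based span to replace.
#' @param replacement Replacement sequence (A/C/G/T, may be `""`).
#' @param splice_policy `"retain"` (default) or `"cryptic-gt"`.
#' @return The mutant [gene_model()], with attributes `retained_introns`
#'   (indices in the wild model) and `splice_policy`.
#' @examples
#' # deletion removing the donor of intron 1 retains that intron
#' wt <- gene_model("toy", paste0("ATGCCC", "GTAAAG", "AAATAA"),
#'                  exons = tibble::tibble(start = c(1, 13), end = c(6, 18)),
#'                  cds_start = 1)
#' mut <- apply_gene_variant(wt, 5, 8, "")
#' mature_transcript(mut)
#' @export
apply_gene_variant <- function(model, start, end, replacement = "",
                               splice_policy = c("retain", "cryptic-gt")) {
  splice_policy <- match.arg(splice_policy)
  if (!inherits(model, "gene_model")) abort("`model` must be a gene_model.")
  len <- nchar(model$seq)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end > len || start > end) {
    abort(sprintf("Event span %d-%d must lie within the gene (1-%d).", start, end, len))
  }
  replacement <- toupper(replacement)
  if (nchar(replacement) > 0 && !grepl("^[ACGT]+$", replacement)) {
    abort("`replacement` must contain only A/C/G/T (no gap characters).")
  }

  delta <- nchar(replacement) - (end - start + 1L)
  mut_seq <- paste0(
    substr(model$seq, 1L, start - 1L), replacement,
    substr(model$seq, end + 1L, len)
  )

  # identity event: nothing removed, nothing inserted
  if (end - start + 1L == nchar(replacement) &&
      replacement == substr(model$seq, start, end)) {
    out <- model
    attr(out, "retained_introns") <- integer()
    attr(out, "splice_policy") <- splice_policy
    return(out)
  }

  intr <- gene_introns(model)
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2
  if (nrow(intr) > 0 && any(start <= intr$start & end >= intr$end)) {
    abort("Event deletes an entire intron; this rearrangement is not supported.")
  }
  donor_hit <- if (nrow(intr) > 0) {
    overlaps(start, end, intr$start, intr$start + 1L)
  } else logical()
  acceptor_hit <- if (nrow(intr) > 0) {
    overlaps(start, end, intr$end - 1L, intr$end)
  } else logical()
  if (any(acceptor_hit & !donor_hit)) {
    abort("Event disrupts a splice acceptor with an intact donor; not supported.")
  }

  mpos_s <- function(p) ifelse(p < start, p, ifelse(p > end, p + delta, start))
  mpos_e <- function(p) {
    ifelse(p < start, p, ifelse(p > end, p + delta, start + nchar(replacement) - 1L))
  }

  # donors untouched by the span can still be disrupted by an adjacent
  # replacement: verify GT survives at the mapped donor position
  destroyed <- donor_hit
  if (nrow(intr) > 0) {
    for (i in which(!donor_hit)) {
      ds <- mpos_s(intr$start[i])
      if (substr(mut_seq, ds, ds + 1L) != "GT") destroyed[i] <- TRUE
    }
  }

  # cryptic-donor rescue: splice from the first GT at/after the lost donor
  donor_override <- rep(NA_integer_, max(nrow(intr), 0L))
  if (splice_policy == "cryptic-gt" && any(destroyed)) {
    for (i in which(destroyed)) {
      from <- mpos_s(intr$start[i])
      to <- mpos_e(intr$end[i]) - 2L # leave room for the acceptor AG
      window <- substr(mut_seq, from, to)
      hit <- regexpr("GT", window, fixed = TRUE)
      if (hit > 0) {
        donor_override[i] <- from + as.integer(hit) - 1L
        destroyed[i] <- FALSE
      } else {
        warn(sprintf("No cryptic GT donor for intron %d; retaining the intron.", i))
      }
    }
  }

  ex <- model$exons
  n_ex <- nrow(ex)
  starts <- integer(); ends <- integer()
  cur_s <- mpos_s(ex$start[1])
  for (k in seq_len(n_ex)) {
    if (k < n_ex && destroyed[k]) next # extend block through retained intron k
    e_end <- if (k < n_ex && !is.na(donor_override[k])) {
      donor_override[k] - 1L # cryptic donor: exon k now ends just before it
    } else {
      mpos_e(ex$end[k])
    }
    starts <- c(starts, cur_s)
    ends <- c(ends, e_end)
    if (k < n_ex) cur_s <- mpos_s(ex$start[k + 1L])
  }

  new_cds <- mpos_s(model$cds_start)
  if (model$cds_start >= start && model$cds_start <= end) {
    abort("Event overlaps the CDS start; consequence is undefined here.")
  }

  out <- gene_model(
    gene_id = model$gene_id, seq = mut_seq,
    exons = tibble(start = starts, end = ends),
    cds_start = new_cds, strand = model$strand, chrom = model$chrom,
    check_splice = FALSE
  )
  attr(out, "retained_introns") <- which(destroyed)
  attr(out, "splice_policy") <- splice_policy
  out
}

#' Translate an open reading frame
#'
#' Standard-genetic-code translation of a transcript from its CDS start to
#' the first in-frame stop codon. Reports the stop codon identity and the
#' residue index it occupies (protein length + 1). Transcripts with no
#' in-frame stop before their end are flagged `non_stop`.
#'
#' @param transcript Character transcript sequence over A/C/G/T.
#' @param cds_start 1-based position of the ATG within the transcript.
#' @return A list of class `orf_translation`: `protein` (character, no stop
#'   symbol), `n_aa`, `stop_codon` (`NA` when non-stop), `stop_residue`,
#'   `orf_nt` (`3 * (n_aa + 1)`, `NA` when non-stop), `non_stop`.
#' @examples
#' translate_orf("ATGAAATAA", 1) # protein "MK", stop TAA at residue 3
#' @export
translate_orf <- function(transcript, cds_start = 1) {
  transcript <- toupper(transcript)
  if (!grepl("^[ACGT]+$", transcript)) abort("`transcript` must be over A/C/G/T.")
  cds_start <- as.integer(cds_start)
  if (cds_start < 1 || cds_start + 2L > nchar(transcript)) {
    abort("`cds_start` must leave at least one codon in the transcript.")
  }
  if (substr(transcript, cds_start, cds_start + 2L) != "ATG") {
    abort(sprintf("No ATG at cds_start (found %s).",
                  substr(transcript, cds_start, cds_start + 2L)))
  }
  cds <- substr(transcript, cds_start, nchar(transcript))
  n_codons <- nchar(cds) %/% 3L
  cds <- substr(cds, 1L, n_codons * 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    n_aa <- as.integer(stop_at) - 1L
    structure(
      list(
        protein = substr(aa, 1L, n_aa),
        n_aa = n_aa,
        stop_codon = substr(cds, n_aa * 3L + 1L, n_aa * 3L + 3L),
        stop_residue = n_aa + 1L,
        orf_nt = 3L * (n_aa + 1L),
        non_stop = FALSE
      ),
      class = "orf_translation"
    )
  } else {
    structure(
      list(
        protein = aa, n_aa = nchar(aa),
        stop_codon = NA_character_, stop_residue = NA_integer_,
        orf_nt = NA_integer_, non_stop = TRUE
      ),
      class = "orf_translation"
    )
  }
}

#' @export
print.orf_translation <- function(x, ...) {
  cat(sprintf(
    "<orf_translation> %d aa%s\n", x$n_aa,
    if (x$non_stop) " (non-stop)" else sprintf(", stop %s at residue %d (ORF %d nt)",
                                               x$stop_codon, x$stop_residue, x$orf_nt)
  ))
  invisible(x)
}

#' Compare a wild-type and a mutant protein
#'
#' Locates the first differing residue, the contiguous run of substituted
#' residues from there, and classifies the length change as
#' `"synonymous-length"`, `"truncating"` or `"elongating"`. When the two
#' proteins share their whole common prefix but differ in length, the first
#' difference is the first missing/extra residue (common length + 1) and the
#' substituted run is empty.
#'
#' @param wild,mutant Protein sequences (characters, no stop symbol).
#' @return A list of class `protein_diff`: `identical`, `first_diff`,
#'   `run_length`, `from_run`, `to_run`, `wild_length`, `mutant_length`,
#'   `classification`.
#' @examples
#' diff_proteins("MKLV", "MKCV")
#' @export
diff_proteins <- function(wild, mutant) {
  if (nchar(wild) == 0 || nchar(mutant) == 0) {
    abort("Both proteins must be non-empty.")
  }
  nw <- nchar(wild); nm <- nchar(mutant)
  L <- min(nw, nm)
  w <- strsplit(wild, "")[[1]]
  m <- strsplit(mutant, "")[[1]]
  differ <- which(w[seq_len(L)] != m[seq_len(L)])
  classification <- if (nm < nw) "truncating" else if (nm > nw) "elongating" else "synonymous-length"
  if (length(differ) == 0 && nw == nm) {
    out <- list(
      identical = TRUE, first_diff = NA_integer_, run_length = 0L,
      from_run = "", to_run = "", wild_length = nw, mutant_length = nm,
      classification = classification
    )
    return(structure(out, class = "protein_diff"))
  }
  if (length(differ) == 0) {
    first_diff <- L + 1L
    run_length <- 0L
    from_run <- ""; to_run <- ""
  } else {
    first_diff <- differ[1]
    run_end <- first_diff
    while (run_end < L && w[run_end + 1L] != m[run_end + 1L]) run_end <- run_end + 1L
    run_length <- run_end - first_diff + 1L
    from_run <- paste(w[first_diff:run_end], collapse = "")
    to_run <- paste(m[first_diff:run_end], collapse = "")
  }
  structure(
    list(
      identical = FALSE, first_diff = first_diff, run_length = run_length,
      from_run = from_run, to_run = to_run,
      wild_length = nw, mutant_length = nm, classification = classification
    ),
    class = "protein_diff"
  )
}

#' @export
print.protein_diff <- function(x, ...) {
  if (x$identical) {
    cat(sprintf("<protein_diff> identical (%d aa)\n", x$wild_length))
  } else {
    cat(sprintf(
      "<protein_diff> %s: %d aa -> %d aa, first diff at residue %s (%s -> %s)\n",
      x$classification, x$wild_length, x$mutant_length,
      x$first_diff, x$from_run, x$to_run
    ))
  }
  invisible(x)
}

#' Overlap of protein domains with a mutation
#'
#' Classifies each domain (in wild-protein coordinates) against a
#' [diff_proteins()] result: `"lost"` when the domain lies entirely beyond
#' the mutant protein's end, `"disrupted"` when the first altered residue or
#' the premature stop falls inside the domain span, `"intact"` otherwise.
#'
#' @param domains Tibble with `domain`, `start`, `end` (residue coordinates
#'   in the wild protein).
#' @param diff A `protein_diff` (or a `consequence_report`, whose diff is
#'   used).
#' @return `domains` with a `status` column appended.
#' @export
domain_overlap <- function(domains, diff) {
  if (inherits(diff, "consequence_report")) diff <- diff$diff
  if (!inherits(diff, "protein_diff")) abort("`diff` must be a protein_diff.")
  if (!all(c("domain", "start", "end") %in% names(domains))) {
    abort("`domains` must have domain, start and end columns.")
  }
  stop_residue <- diff$mutant_length + 1L
  first_diff <- diff$first_diff
  domains |>
    mutate(status = dplyr::case_when(
      .data$start > diff$mutant_length ~ "lost",
      !is.na(first_diff) & first_diff >= .data$start & first_diff <= .data$end ~ "disrupted",
      !diff$identical & diff$classification == "truncating" &
        stop_residue >= .data$start & stop_residue <= .data$end ~ "disrupted",
      TRUE ~ "intact"
    ))
}

#' Enumerate isoforms of an alternative splice site
#'
#' Models an alternative donor/acceptor a few nucleotides away from the
#' canonical one: emits the canonical isoform and the isoform spliced at the
#' shifted site. A shift that is a multiple of 3 inside the CDS changes the
#' protein by whole residues (a 3-nt acceptor shift deletes exactly one);
#' any other shift changes the reading frame downstream and is flagged.
#'
#' @param model A [gene_model()].
#' @param intron_index Which intron's splice site moves.
#' @param shift Signed shift in nt of the splice junction (`0` = no
#'   alternative site, a single isoform). For `site = "acceptor"` a positive
#'   shift extends the intron into the downstream exon; for `site = "donor"`
#'   a positive shift extends the upstream exon into the intron.
#' @param site `"acceptor"` or `"donor"`.
#' @return A tibble with one row per isoform: `isoform`, `shift`,
#'   `transcript`, `protein`, `protein_length`, `frameshift`.
#' @export
alternative_splice_isoforms <- function(model, intron_index, shift,
                                        site = c("acceptor", "donor")) {
  site <- match.arg(site)
  if (!inherits(model, "gene_model")) abort("`model` must be a gene_model.")
  intr <- gene_introns(model)
  if (intron_index < 1 || intron_index > nrow(intr)) {
    abort("`intron_index` does not name an intron of this model.")
  }
  isoform_row <- function(name, m, fs) {
    tx <- mature_transcript(m)
    tr <- translate_orf(tx, gene_to_tx(m, m$cds_start))
    tibble(
      isoform = name, shift = shift, transcript = tx,
      protein = tr$protein, protein_length = tr$n_aa, frameshift = fs
    )
  }
  rows <- isoform_row("canonical", model, FALSE)
  if (shift != 0) {
    ex <- model$exons
    if (site == "acceptor") {
      ex$start[intron_index + 1L] <- ex$start[intron_index + 1L] + as.integer(shift)
    } else {
      ex$end[intron_index] <- ex$end[intron_index] + as.integer(shift)
    }
    if (any(ex$start > ex$end)) abort("Shift collapses an exon; not a valid isoform.")
    alt <- gene_model(model$gene_id, model$seq, ex, model$cds_start,
                      strand = model$strand, chrom = model$chrom,
                      check_splice = FALSE)
    rows <- bind_rows(rows, isoform_row("shifted", alt, abs(shift) %% 3L != 0L))
  }
  rows
}

#' Full molecular-consequence report for a gene variant
#'
#' Runs the whole consequence chain: applies the event to the wild gene
#' model ([apply_gene_variant()]), assembles both mature transcripts,
#' translates both ORFs, diffs the proteins and scores domain overlap. The
#' frameshift cDNA position is the first CDS nucleotide at which the mutant
#' coding sequence diverges from the wild one (counted from the A of the
#' ATG).
#'
#' @param model Wild-type [gene_model()].
#' @param start,end,replacement The event, as in [apply_gene_variant()].
#' @param domains Optional domain tibble (`domain`, `start`, `end`) in
#'   wild-protein residue coordinates.
#' @param splice_policy Passed to [apply_gene_variant()].
#' @return An object of class `consequence_report`: a list with the mutant
#'   `model`, both `orf_translation`s (`wild_orf`, `mutant_orf`), the `diff`,
#'   `frameshift_cdna_pos`, `domains` (with status) and headline scalars
#'   (`mutant_gene_length`, `mutant_orf_nt`, `mutant_protein_length`,
#'   `stop_codon`, `stop_residue`, `classification`). Use [glance()] for a
#'   one-row summary.
#' @export
consequence_report <- function(model, start, end, replacement = "",
                               domains = NULL,
                               splice_policy = c("retain", "cryptic-gt")) {
  splice_policy <- match.arg(splice_policy)
  mutant <- apply_gene_variant(model, start, end, replacement,
                               splice_policy = splice_policy)
  wild_tx <- mature_transcript(model)
  mut_tx <- mature_transcript(mutant)
  wild_orf <- translate_orf(wild_tx, gene_to_tx(model, model$cds_start))
  mut_orf <- translate_orf(mut_tx, gene_to_tx(mutant, mutant$cds_start))
  diff <- diff_proteins(wild_orf$protein, mut_orf$protein)

  wild_cds <- substr(wild_tx, gene_to_tx(model, model$cds_start), nchar(wild_tx))
  mut_cds <- substr(mut_tx, gene_to_tx(mutant, mutant$cds_start), nchar(mut_tx))
  frameshift_cdna_pos <- first_string_diff(wild_cds, mut_cds)

  dom <- if (!is.null(domains)) domain_overlap(domains, diff) else NULL
  structure(
    list(
      model = mutant,
      wild_orf = wild_orf,
      mutant_orf = mut_orf,
      diff = diff,
      frameshift_cdna_pos = frameshift_cdna_pos,
      domains = dom,
      mutant_gene_length = nchar(mutant$seq),
      mutant_orf_nt = mut_orf$orf_nt,
      mutant_protein_length = mut_orf$n_aa,
      stop_codon = mut_orf$stop_codon,
      stop_residue = mut_orf$stop_residue,
      classification = diff$classification,
      retained_introns = attr(mutant, "retained_introns")
    ),
    class = "consequence_report"
  )
}

first_string_diff <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  if (L == 0) return(if (nchar(a) == nchar(b)) NA_integer_ else 1L)
  av <- utf8ToInt(substr(a, 1, L))
  bv <- utf8ToInt(substr(b, 1, L))
  d <- which(av != bv)
  if (length(d) > 0) d[1] else if (nchar(a) != nchar(b)) L + 1L else NA_integer_
}

#' @export
print.consequence_report <- function(x, ...) {
  cat(sprintf(
    "<consequence_report> %s: %s\n", x$model$gene_id, x$classification
  ))
  cat(sprintf(
    "  mutant gene %d bp; ORF %s nt -> %d aa (wild %d aa)\n",
    x$mutant_gene_length,
    ifelse(is.na(x$mutant_orf_nt), "non-stop", x$mutant_orf_nt),
    x$mutant_protein_length, x$diff$wild_length
  ))
  if (!is.na(x$frameshift_cdna_pos)) {
    cat(sprintf(
      "  first cDNA divergence at %d; first altered residue %s (%s -> %s); stop %s at residue %s\n",
      x$frameshift_cdna_pos, x$diff$first_diff, x$diff$from_run, x$diff$to_run,
      x$stop_codon, x$stop_residue
    ))
  }
  if (length(x$retained_introns) > 0) {
    cat(sprintf("  retained intron(s): %s\n", paste(x$retained_introns, collapse = ", ")))
  }
  if (!is.null(x$domains)) {
    for (i in seq_len(nrow(x$domains))) {
      d <- x$domains[i, ]
      cat(sprintf("  domain %s (%d-%d): %s\n", d$domain, d$start, d$end, d$status))
    }
  }
  invisible(x)
}

#' @export
tidy.consequence_report <- function(x, ...) {
  if (is.null(x$domains)) tibble(domain = character(), start = integer(),
                                 end = integer(), status = character())
  else x$domains
}

#' @export
glance.consequence_report <- function(x, ...) {
  tibble(
    gene_id = x$model$gene_id,
    classification = x$classification,
    mutant_gene_length = x$mutant_gene_length,
    mutant_orf_nt = x$mutant_orf_nt,
    mutant_protein_length = x$mutant_protein_length,
    wild_protein_length = x$diff$wild_length,
    frameshift_cdna_pos = x$frameshift_cdna_pos,
    first_altered_residue = x$diff$first_diff,
    stop_codon = x$stop_codon,
    stop_residue = x$stop_residue,
    n_retained_introns = length(x$retained_introns)
  )
}
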