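# Independent oracles and small builders shared across the suite.

# Pearson goodness-of-fit, written independently of the package
oracle_gof_chi2 <- function(counts, ratio) {
  expected <- sum(counts) * ratio / sum(ratio)
  sum((counts - expected)^2 / expected)
}

# brute-force standard-code translation with an explicit codon table
oracle_translate <- function(cds) {
  tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  n <- nchar(cds) %/% 3
  aa <- character(0)
  for (i in seq_len(n)) {
    codon <- substr(cds, 3 * i - 2, 3 * i)
    a <- tab[[codon]]
    if (a == "*") return(list(protein = paste(aa, collapse = ""), stop_codon = codon))
    aa <- c(aa, a)
  }
  list(protein = paste(aa, collapse = ""), stop_codon = NA_character_)
}

# wide genotype tibble from explicit per-sample genotype vectors
make_geno_tbl <- function(geno_by_variant, chrom = "C1", pos = NULL) {
  nv <- length(geno_by_variant)
  n <- length(geno_by_variant[[1]])
  if (is.null(pos)) pos <- seq_len(nv) * 1000L
  ids <- sprintf("S%03d", seq_len(n))
  g <- do.call(rbind, geno_by_variant)
  colnames(g) <- ids
  dplyr::bind_cols(
    tibble::tibble(
      variant_id = mendelscan::marker_id(chrom, pos),
      chrom = chrom, pos = as.integer(pos),
      ref = "A", alt = "T", type = "SNP"
    ),
    tibble::as_tibble(g)
  )
}

# genotype vector realising given class counts (n0 hom-ref, n1 het, n2 hom-alt)
geno_from_classes <- function(n0, n1, n2) {
  rep(c(0L, 1L, 2L), times = c(n0, n1, n2))
}

make_pheno_tbl <- function(y) {
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_along(y)),
    phenotype = ifelse(y == 1, "cl", "CL")
  )
}

# quick toy gene: 3 exons / 2 introns, CDS from the start of exon 1
toy_gene <- function() {
  # exon1 1-9 ATGGCCGCA | intron1 10-17 GTTTTTAG | exon2 18-26 TCATCAGCA |
  # intron2 27-34 GTCCCCAG | exon3 35-46 AAGGGATCCTAA
  gene_model(
    "toy3",
    paste0("ATGGCCGCA", "GTTTTTAG", "TCATCAGCA", "GTCCCCAG", "AAGGGATCCTAA"),
    exons = tibble::tibble(start = c(1L, 18L, 35L), end = c(9L, 26L, 46L)),
    cds_start = 1L
  )
}
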