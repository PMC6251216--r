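#' Write and read multi-sample genotype VCFs
#'
#' `write_vcf()` emits a minimal VCF v4.2 with GT fields (0/0, 0/1, 1/1,
#' ./.) for a genotype table, optionally prepending parental columns.
#' `read_vcf()` parses such a file (via vcfR) back into the package's wide
#' genotype-table format; the round trip is lossless for the fields the
#' pipeline uses.
#'
#' @param genotypes Genotype table (meta columns + one 0/1/2/`NA` column per
#'   sample).
#' @param file Path to write/read.
#' @param parents Optional tibble of extra sample columns keyed by
#'   `variant_id` (e.g. the `parents` element of an `f2_population`).
#' @return `write_vcf()`: the path, invisibly. `read_vcf()`: a genotype
#'   tibble.
#' @export
write_vcf <- function(genotypes, file, parents = NULL) {
  assert_genotype_tbl(genotypes)
  gt_tbl <- genotypes
  if (!is.null(parents)) {
    extra <- parents[match(genotypes$variant_id, parents$variant_id),
                     setdiff(names(parents), c("variant_id", "chrom", "pos")),
                     drop = FALSE]
    gt_tbl <- bind_cols(genotypes[, intersect(GENO_META, names(genotypes))],
                        extra,
                        genotypes[, geno_sample_ids(genotypes), drop = FALSE])
  }
  samples <- geno_sample_ids(gt_tbl)
  g <- geno_matrix(gt_tbl)
  code <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  code[g == 0L] <- "0/0"
  code[g == 1L] <- "0/1"
  code[g == 2L] <- "1/1"
  ref <- gt_tbl$ref %||% rep("A", nrow(gt_tbl))
  alt <- gt_tbl$alt %||% rep("T", nrow(gt_tbl))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mendelscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    gt_tbl$chrom, gt_tbl$pos, gt_tbl$variant_id, ref, alt, ".", "PASS", ".",
    "GT", apply(code, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), file)
  invisible(file)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  num <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  num[gt %in% c("0/0", "0|0")] <- 0L
  num[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  num[gt %in% c("1/1", "1|1")] <- 2L
  fx <- vcfR::getFIX(v)
  ref <- fx[, "REF"]
  alt <- fx[, "ALT"]
  meta <- tibble(
    variant_id = fx[, "ID"],
    chrom = fx[, "CHROM"],
    pos = as.integer(fx[, "POS"]),
    ref = ref,
    alt = alt,
    type = ifelse(nchar(ref) == nchar(alt), "SNP", "InDel")
  )
  bind_cols(meta, as_tibble(num))
}

#' Write and read pooled allele-depth VCFs
#'
#' The BSA pool is represented as a single-sample VCF whose AD field carries
#' the (ref, alt) read counts per variant.
#'
#' @param pool Tibble `variant_id`, `chrom`, `pos`, `ref_count`, `alt_count`.
#' @param file Path.
#' @param sample_name Name of the pool sample column.
#' @return `write_pool_vcf()`: the path, invisibly. `read_pool_vcf()`: a
#'   pool-counts tibble.
#' @export
write_pool_vcf <- function(pool, file, sample_name = "BSA_pool") {
  need <- c("variant_id", "chrom", "pos", "ref_count", "alt_count")
  if (!all(need %in% names(pool))) {
    abort(paste0("`pool` must have columns: ", paste(need, collapse = ", "), "."))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mendelscan",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  ad <- ifelse(
    is.na(pool$ref_count) | is.na(pool$alt_count), ".,.",
    paste0(pool$ref_count, ",", pool$alt_count)
  )
  dp <- ifelse(is.na(pool$ref_count) | is.na(pool$alt_count), ".",
               as.character(pool$ref_count + pool$alt_count))
  body <- paste(
    pool$chrom, pool$pos, pool$variant_id, "N", "A", ".", "PASS", ".",
    "AD:DP", paste0(ad, ":", dp),
    sep = "\t"
  )
  readr::write_lines(c(header, body), file)
  invisible(file)
}

#' @rdname write_pool_vcf
#' @export
read_pool_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  parts <- stringr::str_split_fixed(ad, ",", 2)
  fx <- vcfR::getFIX(v)
  tibble(
    variant_id = fx[, "ID"],
    chrom = fx[, "CHROM"],
    pos = as.integer(fx[, "POS"]),
    ref_count = suppressWarnings(as.integer(parts[, 1])),
    alt_count = suppressWarnings(as.integer(parts[, 2]))
  )
}

#' Write and read phenotype tables
#'
#' Tab-separated table of `sample_id` and `phenotype` (`"CL"` normal /
#' `"cl"` recessive).
#'
#' @param phenotypes Tibble `sample_id`, `phenotype`.
#' @param file Path.
#' @return `read_phenotypes()`: the phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, file) {
  readr::write_tsv(phenotypes[, c("sample_id", "phenotype")], file)
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  ph <- readr::read_tsv(file, col_types = readr::cols(
    sample_id = readr::col_character(), phenotype = readr::col_character()
  ))
  bad <- !ph$phenotype %in% c("CL", "cl")
  if (any(bad)) {
    abort(sprintf(
      "Invalid phenotype value(s) for sample(s) %s (expected \"CL\" or \"cl\").",
      paste(head(ph$sample_id[bad], 5), collapse = ", ")
    ))
  }
  ph
}

#' Check that phenotype samples match genotype samples
#'
#' @param genotypes Genotype table.
#' @param phenotypes Phenotype tibble.
#' @return Invisibly `TRUE`; errors naming the offending samples otherwise.
#' @export
validate_samples <- function(genotypes, phenotypes) {
  samples <- geno_sample_ids(genotypes)
  extra <- setdiff(phenotypes$sample_id, samples)
  missing <- setdiff(samples, phenotypes$sample_id)
  if (length(extra) > 0) {
    abort(sprintf("Phenotyped sample(s) absent from the VCF: %s.",
                  paste(head(extra, 5), collapse = ", ")))
  }
  if (length(missing) > 0) {
    abort(sprintf("VCF sample(s) missing a phenotype: %s.",
                  paste(head(missing, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write and read gene annotations as GFF3
#'
#' `write_gff3()` emits gene and exon features; `read_gff3()` imports a GFF3
#' (via rtracklayer) and rebuilds the [gene_annotation()] from its gene and
#' exon records (exons are linked to genes by their `Parent` attribute).
#'
#' @param annotation A [gene_annotation()].
#' @param file Path.
#' @return `read_gff3()`: a `gene_annotation`.
#' @export
write_gff3 <- function(annotation, file) {
  if (!inherits(annotation, "gene_annotation")) {
    abort("`annotation` must be a gene_annotation.")
  }
  genes <- annotation$genes
  exons <- annotation$exons[, c("gene_id", "start", "end")] |>
    left_join(select(genes, "gene_id", "chrom", "strand"), by = "gene_id")
  lines <- c(
    "##gff-version 3",
    paste(genes$chrom, "mendelscan", "gene", genes$start, genes$end, ".",
          genes$strand, ".", paste0("ID=", genes$gene_id), sep = "\t"),
    paste(exons$chrom, "mendelscan", "exon", exons$start, exons$end, ".",
          exons$strand, ".", paste0("Parent=", exons$gene_id), sep = "\t")
  )
  readr::write_lines(lines, file)
  invisible(file)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  parent <- vapply(exons$Parent, function(p) as.character(p)[1], character(1))
  gene_annotation(
    genes = tibble(
      gene_id = as.character(genes$ID),
      chrom = as.character(genes$seqnames),
      strand = as.character(genes$strand),
      start = as.integer(genes$start),
      end = as.integer(genes$end)
    ),
    exons = tibble(
      gene_id = parent,
      chrom = as.character(exons$seqnames),
      start = as.integer(exons$start),
      end = as.integer(exons$end)
    )
  )
}

#' Write and read FASTA sequences
#'
#' Thin wrappers around Biostrings for the genome/gene sequences the
#' consequence engine consumes.
#'
#' @param seqs Named character vector of sequences.
#' @param file Path.
#' @return `read_fasta()`: a named character vector.
#' @export
write_fasta <- function(seqs, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  setNames(as.character(ss), names(ss))
}
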