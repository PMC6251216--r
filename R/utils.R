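#' Haldane map function
#'
#' Converts a genetic map distance into a recombination fraction assuming no
#' crossover interference: `r = (1 - exp(-2 d / 100)) / 2` for a distance `d`
#' in centimorgans. `r` rises from 0 at `d = 0` towards 0.5 for unlinked loci.
#'
#' @param d_cM Map distance(s) in centimorgans; non-negative.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 1, 10, 50, 1000))
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) abort("Map distances must be non-negative.")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Marker identifiers of the form "C<scaffold>_<position>"
#'
#' Variant markers are named after their scaffold and 1-based position, e.g.
#' `"C29_6721563"`. `marker_id()` builds the identifier, `parse_marker_id()`
#' splits it back into scaffold and position.
#'
#' @param chrom Scaffold/chromosome name(s), e.g. `"C29"`.
#' @param pos 1-based position(s) in bp.
#' @return `marker_id()`: character ids. `parse_marker_id()`: a tibble with
#'   columns `scaffold` and `pos`.
#' @examples
#' marker_id("C29", 6721563)
#' parse_marker_id("C29_6721563")
#' @export
marker_id <- function(chrom, pos) {
  paste0(chrom, "_", format(pos, scientific = FALSE, trim = TRUE))
}

#' @rdname marker_id
#' @param id Marker identifier(s) to parse.
#' @export
parse_marker_id <- function(id) {
  m <- stringr::str_match(id, "^C([0-9A-Za-z.]+)_([0-9]+)$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(sprintf(
      "Malformed marker identifier(s): %s (expected \"C<scaffold>_<position>\").",
      paste(id[bad], collapse = ", ")
    ))
  }
  tibble(scaffold = m[, 2], pos = as.integer(m[, 3]))
}

#' Physical distance between two markers on the same scaffold
#'
#' @param id_a,id_b Marker identifiers such as `"C29_6721553"`.
#' @return Absolute position difference in bp.
#' @examples
#' marker_distance("C29_6721553", "C29_6912561") # 191008
#' @export
marker_distance <- function(id_a, id_b) {
  a <- parse_marker_id(id_a)
  b <- parse_marker_id(id_b)
  if (a$scaffold != b$scaffold) {
    abort(sprintf(
      "Markers lie on different scaffolds (C%s vs C%s); distance is undefined.",
      a$scaffold, b$scaffold
    ))
  }
  abs(a$pos - b$pos)
}

chrom_name <- function(i) paste0("C", as.integer(i))

# meta columns of a genotype table; everything after them is a sample column
GENO_META <- c("variant_id", "chrom", "pos", "ref", "alt", "type")

geno_sample_ids <- function(genotypes) {
  setdiff(names(genotypes), GENO_META)
}

geno_matrix <- function(genotypes) {
  ids <- geno_sample_ids(genotypes)
  m <- as.matrix(genotypes[, ids, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genotypes$variant_id
  m
}

variant_meta <- function(genotypes) {
  genotypes[, intersect(GENO_META, names(genotypes)), drop = FALSE]
}

assert_genotype_tbl <- function(genotypes, arg = "genotypes") {
  if (!is.data.frame(genotypes) || !all(c("variant_id", "chrom", "pos") %in% names(genotypes))) {
    abort(sprintf(
      "`%s` must be a genotype table with at least variant_id/chrom/pos columns.", arg
    ))
  }
  invisible(genotypes)
}
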