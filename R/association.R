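#' Quality-filter a genotype table
#'
#' Joint-calling style variant QC: a variant is retained iff its number of
#' non-missing genotype calls is at least `min_count` AND its minor-allele
#' frequency (computed from genotype dosages over non-missing calls) is at
#' least `min_freq`. Both thresholds are inclusive; variant order is
#' preserved.
#'
#' @param genotypes Genotype table as produced by [simulate_f2()] (rows =
#'   variants, meta columns then one 0/1/2/`NA` column per sample).
#' @param min_count Minimum non-missing call count (default 100).
#' @param min_freq Minimum minor-allele frequency in `[0, 0.5]` (default 0.1).
#' @return The retained rows of `genotypes`, with an attribute `qc` holding a
#'   per-variant tibble of `n_called`, `maf` and `retained`.
#' @examples
#' pop <- simulate_f2(cross_design(n_f2 = 130, n_chromosomes = 2,
#'                                 variants_per_chrom = 50, causal_pos = 1e6))
#' nrow(qc_filter(pop$genotypes))
#' @export
qc_filter <- function(genotypes, min_count = 100, min_freq = 0.1) {
  assert_genotype_tbl(genotypes)
  if (min_count < 0) abort("`min_count` must be >= 0.")
  if (min_freq < 0 || min_freq > 0.5) abort("`min_freq` must be in [0, 0.5].")
  g <- geno_matrix(genotypes)
  n_called <- rowSums(!is.na(g))
  freq <- ifelse(n_called > 0, rowSums(g, na.rm = TRUE) / (2 * n_called), NA_real_)
  maf <- pmin(freq, 1 - freq)
  keep <- n_called >= min_count & !is.na(maf) & maf >= min_freq
  out <- genotypes[keep, , drop = FALSE]
  attr(out, "qc") <- tibble(
    variant_id = genotypes$variant_id,
    n_called = unname(n_called), maf = unname(maf), retained = unname(keep)
  )
  out
}

#' Per-variant genotype-phenotype association scan
#'
#' Tests every variant for association with a binary phenotype across the F2
#' population. Two methods are available:
#'
#' * `"chi2"` (default): Pearson chi-square on the 2 (phenotype) x k
#'   (observed genotype class) contingency table, `df = k - 1`. For a fully
#'   penetrant phenotype that is a deterministic function of genotype the
#'   statistic equals the number of non-missing samples.
#' * `"glm"`: the general-linear-model route - an F-test of the phenotype
#'   regressed on genotype-class indicators against the intercept-only model
#'   (one-way ANOVA on the 0/1 phenotype).
#'
#' Missing genotypes are dropped variant-wise; monomorphic variants (a single
#' observed genotype class) get statistic 0, `df` 0 and `p_value` 1.
#'
#' @param genotypes Genotype table (rows = variants).
#' @param phenotypes Tibble with `sample_id` and `phenotype` (`"CL"`/`"cl"`
#'   or 0/1); every genotype sample column must be present here.
#' @param method `"chi2"` or `"glm"`.
#' @return A tibble of class `assoc_scan`: `variant_id`, `chrom`, `pos`, `n`
#'   (non-missing calls), `statistic`, `df`, `p_value`, `method`, sorted in
#'   input variant order.
#' @examples
#' pop <- simulate_f2(cross_design(n_f2 = 130, n_chromosomes = 2,
#'                                 variants_per_chrom = 40, causal_pos = 1e6))
#' scan <- assoc_scan(pop$genotypes, pop$phenotypes)
#' dplyr::arrange(scan, p_value)
#' @export
assoc_scan <- function(genotypes, phenotypes, method = c("chi2", "glm")) {
  assert_genotype_tbl(genotypes)
  method <- match.arg(method)
  y <- align_phenotypes(genotypes, phenotypes)
  if (length(unique(y)) < 2) {
    abort("All samples share one phenotype; association is undefined.")
  }
  g <- geno_matrix(genotypes)
  case <- y == 1L # recessive-phenotype group

  # per-variant 2 x 3 class counts via vectorised column sums
  cnt <- function(mask) {
    m <- g[, mask, drop = FALSE]
    cbind(rowSums(m == 0L, na.rm = TRUE),
          rowSums(m == 1L, na.rm = TRUE),
          rowSums(m == 2L, na.rm = TRUE))
  }
  O1 <- cnt(!case) # normal phenotype
  O2 <- cnt(case)  # recessive phenotype
  col_tot <- O1 + O2
  r1 <- rowSums(O1)
  r2 <- rowSums(O2)
  N <- r1 + r2
  k <- rowSums(col_tot > 0)

  if (method == "chi2") {
    stat <- numeric(nrow(g))
    for (cls in 1:3) {
      cj <- col_tot[, cls]
      e1 <- r1 * cj / N
      e2 <- r2 * cj / N
      term <- ifelse(cj > 0, (O1[, cls] - e1)^2 / pmax(e1, .Machine$double.eps) +
                       (O2[, cls] - e2)^2 / pmax(e2, .Machine$double.eps), 0)
      stat <- stat + term
    }
    df <- pmax(k - 1L, 0L)
  } else {
    # one-way ANOVA F on the 0/1 phenotype from class counts:
    # within class c, n_c calls of which m_c are recessive
    n_c <- col_tot
    m_c <- O2
    ybar <- r2 / N
    ssb <- rowSums(ifelse(n_c > 0, n_c * (m_c / pmax(n_c, 1) - ybar)^2, 0))
    ssw <- rowSums(ifelse(n_c > 0, m_c - m_c^2 / pmax(n_c, 1), 0))
    df <- pmax(k - 1L, 0L)
    df2 <- N - k
    stat <- ifelse(df > 0 & df2 > 0 & ssw > 0, (ssb / pmax(df, 1)) / (ssw / pmax(df2, 1)), Inf)
    # a perfect fit (ssw == 0) with df > 0 is infinitely significant
    stat[df == 0] <- 0
  }

  p <- rep(1, nrow(g))
  poly <- df > 0
  if (method == "chi2") {
    p[poly] <- pchisq(stat[poly], df[poly], lower.tail = FALSE)
  } else {
    df2 <- N - k
    ok <- poly & is.finite(stat)
    p[ok] <- pf(stat[ok], df[ok], df2[ok], lower.tail = FALSE)
    p[poly & !is.finite(stat)] <- 0
  }
  stat[df == 0] <- 0
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1]

  out <- tibble(
    variant_id = genotypes$variant_id,
    chrom = genotypes$chrom,
    pos = genotypes$pos,
    n = unname(N),
    statistic = unname(stat),
    df = as.integer(unname(df)),
    p_value = unname(p),
    method = if (method == "chi2") "chi2_genotypic" else "glm_dosage_F"
  )
  class(out) <- c("assoc_scan", class(out))
  out
}

align_phenotypes <- function(genotypes, phenotypes) {
  if (!all(c("sample_id", "phenotype") %in% names(phenotypes))) {
    abort("`phenotypes` must have sample_id and phenotype columns.")
  }
  samples <- geno_sample_ids(genotypes)
  if (length(samples) == 0) abort("Empty population: genotype table has no sample columns.")
  missing <- setdiff(samples, phenotypes$sample_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Samples missing from the phenotype table: %s.",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  ph <- phenotypes$phenotype[match(samples, phenotypes$sample_id)]
  y <- encode_phenotype(ph)
  if (anyNA(y)) abort("Phenotypes must be \"CL\"/\"cl\" (or 0/1).")
  y
}

encode_phenotype <- function(ph) {
  if (is.numeric(ph)) {
    ifelse(ph %in% c(0, 1), as.integer(ph), NA_integer_)
  } else {
    dplyr::case_match(as.character(ph), "CL" ~ 0L, "cl" ~ 1L, .default = NA_integer_)
  }
}

#' Define the target interval around the association peak
#'
#' Selects the variant with the lowest association p-value (ties broken by
#' chromosome then position) and collects all scanned variants within
#' `flank_bp` up- and downstream of it on the same chromosome. Interval
#' endpoints are the positions of the outermost member variants, not the
#' literal peak +/- flank coordinates.
#'
#' @param scan An `assoc_scan` result (or any tibble with `variant_id`,
#'   `chrom`, `pos`, `p_value`).
#' @param flank_bp Flanking distance on each side of the peak (default
#'   200,000 bp).
#' @return An object of class `target_interval`: a list with `chrom`,
#'   `peak` (one-row tibble), `flank_bp`, `start`, `end` and `members` (a
#'   tibble of the in-interval variants sorted by position). [tidy()] returns
#'   the members, [glance()] a one-row summary.
#' @examples
#' scan <- tibble::tibble(
#'   variant_id = c("C29_6522236", "C29_6721563", "C29_6918901"),
#'   chrom = "C29", pos = c(6522236, 6721563, 6918901),
#'   p_value = c(1e-20, 1e-90, 1e-25)
#' )
#' define_interval(scan)
#' @export
define_interval <- function(scan, flank_bp = 200000) {
  if (!is.data.frame(scan) || nrow(scan) == 0) {
    abort("`scan` must be a non-empty association result.")
  }
  if (!all(c("variant_id", "chrom", "pos", "p_value") %in% names(scan))) {
    abort("`scan` must have variant_id, chrom, pos and p_value columns.")
  }
  if (any(!is.finite(scan$p_value))) abort("All p-values must be finite.")
  # A fully penetrant binary trait separates perfectly at every marker with
  # no informative recombinant, so a whole linkage block attains the maximal
  # statistic (chi-square = n); the p-value ordering inside that block only
  # reflects per-marker call counts, which is noise. The peak is therefore
  # the marker closest to the midpoint of the perfectly-separating block
  # (on its modal chromosome); without perfect separators, the lowest-p
  # variant wins, ties broken by chromosome then position.
  cand <- integer()
  if (all(c("statistic", "n", "df") %in% names(scan))) {
    cand <- which(scan$df > 0 & abs(scan$statistic - scan$n) < 1e-9)
  }
  if (length(cand) == 0) {
    tied <- which(scan$p_value == min(scan$p_value))
    cand <- if (length(tied) > 1) tied else tied[1]
  }
  if (length(cand) > 1) {
    chroms <- scan$chrom[cand]
    modal <- names(sort(table(chroms), decreasing = TRUE))[1]
    cand <- cand[chroms == modal]
    mid <- (min(scan$pos[cand]) + max(scan$pos[cand])) / 2
    cand <- cand[order(abs(scan$pos[cand] - mid), scan$pos[cand])]
  }
  peak <- scan[cand[1], ]
  members <- scan |>
    filter(.data$chrom == peak$chrom, abs(.data$pos - peak$pos) <= flank_bp) |>
    arrange(.data$pos)
  structure(
    list(
      chrom = peak$chrom,
      peak = peak,
      flank_bp = flank_bp,
      start = min(members$pos),
      end = max(members$pos),
      members = members
    ),
    class = "target_interval"
  )
}

#' @export
print.target_interval <- function(x, ...) {
  cat(sprintf(
    "<target_interval> %s:%d-%d (%d bp), peak %s (P = %.3g), %d member variants\n",
    x$chrom, x$start, x$end, x$end - x$start, x$peak$variant_id,
    x$peak$p_value, nrow(x$members)
  ))
  invisible(x)
}

#' @export
tidy.target_interval <- function(x, ...) x$members

#' @export
glance.target_interval <- function(x, ...) {
  tibble(
    chrom = x$chrom,
    start = x$start,
    end = x$end,
    span_bp = x$end - x$start,
    peak_id = x$peak$variant_id,
    peak_p = x$peak$p_value,
    flank_bp = x$flank_bp,
    n_members = nrow(x$members)
  )
}

#' Sequencing coverage arithmetic
#'
#' `coverage_per_sample()` divides a summed fold-coverage across samples into
#' the mean per-sample fold coverage. `raw_gb_to_coverage()` converts a total
#' raw yield in Gb into mean fold coverage given a genome size in Mb and a
#' sample count.
#'
#' @param total_coverage_x Summed fold coverage over all samples.
#' @param n_samples Number of samples; must be positive.
#' @return Mean fold coverage per sample (unrounded).
#' @examples
#' coverage_per_sample(2347.32, 130) # ~18.06
#' raw_gb_to_coverage(847.46, 354, 132) # ~18.1
#' @export
coverage_per_sample <- function(total_coverage_x, n_samples) {
  if (n_samples <= 0) abort("`n_samples` must be positive.")
  total_coverage_x / n_samples
}

#' @rdname coverage_per_sample
#' @param total_gb Total raw data in gigabases.
#' @param genome_mb Genome size in megabases; must be positive.
#' @export
raw_gb_to_coverage <- function(total_gb, genome_mb, n_samples) {
  if (genome_mb <= 0) abort("`genome_mb` must be positive.")
  if (n_samples <= 0) abort("`n_samples` must be positive.")
  total_gb * 1000 / genome_mb / n_samples
}
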