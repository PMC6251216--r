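#' Chi-square goodness-of-fit test for a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit of observed phenotype-class counts against an
#' expected segregation ratio, e.g. 3:1 for an F2 of a monogenic recessive
#' trait or 1:1 for its backcross. The statistic is
#' `sum((O - E)^2 / E)` with `E = total * ratio / sum(ratio)` and no
#' continuity correction; the p-value comes from the chi-square distribution
#' with `length(counts) - 1` degrees of freedom. The result also carries the
#' critical value at `alpha` so the usual "fits / does not fit" call can be
#' read off directly.
#'
#' @param counts Ordered non-negative class counts, e.g. `c(normal, mutant)`.
#' @param ratio Ordered positive expected ratio, e.g. `c(3, 1)`; same length
#'   as `counts`. Scaling the ratio does not change the statistic.
#' @param label Optional free-text label carried into the result.
#' @param alpha Significance level for the fit call (default 0.05).
#' @return An object of class `seg_gof` with elements `chi_square`, `df`,
#'   `p_value`, `critical_value`, `fits`, `counts`, `expected`, `ratio`,
#'   `label`, `alpha`. Use [tidy()]/[glance()] for tibble output.
#' @examples
#' seg_test(c(830, 261), ratio = c(3, 1)) # chi-square 0.67, fits
#' seg_test(c(221, 213), ratio = c(1, 1))
#' @export
seg_test <- function(counts, ratio = c(3, 1), label = NULL, alpha = 0.05) {
  if (length(counts) != length(ratio) || length(counts) < 2) {
    abort("`counts` and `ratio` must have equal length >= 2.")
  }
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  if (any(ratio <= 0)) abort("`ratio` classes must all be positive.")
  total <- sum(counts)
  if (total == 0) abort("Total count is zero; the test is undefined.")
  expected <- total * ratio / sum(ratio)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  crit <- qchisq(1 - alpha, df)
  structure(
    list(
      chi_square = chi2,
      df = df,
      p_value = pchisq(chi2, df, lower.tail = FALSE),
      critical_value = crit,
      fits = chi2 <= crit,
      counts = as.numeric(counts),
      expected = expected,
      ratio = as.numeric(ratio),
      label = label,
      alpha = alpha
    ),
    class = "seg_gof"
  )
}

#' @export
print.seg_gof <- function(x, ...) {
  cat(sprintf(
    "<seg_gof>%s %s vs %s: chi-square = %.4f (df = %d, crit %.2f), P = %.4g -> %s\n",
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    paste(x$counts, collapse = ":"), paste(x$ratio, collapse = ":"),
    x$chi_square, x$df, x$critical_value, x$p_value,
    if (x$fits) "fits" else "does not fit"
  ))
  invisible(x)
}

#' @export
tidy.seg_gof <- function(x, ...) {
  tibble(
    class = seq_along(x$counts),
    observed = x$counts,
    expected = x$expected,
    ratio = x$ratio
  )
}

#' @export
glance.seg_gof <- function(x, ...) {
  tibble(
    label = x$label %||% NA_character_,
    chi_square = x$chi_square,
    df = x$df,
    p_value = x$p_value,
    critical_value = x$critical_value,
    fits = x$fits
  )
}

#' Run segregation tests over a table of observations
#'
#' Vectorised wrapper around [seg_test()] for a tibble of crosses, e.g. the
#' BC1 and F2 rows of an inheritance table.
#'
#' @param observations A data frame with columns `label`, `n_normal`,
#'   `n_mutant`, `ratio_normal`, `ratio_mutant`.
#' @param alpha Significance level.
#' @return A tibble with one [glance()] row per observation.
#' @examples
#' seg_test_all(tibble::tibble(
#'   label = c("F2 cross 1", "BC1 cross 1"),
#'   n_normal = c(830, 221), n_mutant = c(261, 213),
#'   ratio_normal = c(3, 1), ratio_mutant = c(1, 1)
#' ))
#' @export
seg_test_all <- function(observations, alpha = 0.05) {
  needed <- c("label", "n_normal", "n_mutant", "ratio_normal", "ratio_mutant")
  if (!all(needed %in% names(observations))) {
    abort(paste0("`observations` must have columns: ", paste(needed, collapse = ", "), "."))
  }
  purrr::map_dfr(seq_len(nrow(observations)), function(i) {
    o <- observations[i, ]
    glance(seg_test(
      c(o$n_normal, o$n_mutant),
      ratio = c(o$ratio_normal, o$ratio_mutant),
      label = o$label, alpha = alpha
    ))
  })
}

#' Classify the inheritance mode of a binary trait
#'
#' Applies the classical monogenic-recessive checklist to cross data: all F1
#' individuals (direct and reciprocal) must show the normal phenotype, the
#' backcross to the mutant parent must segregate 1:1, and the F2 must
#' segregate 3:1 (both by [seg_test()] at `alpha`). The verdict is
#' `"monogenic recessive"` only if every condition holds; otherwise
#' `"not consistent"` with the failing conditions named.
#'
#' @param f1_counts Numeric `c(normal, mutant)` tallies pooled over F1s.
#' @param bc1_counts Numeric `c(normal, mutant)` for the backcross; tested
#'   against `1:1`.
#' @param f2_counts Numeric `c(normal, mutant)` for the F2; tested against
#'   `3:1`.
#' @param alpha Significance level for both goodness-of-fit tests.
#' @return A list of class `inheritance_verdict`: `verdict`, `reasons`
#'   (character, empty when consistent), and the two `seg_gof` objects.
#' @examples
#' classify_inheritance(c(58, 0), bc1_counts = c(221, 213),
#'                      f2_counts = c(830, 261))
#' @export
classify_inheritance <- function(f1_counts, bc1_counts, f2_counts, alpha = 0.05) {
  if (length(f1_counts) != 2 || sum(f1_counts) == 0) {
    abort("`f1_counts` must be c(normal, mutant) with a positive total.")
  }
  bc1 <- seg_test(bc1_counts, ratio = c(1, 1), label = "BC1 vs 1:1", alpha = alpha)
  f2 <- seg_test(f2_counts, ratio = c(3, 1), label = "F2 vs 3:1", alpha = alpha)
  reasons <- character()
  if (f1_counts[2] > 0) {
    reasons <- c(reasons, sprintf("F1 segregates (%d mutant-phenotype F1s)", f1_counts[2]))
  }
  if (!bc1$fits) {
    reasons <- c(reasons, sprintf("BC1 deviates from 1:1 (chi-square %.2f)", bc1$chi_square))
  }
  if (!f2$fits) {
    reasons <- c(reasons, sprintf("F2 deviates from 3:1 (chi-square %.2f)", f2$chi_square))
  }
  structure(
    list(
      verdict = if (length(reasons) == 0) "monogenic recessive" else "not consistent",
      reasons = reasons,
      bc1 = bc1,
      f2 = f2
    ),
    class = "inheritance_verdict"
  )
}

#' @export
print.inheritance_verdict <- function(x, ...) {
  cat(sprintf("<inheritance_verdict> %s\n", x$verdict))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  if (!is.null(x$bc1)) print(x$bc1)
  if (!is.null(x$f2)) print(x$f2)
  invisible(x)
}
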