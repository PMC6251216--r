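#' Manhattan plot of an association scan
#'
#' Plots -log10(p) along a cumulative genome coordinate, alternating shades
#' by chromosome, optionally highlighting a target interval and its peak.
#'
#' @param object An `assoc_scan` result.
#' @param interval Optional [define_interval()] result to highlight.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.assoc_scan <- function(object, interval = NULL, ...) {
  offsets <- object |>
    group_by(.data$chrom) |>
    summarise(chrom_len = max(.data$pos), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$chrom_len, default = 0)))
  dat <- object |>
    left_join(offsets, by = "chrom") |>
    mutate(
      x = .data$pos + .data$offset,
      logp = -log10(.data$p_value),
      shade = factor(match(.data$chrom, unique(object$chrom)) %% 2)
    )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$logp)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$shade), size = 0.8,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "grey65")) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
  if (!is.null(interval)) {
    hl <- dat |>
      filter(.data$chrom == interval$chrom,
             .data$pos >= interval$start, .data$pos <= interval$end)
    peak <- dat |> filter(.data$variant_id == interval$peak$variant_id)
    p <- p +
      ggplot2::geom_point(data = hl, colour = "forestgreen", size = 1) +
      ggplot2::geom_point(data = peak, colour = "red", size = 2)
  }
  p
}

#' Funnel plot of a screening report
#'
#' Bar chart of the variant counts surviving each screening step, the
#' package's analogue of the "90 -> 6 / 42 -> 6" narrative a screening run
#' produces.
#'
#' @param object A `screen_report` from [variant_screen()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  f <- object$funnel
  dat <- tibble(
    step = factor(
      c("interval", "panel screen", "pool screen", "intersection"),
      levels = c("interval", "panel screen", "pool screen", "intersection")
    ),
    n = c(f[["input"]], f[["panel_retained"]], f[["pool_retained"]],
          f[["intersection"]])
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "variants retained") +
    ggplot2::theme_minimal()
}
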