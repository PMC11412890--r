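#' Plot an information-component time series
#'
#' Ribbon of the 95% interval around the yearly IC, with the conventional
#' `IC - 2SD` screening bound dashed and the zero line marking "no signal".
#'
#' @param object An `ic_trend` from [ic_time_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ic_trend <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$undefined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$ic)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ic_lo,
                                      ymax = .data$ic_hi),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ic025), linetype = 2,
                       colour = "grey30") +
    ggplot2::labs(
      title = paste0("Information component over time: ",
                     attr(object, "term")),
      subtitle = paste0(attr(object, "mode"),
                        " mode; dashed: IC - 2SD screening bound"),
      x = "receipt year", y = "IC (bits)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of disproportionality results
#'
#' @param stats Tibble from [dispro_stats()].
#' @param x Which statistic drives the x axis.
#' @param label_top Label the strongest `label_top` terms.
#' @return A ggplot.
#' @export
plot_volcano <- function(stats, x = c("ror", "prr", "ic025", "eb05"),
                         label_top = 5) {
  x <- match.arg(x)
  xv <- switch(x,
    ror = log2(stats$ror), prr = log2(stats$prr),
    ic025 = stats$ic025, eb05 = log2(stats$eb05)
  )
  df <- tibble::tibble(
    term = stats$term, a = stats$a, x = xv,
    y = -log(pmax(stats$p_chi2, .Machine$double.xmin))
  )
  df <- dplyr::filter(df, is.finite(.data$x), is.finite(.data$y))
  lab <- df |>
    dplyr::arrange(dplyr::desc(.data$x * .data$y)) |>
    dplyr::slice_head(n = label_top)
  xlab <- if (x == "ic025") "IC - 2SD (bits)" else paste0("log2(", x, ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = log10(.data$a)), alpha = 0.7) +
    ggplot2::scale_colour_gradient(low = "steelblue", high = "firebrick",
                                   name = "log10 count") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$term),
                       size = 2.8, vjust = -0.6) +
    ggplot2::labs(x = xlab, y = "-ln(p), chi-square test") +
    ggplot2::theme_minimal()
}

#' Heatmap of positive signal counts per SOC and algorithm
#'
#' @param decisions Tibble from [evaluate_signals()] (PT level).
#' @param pt_to_soc SOC map.
#' @return A ggplot.
#' @export
plot_signal_heatmap <- function(decisions, pt_to_soc) {
  hm <- export_plot_tables(
    stats = tibble::tibble(term = decisions$term, a = decisions$a,
                           ror = NA_real_, prr = NA_real_,
                           ic025 = NA_real_, eb05 = NA_real_, p_chi2 = 1),
    decisions = decisions, pt_to_soc = pt_to_soc
  )$heatmap
  ggplot2::ggplot(hm, ggplot2::aes(x = .data$algorithm, y = .data$soc,
                                   fill = .data$n_positive_pts)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "positive PTs") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Intersection-size bars of the multi-algorithm overlap
#'
#' A compact UpSet-style display: one bar per observed intersection pattern
#' of the five algorithms, ordered by size.
#'
#' @param overlap An `overlap_summary`.
#' @param top Show the `top` largest patterns.
#' @return A ggplot.
#' @export
plot_overlap <- function(overlap, top = 15) {
  stopifnot(inherits(overlap, "overlap_summary"))
  df <- overlap$patterns |>
    dplyr::slice_head(n = top) |>
    dplyr::mutate(pattern = factor(.data$pattern,
                                   levels = rev(.data$pattern)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$pattern)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.2,
                       size = 3) +
    ggplot2::labs(x = "terms in intersection", y = NULL) +
    ggplot2::theme_minimal()
}
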