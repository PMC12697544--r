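# ggplot2 views of the main result types.

#' Plot subfield appearance order
#'
#' Dot plot of appearance distance from the anterior tip, in mm or as % of
#' head length, per subfield (optionally across cases).
#'
#' @param order_tbl Output of [appearance_order()] (rows from several cases
#'   may be bound together).
#' @param unit `"mm"` or `"pct"`.
#' @return A ggplot object.
#' @export
plot_appearance_order <- function(order_tbl, unit = c("mm", "pct")) {
  unit <- match.arg(unit)
  ycol <- if (unit == "mm") "distance_from_tip_mm" else "distance_from_tip_pct"
  lab <- if (unit == "mm") "Distance from anterior tip (mm)" else "Distance from tip (% head length)"
  order_tbl$label <- stats::reorder(order_tbl$label, order_tbl[[ycol]], mean)
  ggplot2::ggplot(order_tbl, ggplot2::aes(x = .data$label, y = .data[[ycol]])) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Plot subicular-complex composition along the body
#'
#' Stacked composition of SUB / PrS / PaS percentages by long-axis
#' position.
#'
#' @param subic_tbl Output of [measure_subicular()] (possibly multi-case).
#' @return A ggplot object.
#' @export
plot_subicular_proportions <- function(subic_tbl) {
  long <- subic_tbl |>
    dplyr::filter(is.na(.data$skipped_reason)) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("pct_SUB", "pct_PrS", "pct_PaS")),
      names_to = "region", values_to = "pct", names_prefix = "pct_"
    ) |>
    dplyr::filter(!is.na(.data$pct)) |>
    dplyr::group_by(.data$position_pct, .data$region) |>
    dplyr::summarise(pct = mean(.data$pct), .groups = "drop")
  long$region <- factor(long$region, levels = c("PaS", "PrS", "SUB"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$position_pct, y = .data$pct, fill = .data$region
  )) +
    ggplot2::geom_col(position = "stack", width = 6) +
    ggplot2::labs(
      x = "Position along long axis (% of total length from uncal apex)",
      y = "% of subicular complex width", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the SRLM projection profile
#'
#' Median and IQR of the CA1/CA2/CA3 SRLM proportions per long-axis
#' position.
#'
#' @param srlm_tbl Output of [srlm_profile()] (possibly multi-case).
#' @return A ggplot object.
#' @export
plot_srlm_profile <- function(srlm_tbl) {
  long <- srlm_tbl |>
    dplyr::filter(is.na(.data$skipped_reason)) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("prop_CA1", "prop_CA2", "prop_CA3")),
      names_to = "subfield", values_to = "prop", names_prefix = "prop_"
    ) |>
    dplyr::group_by(.data$position_pct, .data$subfield) |>
    dplyr::summarise(
      med = stats::median(.data$prop),
      lo = stats::quantile(.data$prop, 0.25),
      hi = stats::quantile(.data$prop, 0.75),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$position_pct, y = .data$med,
    colour = .data$subfield, fill = .data$subfield
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Position along long axis (%)", y = "Proportion of lateral SRLM",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the SUB-CA1 border shift
#'
#' Relative border position per offset (0 mm vs 20 mm posterior to the
#' uncal apex), for each reference width.
#'
#' @param border_tbl Output of [measure_border_at_offsets()]
#'   (possibly multi-case).
#' @return A ggplot object.
#' @export
plot_border_shift <- function(border_tbl) {
  long <- border_tbl |>
    dplyr::filter(!is.na(.data$z_used)) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("pct_of_full_width", "pct_of_dg_width")),
      names_to = "reference", values_to = "pct"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$offset_mm), y = .data$pct
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$reference) +
    ggplot2::labs(
      x = "Offset posterior to uncal apex (mm)",
      y = "Relative SUB-CA1 border position (%)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname digitation_profile
#' @param object A `digitation_profile`.
#' @param ... Unused.
#' @export
autoplot.digitation_profile <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y_smooth)
  peaks <- tibble::tibble(x = object$peaks_x)
  peaks$y <- df$y[match(peaks$x, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = peaks, colour = "red", size = 2) +
    ggplot2::labs(
      x = "Column (medial to lateral)", y = "Superior surface height (voxels)",
      title = sprintf("%d digitation(s)", object$n_digitations)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
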