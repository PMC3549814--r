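#' Feature-plane plot of fate calls
#'
#' Draws the trapezoid feature plane with the three pure-fate segments and
#' overlays classified points colored by their argmax fate.
#'
#' @param calls A tibble with columns `u`, `v`, `label` (e.g. from
#'   [classify_fates()] or [infer_fates()]).
#' @return A ggplot object.
#' @export
plot_feature_plane <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("u", "v", "label") %in% names(calls)))
  segs <- fate_segments()
  hull <- tibble::tibble(u = c(-1, 1, 0.5, -0.5, -1),
                         v = c(-1, 1, 0.5, 0, -1))
  fate_cols <- c(SF = "#D55E00", CF = "#009E73", NF = "#0072B2")
  ggplot2::ggplot() +
    ggplot2::geom_path(data = hull, ggplot2::aes(x = .data$u, y = .data$v),
                       color = "grey60", linetype = "dashed") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$u0, y = .data$v0, xend = .data$u1,
                   yend = .data$v1, color = .data$fate),
      linewidth = 1.2
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(calls, !is.na(.data$label)),
      ggplot2::aes(x = .data$u, y = .data$v, color = .data$label),
      alpha = 0.6
    ) +
    ggplot2::scale_color_manual(values = fate_cols, name = "fate") +
    ggplot2::labs(x = "u = x - max(a, b)", y = "v = x - min(a, b)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @describeIn run_table1_experiment Bar chart of per-node mean accuracy
#'   with across-dataset standard deviation and the 33.3% three-way chance
#'   line.
#' @param object A `fate_accuracy` tibble.
#' @param ... Unused.
#' @export
autoplot.fate_accuracy <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$node_index),
                               y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      width = 0.15
    ) +
    ggplot2::geom_hline(yintercept = 100 / 3, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = "internal node index (1 = root)",
                  y = "classification accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn run_nbp Mixture densities per internal node, with the
#'   ancestral estimate marked.
#' @param object An `nbp_fit`.
#' @export
autoplot.nbp_fit <- function(object, ...) {
  pars <- tidy(object)
  grid <- pars |>
    dplyr::group_by(.data$node_index) |>
    dplyr::reframe(xg = seq(max(0, min(.data$mean - 3 * .data$sd)),
                            max(.data$mean + 3 * .data$sd),
                            length.out = 200))
  dens <- dplyr::inner_join(grid, pars, by = "node_index",
                            relationship = "many-to-many") |>
    dplyr::mutate(d = .data$weight *
                    stats::dnorm(.data$xg, .data$mean, .data$sd)) |>
    dplyr::group_by(.data$node_index, .data$xg) |>
    dplyr::summarise(density = sum(.data$d), .groups = "drop")
  est <- tibble::tibble(node_index = seq_along(object$estimates),
                        estimate = object$estimates)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$xg, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = est,
                        ggplot2::aes(xintercept = .data$estimate),
                        color = "firebrick", linetype = "dashed") +
    ggplot2::facet_wrap(~node_index, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "expression level", y = "mixture density") +
    ggplot2::theme_minimal()
}
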