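#' Plot a polar gaitogram
#'
#' Renders the gaitogram in the plane (`x = r cos(theta)`, `y = r sin(theta)`):
#' right-stance (upper) cycles in blue, left-stance (lower) in red, the
#' across-cycle mean curve drawn solid with a grey across-cycle SD band, and
#' optionally the tangent line between the weight-transfer points as a
#' dashed black segment.
#'
#' @param object A `polar_gaitogram`.
#' @param indices Optional `gaitogram_indices` row; when given, the tangent
#'   segment between the stored crossing points is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polar_gaitogram <- function(object, indices = NULL, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(x = .data$r * cos(.data$theta), y = .data$r * sin(.data$theta))
  grid <- df |>
    dplyr::mutate(bin = round(.data$theta / (2 * pi) * 72)) |>
    dplyr::group_by(.data$side, .data$bin) |>
    dplyr::summarise(theta = mean(.data$theta), r_m = mean(.data$r),
                     r_sd = sd(.data$r), .groups = "drop") |>
    dplyr::mutate(r_sd = ifelse(is.na(.data$r_sd), 0, .data$r_sd))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(group = interaction(.data$cycle, .data$side),
                                    colour = .data$side),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_polygon(
      data = dplyr::bind_rows(
        dplyr::arrange(grid, .data$side, .data$theta) |>
          dplyr::mutate(rr = pmax(0, .data$r_m - .data$r_sd)),
        dplyr::arrange(grid, .data$side, dplyr::desc(.data$theta)) |>
          dplyr::mutate(rr = .data$r_m + .data$r_sd)
      ),
      ggplot2::aes(x = .data$rr * cos(.data$theta), y = .data$rr * sin(.data$theta),
                   group = .data$side),
      inherit.aes = FALSE, fill = "grey60", alpha = 0.4
    ) +
    ggplot2::geom_path(
      data = grid,
      ggplot2::aes(x = .data$r_m * cos(.data$theta), y = .data$r_m * sin(.data$theta),
                   colour = .data$side, group = .data$side),
      linewidth = 0.9
    ) +
    ggplot2::scale_colour_manual(values = c(R = "#2166ac", L = "#b2182b"),
                                 labels = c(R = "right stance", L = "left stance")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r cos θ  (% of 5th-metatarsal coordinate)",
                  y = "r sin θ", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(indices) && is.finite(indices$crossing_r_R) && is.finite(indices$crossing_r_L)) {
    seg <- tibble::tibble(
      x = indices$crossing_r_R * cos(indices$crossing_theta_R),
      y = indices$crossing_r_R * sin(indices$crossing_theta_R),
      xend = indices$crossing_r_L * cos(indices$crossing_theta_L),
      yend = indices$crossing_r_L * sin(indices$crossing_theta_L)
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      inherit.aes = FALSE, linetype = "dashed", colour = "black"
    )
  }
  p
}

#' Plot the oscillator traces
#'
#' Input signal against its oscillator reconstruction (top) and the wrapped
#' continuous gait phase (bottom).
#'
#' @param object A `gait_phase_series`.
#' @param cop Optional `copx_series` to overlay the input signal.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_phase_series <- function(object, cop = NULL, ...) {
  d1 <- tibble::tibble(t = object$t, value = object$uhat, trace = "reconstruction")
  if (!is.null(cop)) {
    d1 <- dplyr::bind_rows(d1, tibble::tibble(t = cop$t, value = cop$copx, trace = "COPx input"))
  }
  d2 <- tibble::tibble(t = object$t, value = object$phase, trace = "gait phase (rad)")
  dplyr::bind_rows(dplyr::mutate(d1, panel = "signal"),
                   dplyr::mutate(d2, panel = "phase")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$t, y = .data$value, colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c("reconstruction" = "red",
                                            "COPx input" = "black",
                                            "gait phase (rad)" = "#2166ac")) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of an index by group with its decision threshold
#'
#' One panel per index, subjects as points, the decision threshold (where
#' one exists) as a dashed line — the side-by-side view used to judge
#' whether an index separates healthy from stroke gait.
#'
#' @param records Per-subject index table (e.g. [gait_index_table()] or
#'   `analyze_cohort()$reports`).
#' @param indices Index columns to show.
#' @param thresholds Named thresholds drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_index_comparison <- function(records,
                                  indices = c("ARI", "ppd", "pci"),
                                  thresholds = c(ARI = 10, ppd = 10)) {
  long <- tibble::as_tibble(records) |>
    tidyr::pivot_longer(dplyr::all_of(indices), names_to = "index", values_to = "value")
  thr <- tibble::tibble(index = names(thresholds), value = unname(thresholds)) |>
    dplyr::filter(.data$index %in% indices)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value, colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
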