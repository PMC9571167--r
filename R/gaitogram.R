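#' Build a polar gaitogram
#'
#' Pairs each sample's wrapped gait phase (angle \eqn{\theta = \varphi_1})
#' with the COPx magnitude (radius \eqn{r = |COPx|}). Right-foot stance
#' (positive COPx) forms the upper closed curve, left-foot stance the lower
#' one. Samples are grouped into complete cycles delimited by downward phase
#' wraps; the incomplete cycles at either end of the trial are dropped, as
#' are an optional number of warm-up cycles while the oscillator entrains.
#' Within a cycle, rare samples where the phase momentarily steps backwards
#' (adaptation jitter) are removed so that theta is non-decreasing.
#'
#' @param phase A `gait_phase_series` (see [estimate_phase()]).
#' @param cop The `copx_series` the phase was estimated from (same time grid).
#' @param warmup_cycles Complete cycles to discard at the start (default 2).
#' @return Tibble of class `polar_gaitogram` with columns `cycle`, `theta`,
#'   `r`, `side`; attribute `n_cycles`.
#' @examples
#' tr <- generate_trial(gait_template(n_strides = 10, seed = 1))$trial
#' cop <- compute_copx(tr)
#' gg <- build_gaitogram(estimate_phase(cop), cop)
#' attr(gg, "n_cycles")
#' @export
build_gaitogram <- function(phase, cop, warmup_cycles = 2L) {
  stopifnot(inherits(phase, "gait_phase_series"), inherits(cop, "copx_series"))
  if (nrow(phase) != nrow(cop) || max(abs(phase$t - cop$t)) > 1e-9) {
    abort("phase and COPx series are not on the same time grid", class = "gaitpolar_format_error")
  }
  p <- phase$phase
  wraps <- which(diff(p) < -pi)
  if (length(wraps) < 2) abort("no complete gait cycle in the trial", class = "gaitpolar_signal_error")
  cycle <- rep(NA_integer_, length(p))
  starts <- wraps + 1L
  for (k in seq_len(length(starts) - 1L)) {
    cycle[starts[k]:wraps[k + 1L]] <- k
  }
  seg <- stance_sign_segments(cop)
  side <- rep(NA_character_, length(p))
  for (j in seq_len(nrow(seg))) side[seg$start[j]:seg$end[j]] <- seg$side[j]
  keep <- !is.na(cycle) & cycle > warmup_cycles
  # a series that never takes a sign yields a degenerate (r = 0, sideless)
  # gaitogram; otherwise unsigned samples are dropped
  if (nrow(seg) > 0) keep <- keep & !is.na(side)
  if (!any(keep)) abort("no complete gait cycle after warm-up", class = "gaitpolar_signal_error")
  gg <- tibble::tibble(
    cycle = cycle[keep] - as.integer(warmup_cycles),
    theta = p[keep],
    r = abs(cop$copx[keep]),
    side = side[keep]
  )
  # enforce non-decreasing theta within each cycle (drop backward jitter)
  gg <- gg |>
    dplyr::group_by(.data$cycle) |>
    dplyr::filter(.data$theta == cummax(.data$theta)) |>
    dplyr::ungroup()
  structure(gg,
            class = c("polar_gaitogram", class(tibble::tibble())),
            n_cycles = length(unique(gg$cycle)),
            t_range = range(phase$t[keep]))
}

#' Area inside one polar closed curve
#'
#' Standard polar area \eqn{\int \frac{1}{2} r^2 \, d\theta} by the trapezoid
#' rule over the curve's theta span. The curve is closed through the origin
#' at its endpoints (the COPx sign changes), so no end correction is needed.
#' The published formula carries a stray extra theta factor inside the
#' integrand; that literal variant (\eqn{\int \frac{1}{2} r^2 \theta\,
#' d\theta}) is available with `literal = TRUE` for comparison, but only the
#' standard area makes the area-ratio interpretation as a weight-bearing-time
#' share coherent.
#'
#' @param theta,r Numeric vectors (rad, radius); theta must be non-decreasing
#'   with at least 3 samples.
#' @param literal If `TRUE`, evaluate the literal printed integrand.
#' @return Scalar area (rad * radius^2 units).
#' @export
closed_area <- function(theta, r, literal = FALSE) {
  if (length(theta) < 3 || length(theta) != length(r)) {
    abort("need >= 3 (theta, r) samples", class = "gaitpolar_format_error")
  }
  if (any(diff(theta) < 0)) abort("theta must be non-decreasing within a curve",
                                  class = "gaitpolar_geometry_error")
  f <- if (literal) 0.5 * r^2 * theta else 0.5 * r^2
  sum(diff(theta) * (head(f, -1) + tail(f, -1)) / 2)
}

#' Area ratios and the area ratio index (ARI)
#'
#' Each closed curve's share of the total gaitogram area, in percent:
#' `arearatio_R + arearatio_L = 100` by construction, and
#' `ARI = |arearatio_R - arearatio_L|`. ARI is 0% when the weight-bearing
#' times of the two feet are identical and grows as weight bearing
#' concentrates on one side.
#'
#' @param area_R,area_L Closed-curve areas for right and left stance.
#' @return One-row tibble: `arearatio_R`, `arearatio_L`, `ARI`.
#' @export
area_ratio_index <- function(area_R, area_L) {
  if (!is.finite(area_R) || !is.finite(area_L) || area_R < 0 || area_L < 0) {
    abort("areas must be finite and non-negative", class = "gaitpolar_format_error")
  }
  tot <- area_R + area_L
  if (tot <= 0) abort("both closed-curve areas are zero: ARI undefined",
                      class = "gaitpolar_undefined_index_error")
  rr <- area_R / tot * 100
  rl <- area_L / tot * 100
  tibble::tibble(arearatio_R = rr, arearatio_L = rl, ARI = abs(rr - rl))
}

#' Disorder cut-off on the per-foot area ratio
#'
#' With an ARI threshold `thr` (percent), the per-foot area-ratio bounds for
#' gait disorder are `50 +/- thr / 2`: a foot whose share exceeds the upper
#' bound is the unaffected foot; the opposite foot (below the lower bound) is
#' the affected foot.
#'
#' @param ari_threshold ARI threshold in percent (default 10).
#' @return Named numeric `c(lower, upper)` in percent.
#' @examples
#' arearatio_disorder_bounds(10) # 45, 55
#' @export
arearatio_disorder_bounds <- function(ari_threshold = 10) {
  if (!is.finite(ari_threshold) || ari_threshold <= 0) {
    abort("ari_threshold must be > 0", class = "gaitpolar_format_error")
  }
  c(lower = 50 - ari_threshold / 2, upper = 50 + ari_threshold / 2)
}

#' Classify gait disorder and the affected side
#'
#' A subject is classified as having a gait disorder when ARI exceeds the
#' threshold; equivalently one foot's area ratio exceeds
#' `50 + ari_threshold / 2` (that foot is the unaffected, longer
#' weight-bearing one) while the other falls below `50 - ari_threshold / 2`
#' (the affected side).
#'
#' @param indices One-row data frame with `arearatio_R`, `arearatio_L`, `ARI`
#'   (e.g. from [area_ratio_index()] or [gaitogram_indices()]).
#' @param ari_threshold ARI threshold in percent (default 10).
#' @return One-row tibble: `verdict` (`"normal"` / `"disorder"`),
#'   `affected_side` (`"none"`, `"left"`, `"right"`), `unaffected_side`,
#'   `ari_threshold`.
#' @export
classify_disorder <- function(indices, ari_threshold = 10) {
  b <- arearatio_disorder_bounds(ari_threshold)
  disorder <- indices$ARI > ari_threshold
  if (disorder) {
    affected <- if (indices$arearatio_R < b[["lower"]]) "right" else "left"
    unaffected <- setdiff(c("left", "right"), affected)
  } else {
    affected <- "none"
    unaffected <- "none"
  }
  tibble::tibble(
    verdict = if (disorder) "disorder" else "normal",
    affected_side = affected,
    unaffected_side = unaffected,
    ari_threshold = ari_threshold
  )
}

#' Tangent-line angle between the two closed curves
#'
#' The segment joining the two weight-transfer points — \eqn{(r_R, \theta_R)}
#' where COPx changes from positive to negative and \eqn{(r_L, \theta_L)}
#' where it changes from negative to positive — is tangent to both closed
#' curves. Two conventions for its angle are provided and always named in
#' reports:
#'
#' * `"as-printed"`: \eqn{|atan2(\theta_R - \theta_L,\; r_R - r_L)|},
#'   operating directly on the polar differences (dimensionally odd but
#'   faithful to the published formula);
#' * `"cartesian"`: convert both points to Cartesian coordinates and take the
#'   segment's angle with the horizontal axis, folded to `[0, pi/2]` — the
#'   geometric reading used for the figures and the classification cutoff
#'   (about 0.155 rad).
#'
#' @param crossing_R,crossing_L Numeric length-2 vectors `c(r, theta)`.
#' @param mode `"as-printed"` or `"cartesian"`.
#' @return Scalar angle in radians (non-negative).
#' @export
tangent_angle <- function(crossing_R, crossing_L, mode = c("as-printed", "cartesian")) {
  mode <- match.arg(mode)
  rR <- crossing_R[[1]]; thR <- crossing_R[[2]]
  rL <- crossing_L[[1]]; thL <- crossing_L[[2]]
  if (isTRUE(all.equal(c(rR, thR), c(rL, thL)))) {
    abort("coincident crossing points: tangent slope undefined",
          class = "gaitpolar_undefined_slope_error")
  }
  if (mode == "as-printed") {
    return(abs(atan2(thR - thL, rR - rL)))
  }
  dx <- rR * cos(thR) - rL * cos(thL)
  dy <- rR * sin(thR) - rL * sin(thL)
  a <- abs(atan2(dy, dx))
  if (a > pi / 2) a <- pi - a
  a
}

#' Locate the COPx sign-change (weight-transfer) points
#'
#' Finds every positive-to-negative crossing (right transfer point) and
#' negative-to-positive crossing (left transfer point) of the COPx series and
#' returns the gaitogram coordinates of each, linearly interpolating the
#' `(theta, r)` pair between the two samples bracketing the sign change.
#' Interpolating `r = |COPx|` across the sign change takes the chord over the
#' V-shaped dip, so the crossing radius reflects the bracketing magnitudes
#' rather than collapsing to zero.
#'
#' @param phase A `gait_phase_series`.
#' @param cop Matching `copx_series`.
#' @return Tibble with columns `type` (`"R"` = positive-to-negative, `"L"` =
#'   negative-to-positive), `t`, `theta`, `r`.
#' @export
crossing_points <- function(phase, cop) {
  stopifnot(inherits(phase, "gait_phase_series"), inherits(cop, "copx_series"))
  c0 <- cop$copx
  s <- sign(c0)
  j <- which(s[-length(s)] != 0 & s[-1] != 0 & s[-length(s)] != s[-1])
  if (!length(j)) {
    return(tibble::tibble(type = character(), t = numeric(), theta = numeric(), r = numeric()))
  }
  lam <- c0[j] / (c0[j] - c0[j + 1])
  theta1 <- phase$phase[j]
  theta2 <- phase$phase[j + 1]
  # unwrap across the cycle boundary so interpolation is local
  theta2u <- ifelse(theta2 < theta1 - pi, theta2 + 2 * pi, theta2)
  tibble::tibble(
    type = ifelse(c0[j] > 0, "R", "L"),
    t = cop$t[j] + lam * (cop$t[j + 1] - cop$t[j]),
    theta = (theta1 + lam * (theta2u - theta1)) %% (2 * pi),
    r = abs(c0[j]) + lam * (abs(c0[j + 1]) - abs(c0[j]))
  )
}

#' Subject-level gaitogram indices
#'
#' Computes per-cycle closed-curve areas for each side, averages them across
#' cycles, and derives the area ratios, ARI and tangent angle(s). Averaging
#' per-cycle areas (rather than pooling all samples into one mean curve)
#' makes the subject-level index robust to differing stride counts.
#'
#' @param gaitogram A `polar_gaitogram`.
#' @param phase,cop The series the gaitogram was built from (used to locate
#'   the weight-transfer points).
#' @param mode Tangent-angle convention reported in `ang_tangent`; both
#'   variants are always included as `ang_tangent_printed` /
#'   `ang_tangent_cartesian`.
#' @param literal_area Use the literal printed area integrand (see
#'   [closed_area()]).
#' @return One-row tibble of class `gaitogram_indices`: `area_R`, `area_L`,
#'   `arearatio_R`, `arearatio_L`, `ARI`, `ang_tangent`,
#'   `ang_tangent_printed`, `ang_tangent_cartesian`, `ang_mode`,
#'   `crossing_r_R`, `crossing_theta_R`, `crossing_r_L`, `crossing_theta_L`,
#'   `n_cycles`.
#' @export
gaitogram_indices <- function(gaitogram, phase, cop,
                              mode = c("as-printed", "cartesian"),
                              literal_area = FALSE) {
  stopifnot(inherits(gaitogram, "polar_gaitogram"))
  mode <- match.arg(mode)
  per_cycle <- gaitogram |>
    dplyr::group_by(.data$cycle, .data$side) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(area = closed_area(.data$theta, .data$r, literal = literal_area),
                     .groups = "drop")
  areas <- per_cycle |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(area = mean(.data$area), .groups = "drop")
  area_R <- areas$area[match("R", areas$side)]
  area_L <- areas$area[match("L", areas$side)]
  if (is.na(area_R) || is.na(area_L)) {
    abort("gaitogram lacks cycles on one side; cannot form area ratio",
          class = "gaitpolar_undefined_index_error")
  }
  ratios <- area_ratio_index(area_R, area_L)
  cr <- crossing_points(phase, cop)
  # restrict to the gaitogram's retained cycles (entrainment warm-up excluded)
  tr <- attr(gaitogram, "t_range")
  if (!is.null(tr)) cr <- cr[cr$t >= tr[1] & cr$t <= tr[2], ]
  mean_cross <- function(type) {
    d <- cr[cr$type == type, ]
    if (!nrow(d)) return(c(r = NA_real_, theta = NA_real_))
    # circular mean for theta (left crossings sit near the 0/2pi boundary)
    th <- atan2(mean(sin(d$theta)), mean(cos(d$theta))) %% (2 * pi)
    c(r = mean(d$r), theta = th)
  }
  xr <- mean_cross("R")
  xl <- mean_cross("L")
  if (any(is.na(c(xr, xl)))) {
    ang_p <- NA_real_; ang_c <- NA_real_
  } else {
    ang_p <- tangent_angle(xr, xl, mode = "as-printed")
    ang_c <- tangent_angle(xr, xl, mode = "cartesian")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(area_R = area_R, area_L = area_L),
    ratios,
    tibble::tibble(
      ang_tangent = if (mode == "as-printed") ang_p else ang_c,
      ang_tangent_printed = ang_p,
      ang_tangent_cartesian = ang_c,
      ang_mode = mode,
      crossing_r_R = xr[["r"]], crossing_theta_R = xr[["theta"]],
      crossing_r_L = xl[["r"]], crossing_theta_L = xl[["theta"]],
      n_cycles = attr(gaitogram, "n_cycles")
    )
  )
  class(out) <- c("gaitogram_indices", class(out))
  out
}
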