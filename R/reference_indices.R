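#' Detect heel-strike events from the heel sensor channels
#'
#' A strike is recorded at each upward crossing of an adaptive threshold —
#' `threshold_frac` times the channel's robust maximum (95th percentile) —
#' that is sustained for `debounce` consecutive samples, with re-triggers
#' suppressed inside the refractory window. The debounce keeps single-sample
#' sensor noise from registering as contact.
#'
#' @param trial A [grf_trial()].
#' @param layout `sensor_layout`; the channel labelled `"heel"` is used.
#' @param threshold_frac Fraction of the robust maximum (default 0.1).
#' @param refractory Minimum time between strikes on one foot (s, default 0.3).
#' @param debounce Consecutive supra-threshold samples required (default 3).
#' @return List of class `heel_strike_events` with fields `t_R`, `t_L`
#'   (strictly increasing strike times in seconds).
#' @export
detect_heel_strikes <- function(trial, layout = default_sensor_layout(),
                                threshold_frac = 0.1, refractory = 0.3,
                                debounce = 3L) {
  stopifnot(inherits(trial, "grf_trial"), inherits(layout, "sensor_layout"))
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    abort("threshold_frac must be in (0, 1)", class = "gaitpolar_format_error")
  }
  heel_idx <- match("heel", layout$labels)
  one_foot <- function(col, foot) {
    f <- trial[[col]]
    thr <- threshold_frac * quantile(f, 0.95, names = FALSE)
    if (thr <= 0) {
      abort(paste0("no heel-strike events detected on the ", foot, " foot"),
            class = "gaitpolar_detection_error")
    }
    above <- f > thr
    # candidate onsets: upward crossings whose next `debounce` samples stay above
    cand <- which(above & !c(FALSE, head(above, -1)))
    keep <- vapply(cand, function(j) {
      jj <- j:min(j + debounce - 1L, length(above))
      length(jj) == debounce && all(above[jj])
    }, logical(1))
    cand <- cand[keep]
    if (!length(cand)) {
      abort(paste0("no heel-strike events detected on the ", foot, " foot"),
            class = "gaitpolar_detection_error")
    }
    times <- trial$time[cand]
    out <- times[1]
    for (tt in times[-1]) if (tt - tail(out, 1) >= refractory) out <- c(out, tt)
    out
  }
  structure(
    list(t_R = one_foot(paste0("R", heel_idx), "right"),
         t_L = one_foot(paste0("L", heel_idx), "left")),
    class = "heel_strike_events"
  )
}

#' Phase coordination index (PCI)
#'
#' For each right-left-right strike triplet the stepping phase is
#' \deqn{\phi_i = 2\pi \frac{t_{Li} - t_{Ri}}{t_{R(i+1)} - t_{Ri}},}
#' which is \eqn{\pi} for ideally symmetric gait. PCI sums two percentages:
#' the mean absolute deviation from \eqn{\pi} scaled by \eqn{100/\pi}
#' (\eqn{P_{\phi ABS}}) and the coefficient of variation of \eqn{\phi_i}
#' (\eqn{\phi_{CV}}). The published dispersion formula omits the square root;
#' by default the standard CV (`sqrt(mean square deviation) / mean * 100`) is
#' used so that both summands are percentages, and the literal no-root
#' variant is available with `literal_cv = TRUE`.
#'
#' Left strikes that cannot be paired inside a right-right interval (zero or
#' several of them, e.g. from shuffling artefacts) are dropped with a warning
#' listing the affected intervals.
#'
#' @param events A `heel_strike_events` (or list with `t_R`, `t_L`).
#' @param literal_cv Use the literal no-root dispersion.
#' @return One-row tibble of class `pci_result`: `pci`, `p_phi_abs`,
#'   `phi_cv`, `phi_mean`, `n_strides`; attribute `phi_i` (per-stride
#'   phases, rad).
#' @examples
#' compute_pci(list(t_R = c(0, 1, 2), t_L = c(0.5, 1.5)))
#' @export
compute_pci <- function(events, literal_cv = FALSE) {
  t_R <- sort(events$t_R)
  t_L <- sort(events$t_L)
  if (length(t_R) < 2 || length(t_L) < 1) {
    abort("need at least 2 right strikes and 1 left strike", class = "gaitpolar_pairing_error")
  }
  phi <- numeric(0)
  dropped <- integer(0)
  for (i in seq_len(length(t_R) - 1L)) {
    inside <- t_L[t_L > t_R[i] & t_L <= t_R[i + 1L]]
    if (length(inside) == 1L) {
      phi <- c(phi, 2 * pi * (inside - t_R[i]) / (t_R[i + 1L] - t_R[i]))
    } else {
      dropped <- c(dropped, i)
    }
  }
  if (length(dropped)) {
    warn(paste0("dropped ", length(dropped), " right-right interval(s) without a unique left strike: ",
                paste(dropped, collapse = ", ")),
         class = "gaitpolar_pairing_warning")
  }
  if (length(phi) < 1) abort("no pairable stride triplets", class = "gaitpolar_pairing_error")
  p_phi_abs <- 100 * mean(abs(phi - pi)) / pi
  phi_mean <- mean(phi)
  msd <- mean((phi_mean - phi)^2)
  phi_cv <- if (literal_cv) msd / phi_mean * 100 else sqrt(msd) / phi_mean * 100
  out <- tibble::tibble(
    pci = phi_cv + p_phi_abs,
    p_phi_abs = p_phi_abs,
    phi_cv = phi_cv,
    phi_mean = phi_mean,
    n_strides = length(phi)
  )
  attr(out, "phi_i") <- phi
  class(out) <- c("pci_result", class(out))
  out
}

#' Percentage of plantar pressure difference (PPD)
#'
#' Sums all sensor forces per foot over the whole trial and reports
#' \deqn{PPD = \frac{2\,|GRF_R - GRF_L|}{GRF_R + GRF_L} \times 100,}
#' the normalised absolute difference of the weights supported by the two
#' feet. Whole-trial sums make the index invariant to force rescaling and
#' robust to stride-count differences.
#'
#' @param trial A [grf_trial()].
#' @return One-row tibble of class `ppd_result`: `ppd`, `grf_sum_R`,
#'   `grf_sum_L`.
#' @export
compute_ppd <- function(trial) {
  stopifnot(inherits(trial, "grf_trial"))
  gR <- sum(as.matrix(tibble::as_tibble(trial)[paste0("R", 1:5)]))
  gL <- sum(as.matrix(tibble::as_tibble(trial)[paste0("L", 1:5)]))
  if (gR + gL <= 0) abort("zero total force: PPD undefined", class = "gaitpolar_undefined_index_error")
  out <- tibble::tibble(
    ppd = 2 * abs(gR - gL) / (gR + gL) * 100,
    grf_sum_R = gR,
    grf_sum_L = gL
  )
  class(out) <- c("ppd_result", class(out))
  out
}
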