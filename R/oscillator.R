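#' Adaptive-frequency-oscillator parameters
#'
#' The oscillator entrains a bank of harmonics to a quasi-periodic input
#' \eqn{u(t)}. With phases \eqn{\varphi_i}, amplitudes \eqn{\alpha_i}, offset
#' \eqn{\alpha_0} and fundamental frequency \eqn{\omega}, the dynamics are
#' \deqn{\dot\varphi_i = i\omega + k_\varphi e \cos\varphi_i, \quad
#'       \dot\omega = k_\omega e \cos\varphi_1, \quad
#'       \dot\alpha_i = k_\alpha e \sin\varphi_i, \quad
#'       \dot\alpha_0 = k_0 e,}
#' with reconstruction \eqn{\hat u = \alpha_0 + \sum_i \alpha_i \sin\varphi_i}
#' and error \eqn{e = u - \hat u}. The fundamental phase \eqn{\varphi_1},
#' wrapped to \eqn{[0, 2\pi)}, is the continuous gait phase.
#'
#' Two gain profiles are provided: `"healthy"` (0.8, 1.2, 0.6, 1.0) and
#' `"stroke"` (0.2, 0.2, 0.4, 0.8) — slower adaptation for less consistent
#' input. Gains depend on the insole hardware and should be tuned per setup.
#'
#' @param profile Gain preset, `"healthy"` or `"stroke"`.
#' @param k_phi,k_alpha,k_omega,k_0 Adaptation gains (override the profile).
#' @param order Number of harmonics (default 5).
#' @param omega_init Initial fundamental frequency (rad/s); default
#'   `2 * pi * 0.9`, a typical comfortable cadence.
#' @param dt Integration step (s); default `NULL` = use the input sampling
#'   interval.
#' @param omega_floor Lower clip for omega (rad/s), preventing transient sign
#'   flips of the frequency.
#' @return A list of class `ao_params`.
#' @export
ao_params <- function(profile = c("healthy", "stroke"),
                      k_phi = NULL, k_alpha = NULL, k_omega = NULL, k_0 = NULL,
                      order = 5L, omega_init = 2 * pi * 0.9, dt = NULL,
                      omega_floor = 0.1) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    healthy = c(0.8, 1.2, 0.6, 1.0),
    stroke = c(0.2, 0.2, 0.4, 0.8)
  )
  p <- list(
    profile = profile,
    k_phi = k_phi %||% preset[1],
    k_alpha = k_alpha %||% preset[2],
    k_omega = k_omega %||% preset[3],
    k_0 = k_0 %||% preset[4],
    order = as.integer(order),
    omega_init = omega_init,
    dt = dt,
    omega_floor = omega_floor
  )
  with(p, stopifnot(k_phi > 0, k_alpha > 0, k_omega > 0, k_0 > 0,
                    order >= 1L, omega_init > 0, omega_floor > 0))
  structure(p, class = "ao_params")
}

#' Initial oscillator state
#'
#' Phases, amplitudes and offset start at zero; omega starts at
#' `params$omega_init`.
#'
#' @param params An [ao_params()].
#' @return List of class `ao_state` with fields `phi`, `alpha`, `alpha0`,
#'   `omega`.
#' @export
ao_init <- function(params = ao_params()) {
  structure(
    list(phi = rep(0, params$order), alpha = rep(0, params$order),
         alpha0 = 0, omega = params$omega_init),
    class = "ao_state"
  )
}

#' One forward-Euler oscillator update
#'
#' Evaluates the reconstruction and error at the current state, then advances
#' all `2 * order + 2` state variables by one Euler step of length
#' `params$dt`. When the error is exactly zero, omega, the amplitudes and the
#' offset are unchanged and each phase advances by `i * omega * dt`.
#'
#' @param state An `ao_state`.
#' @param u_sample Input signal value at this step.
#' @param params An [ao_params()] with a non-`NULL` `dt`.
#' @return Updated `ao_state` with attributes `uhat` and `error` (the values
#'   used for this step).
#' @export
ao_step <- function(state, u_sample, params) {
  if (!is.finite(u_sample)) abort("non-finite oscillator input", class = "gaitpolar_numeric_error")
  dt <- params$dt
  if (is.null(dt)) abort("ao_step needs params$dt", class = "gaitpolar_format_error")
  i <- seq_len(params$order)
  sin_phi <- sin(state$phi)
  cos_phi <- cos(state$phi)
  uhat <- state$alpha0 + sum(state$alpha * sin_phi)
  e <- u_sample - uhat
  new <- state
  new$phi <- state$phi + dt * (i * state$omega + params$k_phi * e * cos_phi)
  new$omega <- max(params$omega_floor,
                   state$omega + dt * params$k_omega * e * cos_phi[1])
  new$alpha <- state$alpha + dt * params$k_alpha * e * sin_phi
  new$alpha0 <- state$alpha0 + dt * params$k_0 * e
  attr(new, "uhat") <- uhat
  attr(new, "error") <- e
  new
}

#' Continuous gait phase from a COPx series
#'
#' Runs the adaptive oscillator over the series and returns the wrapped
#' fundamental phase together with the omega, reconstruction and error
#' traces. For well-chosen gains the oscillator synchronises within a few
#' strides of walking.
#'
#' The adaptation gains are calibrated for unit-amplitude input, whereas
#' COPx is a percentage of order 100; the input is therefore standardised by
#' its robust amplitude (95th percentile of the absolute value) before
#' integration and the reconstruction/error traces are scaled back on
#' output. The phase and frequency are unaffected by the input units.
#'
#' @param cop A `copx_series` (from [compute_copx()]), or a numeric vector
#'   with `fs` supplied.
#' @param params An [ao_params()]; `dt` defaults to the sampling interval.
#' @param fs Sampling rate, only needed when `cop` is a bare numeric vector.
#' @return Tibble of class `gait_phase_series` with columns `t`, `phase`
#'   (\eqn{\varphi_1} in `[0, 2pi)`), `omega`, `uhat`, `error`; attributes
#'   `params` and `fs`. A warning of class `gaitpolar_convergence_warning` is
#'   issued if the error RMS keeps growing over the last quarter of the trial.
#' @export
estimate_phase <- function(cop, params = ao_params(), fs = NULL) {
  if (inherits(cop, "copx_series")) {
    u <- cop$copx
    t <- cop$t
    fs <- attr(cop, "fs")
  } else {
    u <- as.numeric(cop)
    if (is.null(fs)) abort("fs is required for a bare numeric input", class = "gaitpolar_format_error")
    t <- seq_along(u) / fs - 1 / fs
  }
  if (any(!is.finite(u))) abort("non-finite oscillator input", class = "gaitpolar_numeric_error")
  if (length(u) < 2 * fs) abort("need at least 2 s of signal", class = "gaitpolar_signal_error")
  # The adaptation gains are calibrated for unit-amplitude input; COPx is a
  # percentage (order 100), so standardise by the robust amplitude and scale
  # the reconstruction back afterwards. The phase is unaffected by units.
  scale <- quantile(abs(u), 0.95, names = FALSE)
  if (scale <= 0) scale <- 1
  u <- u / scale
  dt <- params$dt %||% (1 / fs)
  n <- length(u)
  ord <- params$order
  i <- seq_len(ord)
  k_phi <- params$k_phi; k_alpha <- params$k_alpha
  k_omega <- params$k_omega; k_0 <- params$k_0
  floor_w <- params$omega_floor
  phi <- rep(0, ord); alpha <- rep(0, ord); alpha0 <- 0; omega <- params$omega_init
  phase_out <- numeric(n); omega_out <- numeric(n)
  uhat_out <- numeric(n); err_out <- numeric(n)
  for (k in seq_len(n)) {
    sp <- sin(phi); cp <- cos(phi)
    uhat <- alpha0 + sum(alpha * sp)
    e <- u[k] - uhat
    phase_out[k] <- phi[1] %% (2 * pi)
    omega_out[k] <- omega
    uhat_out[k] <- uhat
    err_out[k] <- e
    phi <- phi + dt * (i * omega + k_phi * e * cp)
    omega <- max(floor_w, omega + dt * k_omega * e * cp[1])
    alpha <- alpha + dt * k_alpha * e * sp
    alpha0 <- alpha0 + dt * k_0 * e
  }
  q <- floor(n / 4)
  rms <- function(x) sqrt(mean(x^2))
  if (q >= 8) {
    late <- rms(err_out[(n - q + 1):n])
    mid <- rms(err_out[(n - 2 * q + 1):(n - q)])
    if (late > 2 * mid && late > rms(u)) {
      warn("oscillator error is growing over the last quarter of the trial",
           class = "gaitpolar_convergence_warning")
    }
  }
  structure(
    tibble::tibble(t = t, phase = phase_out, omega = omega_out,
                   uhat = uhat_out * scale, error = err_out * scale),
    class = c("gait_phase_series", class(tibble::tibble())),
    params = params, fs = fs, input_scale = scale
  )
}

#' Per-cycle phase-span statistics
#'
#' A gait cycle ends at each downward wrap of the fundamental phase; the
#' cycle's span is the last phase value before the wrap. Because the phase is
#' sampled discretely, spans fall slightly short of \eqn{2\pi} (by about half
#' a phase step on average); the summary therefore also reports the deficit
#' \eqn{2\pi - \mathrm{mean}}.
#'
#' @param phase A `gait_phase_series`.
#' @return List of class `cycle_phase_stats`: `spans` (rad, one per completed
#'   cycle), `mean`, `sd` (sample SD), `deficit` (\eqn{2\pi -} mean),
#'   `n_cycles`.
#' @export
cycle_phase_stats <- function(phase) {
  stopifnot(inherits(phase, "gait_phase_series"))
  p <- phase$phase
  wraps <- which(diff(p) < -pi)
  if (length(wraps) < 2) {
    abort("fewer than 2 phase wraps: not enough gait cycles", class = "gaitpolar_signal_error")
  }
  spans <- p[wraps[-1]]
  structure(
    list(spans = spans, mean = mean(spans), sd = sd(spans),
         deficit = 2 * pi - mean(spans), n_cycles = length(spans)),
    class = "cycle_phase_stats"
  )
}

#' @export
print.cycle_phase_stats <- function(x, ...) {
  cat(sprintf("<cycle_phase_stats> %d cycles, span %.3f +/- %.3f rad (2pi deficit %.3f)\n",
              x$n_cycles, x$mean, x$sd, x$deficit))
  invisible(x)
}
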