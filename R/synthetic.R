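#' Synthetic gait template
#'
#' Parameters of the seeded synthetic-gait generator. The generator emulates
#' level walking recorded by a five-sensor insole pair: per stance, the total
#' vertical force follows a double-bump (loading / push-off) profile,
#' distributed across the sensors with a piecewise heel-to-toe activation
#' progression, so the pooled signed COPx is a sinusoid-like alternating
#' waveform. Ground truth (heel-strike times, stance shares, stride time) is
#' returned alongside the signals.
#'
#' Defaults describe a comfortable healthy adult gait: 1.1 s stride, equal
#' stance duty, left step at mid-stride, each weight transfer (double
#' support) taking 10% of the stride, 1% force noise.
#'
#' @param stride_time Stride duration (s).
#' @param duty_R,duty_L Stance-time duty weights per foot; only their ratio
#'   matters — the right foot carries weight for a fraction
#'   `duty_R / (duty_R + duty_L)` of each stride.
#' @param left_offset_frac Left heel-strike time as a fraction of the stride
#'   (0.5 = ideally symmetric stepping).
#' @param amplitude_R,amplitude_L Peak total force per foot (body-weight
#'   units).
#' @param double_support_frac Duration of each weight transfer as a fraction
#'   of the stride.
#' @param noise_sd Gaussian noise SD added to every sensor channel, in units
#'   of the mean amplitude.
#' @param shuffle_prob Per-stride probability of an extra low-force heel tap
#'   shortly before the true left contact (the shuffling artefact that
#'   degrades event-based indices).
#' @param shuffle_magnitude Peak force of a shuffle tap (fraction of the
#'   amplitude).
#' @param n_strides Number of strides (>= 2).
#' @param seed RNG seed; the same template always regenerates an identical
#'   trial.
#' @return List of class `gait_template`.
#' @export
gait_template <- function(stride_time = 1.1, duty_R = 0.6, duty_L = 0.6,
                          left_offset_frac = 0.5,
                          amplitude_R = 1.0, amplitude_L = 1.0,
                          double_support_frac = 0.1, noise_sd = 0.01,
                          shuffle_prob = 0, shuffle_magnitude = 0.1,
                          n_strides = 20L, seed = 1L) {
  tpl <- list(stride_time = stride_time, duty_R = duty_R, duty_L = duty_L,
              left_offset_frac = left_offset_frac,
              amplitude_R = amplitude_R, amplitude_L = amplitude_L,
              double_support_frac = double_support_frac, noise_sd = noise_sd,
              shuffle_prob = shuffle_prob, shuffle_magnitude = shuffle_magnitude,
              n_strides = as.integer(n_strides), seed = as.integer(seed))
  with(tpl, stopifnot(stride_time > 0, duty_R > 0, duty_R < 1, duty_L > 0, duty_L < 1,
                      left_offset_frac > 0, left_offset_frac < 1,
                      amplitude_R > 0, amplitude_L > 0,
                      double_support_frac > 0, double_support_frac < 0.5,
                      noise_sd >= 0, shuffle_prob >= 0, shuffle_prob <= 1,
                      n_strides >= 2))
  structure(tpl, class = "gait_template")
}

# Stroke-like template: longer stride, stance time and load shifted to the
# (unaffected) right foot, delayed left step, noisier, with shuffling taps.
#' @rdname gait_template
#' @export
stroke_gait_template <- function(stride_time = 1.4, duty_R = 0.66, duty_L = 0.47,
                                 left_offset_frac = 0.58,
                                 amplitude_R = 1.15, amplitude_L = 0.885,
                                 double_support_frac = 0.12, noise_sd = 0.02,
                                 shuffle_prob = 0.15, shuffle_magnitude = 0.1,
                                 n_strides = 20L, seed = 1L) {
  gait_template(stride_time, duty_R, duty_L, left_offset_frac,
                amplitude_R, amplitude_L, double_support_frac, noise_sd,
                shuffle_prob, shuffle_magnitude, n_strides, seed)
}

# raised-cosine ramp from 0 to 1 over [0, 1]
rc_ramp <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))

# M-shaped mid-stance profile: loading and push-off peaks with a mid-stance
# valley, equal to 1 at both ends so the transfer ramps (raised cosines over
# the double-support window) fully determine the force hand-over.
stance_shape <- function(u) 1 + 0.15 * sin(2 * pi * u)^2 - 0.25 * sin(pi * u)^2

# piecewise-linear heel -> cuboid/5th-met -> 1st-met -> toe activation;
# windows are mirror-symmetric about mid-stance so the within-stance COP
# sweep is time-symmetric (idealised sinusoid-like pooled COPx)
sensor_weights <- function(s) {
  tri <- function(s, a, b, c) pmax(0, pmin((s - a) / (b - a), (c - s) / (c - b)))
  w <- cbind(
    big_toe = tri(s, 0.55, 0.90, 1.25),
    met1 = tri(s, 0.35, 0.65, 0.92),
    met5 = tri(s, 0.20, 0.50, 0.80),
    cuboid = tri(s, 0.08, 0.35, 0.65),
    heel = tri(s, -0.25, 0.10, 0.45)
  )
  sw <- rowSums(w)
  sw[sw == 0] <- 1
  w / sw
}

#' Generate a synthetic GRF trial with ground truth
#'
#' Builds the continuous per-foot force profiles implied by the template,
#' samples them at `fs`, distributes each foot's force over its five sensors
#' and adds noise and optional shuffle taps. Weight transfers are centred at
#' the stance-share boundary (or at the late left contact when
#' `left_offset_frac` pushes the left step past it), with congruent
#' raised-cosine ramps on both sides, so the time the pooled COPx spends
#' positive per stride equals the right-foot stance share.
#'
#' @param template A [gait_template()].
#' @param layout A [sensor_layout()].
#' @param fs Sampling rate (Hz, >= 20 so double support is resolved).
#' @return List with `trial` (a [grf_trial()]) and `truth`: tibble-free list
#'   of true right/left heel-strike times, stance shares, stride time and
#'   the template.
#' @export
generate_trial <- function(template = gait_template(), layout = default_sensor_layout(),
                           fs = 100) {
  stopifnot(inherits(template, "gait_template"))
  if (fs < 20) abort("fs below 20 Hz cannot resolve double support", class = "gaitpolar_format_error")
  tp <- template
  T <- tp$stride_time
  ds <- tp$double_support_frac * T
  share_R <- tp$duty_R / (tp$duty_R + tp$duty_L)
  q <- tp$left_offset_frac
  # weight hand-over R->L starts at the stance-share boundary, or at the left
  # contact when the left step is later than that boundary; hand-over L->R
  # starts at each right contact (stride start). Both hand-overs are
  # congruent raised-cosine cross-fades of length ds.
  c1 <- max(share_R, q) * T
  n <- ceiling((tp$n_strides * T + 2 * ds) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  A_mean <- (tp$amplitude_R + tp$amplitude_L) / 2
  withr::with_seed(tp$seed, {
    FR <- numeric(n); FL <- numeric(n)
    sR <- rep(NA_real_, n); sL <- rep(NA_real_, n)
    t_R_true <- numeric(0); t_L_true <- numeric(0)
    for (k in 0:(tp$n_strides - 1L)) {
      t0 <- k * T
      # right stance: contact at t0, loaded until the R->L hand-over ends
      r_on <- t0; r_off <- t0 + c1 + ds
      t_R_true <- c(t_R_true, r_on)
      in_r <- which(t >= r_on & t <= r_off)
      u <- (t[in_r] - r_on) / (r_off - r_on)
      env <- stance_shape(u) * rc_ramp((t[in_r] - r_on) / ds) *
        (1 - rc_ramp((t[in_r] - (r_off - ds)) / ds))
      sR[in_r] <- ifelse(is.na(sR[in_r]) | env > FR[in_r] / tp$amplitude_R, u, sR[in_r])
      FR[in_r] <- pmax(FR[in_r], tp$amplitude_R * env)
      # left stance: contact at t0 + qT; full load from the hand-over window,
      # capped onset-congruent pre-load while waiting for it
      l_contact <- t0 + q * T
      l_main_on <- t0 + c1
      l_off <- t0 + T + ds
      t_L_true <- c(t_L_true, l_contact)
      in_l <- which(t >= l_contact & t <= l_off)
      # roll-over progress runs from weight acceptance (not first contact):
      # during a light pre-contact the foot stays heel-loaded
      u <- pmax(0, t[in_l] - l_main_on) / (l_off - l_main_on)
      main <- stance_shape(u) * rc_ramp((t[in_l] - l_main_on) / ds) *
        (1 - rc_ramp((t[in_l] - (l_off - ds)) / ds))
      # contact tap: onset-congruent rise (so detection delay matches the
      # right foot), peaking at 8% of amplitude, settling to a 1.5% resting
      # load until the weight hand-over starts
      tau <- t[in_l] - l_contact
      pre_cap <- pmax(0.015, 0.08 - 0.065 * rc_ramp((tau - 0.25 * ds) / (0.75 * ds)))
      pre <- pmin(stance_shape(u) * rc_ramp(tau / ds), pre_cap)
      env <- pmax(main, pre)
      sL[in_l] <- ifelse(is.na(sL[in_l]) | env > FL[in_l] / tp$amplitude_L, u, sL[in_l])
      FL[in_l] <- pmax(FL[in_l], tp$amplitude_L * env)
      # shuffle artefact: brief low-force left-heel tap before true contact
      if (tp$shuffle_prob > 0 && stats::runif(1) < tp$shuffle_prob) {
        tap_t <- l_contact - stats::runif(1, 0.10, 0.20) * T
        in_tap <- which(t >= tap_t & t <= tap_t + 0.06)
        FL[in_tap] <- pmax(FL[in_tap],
                           tp$shuffle_magnitude * A_mean * sin(pi * (t[in_tap] - tap_t) / 0.06))
        sL[in_tap] <- ifelse(is.na(sL[in_tap]), 0, sL[in_tap])
      }
    }
    sR[is.na(sR)] <- 0; sL[is.na(sL)] <- 0
    WR <- sensor_weights(sR) * FR
    WL <- sensor_weights(sL) * FL
    if (tp$noise_sd > 0) {
      WR <- WR + matrix(stats::rnorm(n * 5, 0, tp$noise_sd * A_mean), n, 5)
      WL <- WL + matrix(stats::rnorm(n * 5, 0, tp$noise_sd * A_mean), n, 5)
    }
    WR[WR < 0] <- 0
    WL[WL < 0] <- 0
  })
  # order sensor columns as the layout labels (columns built in label order)
  df <- tibble::as_tibble(cbind(time = t, WR, WL), .name_repair = "minimal")
  names(df) <- trial_columns()
  trial <- grf_trial(df, fs = fs)
  list(
    trial = trial,
    truth = list(
      t_R = t_R_true, t_L = t_L_true,
      share_R = share_R,
      pos_frac = max(share_R, q),
      stride_time = T,
      stance_R = c1 + ds,
      stance_L = T + ds - q * T,
      template = tp
    )
  )
}

#' Generate a two-group synthetic cohort
#'
#' Per-subject templates are jittered copies of the healthy and stroke-like
#' base templates (log-normal jitter on stride time, duty weights and
#' amplitudes; additive jitter on the left step offset), each with its own
#' derived seed, so the whole cohort is reproducible from one seed.
#'
#' @param healthy_template,stroke_template Base templates.
#' @param n_healthy,n_stroke Subjects per group (>= 2).
#' @param seed Cohort seed.
#' @param layout,fs Passed to [generate_trial()].
#' @return Tibble with columns `subject_id`, `group`, `trial` (list),
#'   `truth` (list).
#' @export
generate_cohort <- function(healthy_template = gait_template(),
                            stroke_template = stroke_gait_template(),
                            n_healthy = 8L, n_stroke = 4L, seed = 1L,
                            layout = default_sensor_layout(), fs = 100) {
  if (n_healthy < 2 || n_stroke < 2) {
    abort("need at least 2 subjects per group", class = "gaitpolar_format_error")
  }
  groups <- c(rep("healthy", n_healthy), rep("stroke", n_stroke))
  base <- c(rep(list(healthy_template), n_healthy), rep(list(stroke_template), n_stroke))
  jit <- withr::with_seed(seed, {
    purrr::map(seq_along(groups), function(i) {
      list(lt = exp(stats::rnorm(1, 0, 0.03)),
           ldr = exp(stats::rnorm(1, 0, 0.02)), ldl = exp(stats::rnorm(1, 0, 0.02)),
           lar = exp(stats::rnorm(1, 0, 0.04)), lal = exp(stats::rnorm(1, 0, 0.04)),
           dq = stats::rnorm(1, 0, 0.01),
           sub_seed = sample.int(2^31 - 1, 1))
    })
  })
  rows <- purrr::map(seq_along(groups), function(i) {
    b <- base[[i]]; j <- jit[[i]]
    tpl <- gait_template(
      stride_time = b$stride_time * j$lt,
      duty_R = b$duty_R * j$ldr, duty_L = b$duty_L * j$ldl,
      left_offset_frac = min(0.9, max(0.1, b$left_offset_frac + j$dq)),
      amplitude_R = b$amplitude_R * j$lar, amplitude_L = b$amplitude_L * j$lal,
      double_support_frac = b$double_support_frac, noise_sd = b$noise_sd,
      shuffle_prob = b$shuffle_prob, shuffle_magnitude = b$shuffle_magnitude,
      n_strides = b$n_strides, seed = j$sub_seed
    )
    g <- generate_trial(tpl, layout = layout, fs = fs)
    g$trial <- set_trial_attrs(g$trial, fs = fs,
                               subject_id = sprintf("S%02d", i), group = groups[i])
    tibble::tibble(subject_id = sprintf("S%02d", i), group = groups[i],
                   trial = list(g$trial), truth = list(g$truth))
  })
  dplyr::bind_rows(rows)
}
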