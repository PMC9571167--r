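test_that("zero-error input is an exact fixed point of the adaptation laws", {
  p <- ao_params(dt = 0.01)
  st <- ao_init(p)
  st$alpha <- c(0.5, 0.2, 0.1, 0.05, 0.02)
  st$alpha0 <- 0.3
  st$omega <- 5
  st$phi <- c(0.3, 0.6, 0.9, 1.2, 1.5)
  u <- st$alpha0 + sum(st$alpha * sin(st$phi)) # makes e exactly 0
  new <- ao_step(st, u, p)
  expect_identical(attr(new, "error"), 0)
  expect_equal(new$omega, st$omega)
  expect_equal(new$alpha, st$alpha)
  expect_equal(new$alpha0, st$alpha0)
  expect_equal(new$phi, st$phi + (1:5) * st$omega * p$dt)
})

test_that("one step with nonzero error matches an independent Euler update", {
  p <- ao_params(k_phi = 0.8, k_alpha = 1.2, k_omega = 0.6, k_0 = 1.0, dt = 0.01)
  st <- ao_init(p)
  st$alpha <- c(0.4, -0.1, 0.2, 0, 0.05)
  st$alpha0 <- -0.2
  st$omega <- 6
  st$phi <- c(1.1, 2.2, 3.3, 4.4, 5.5)
  u <- 0.7
  new <- ao_step(st, u, p)
  # independent hand-coded update
  e <- u - (st$alpha0 + sum(st$alpha * sin(st$phi)))
  expect_equal(attr(new, "error"), e)
  expect_equal(new$phi, st$phi + 0.01 * ((1:5) * st$omega + 0.8 * e * cos(st$phi)))
  expect_equal(new$omega, st$omega + 0.01 * 0.6 * e * cos(st$phi[1]))
  expect_equal(new$alpha, st$alpha + 0.01 * 1.2 * e * sin(st$phi))
  expect_equal(new$alpha0, st$alpha0 + 0.01 * 1.0 * e)
  expect_error(ao_step(st, NaN, p), class = "gaitpolar_numeric_error")
})

test_that("the offset state absorbs a constant input", {
  u <- rep(0.8, 1000)
  ph <- estimate_phase(u, ao_params(), fs = 100)
  # alpha0 tracks the constant, so the residual error vanishes
  expect_lt(abs(tail(ph$error, 1)), 0.01 * 0.8)
})

test_that("zero input leaves omega at its initial value with a linear phase ramp", {
  p <- ao_params()
  ph <- estimate_phase(rep(0, 500), p, fs = 100)
  expect_equal(unique(ph$omega), p$omega_init)
  dphi <- diff(ph$phase)
  dphi <- dphi[dphi > 0]
  expect_equal(unique(round(dphi, 12)), round(p$omega_init * 0.01, 12))
})

test_that("the oscillator recovers the frequency of pure sinusoids (10 seeds)", {
  fs <- 100
  t <- seq(0, 160, by = 1 / fs)
  set.seed(202)
  fr <- runif(10, 0.5, 1.5)
  phs <- runif(10, 0, 2 * pi)
  for (i in seq_along(fr)) {
    ph <- estimate_phase(sin(2 * pi * fr[i] * t + phs[i]), ao_params(), fs = fs)
    expect_lt(abs(tail(ph$omega, 1) - 2 * pi * fr[i]) / (2 * pi * fr[i]), 0.05,
              label = sprintf("relative omega error at f=%.3f Hz", fr[i]))
  }
})

test_that("halving the integration step changes terminal omega by under 1%", {
  fs <- 100
  t1 <- seq(0, 30, by = 1 / fs)
  u1 <- sin(2 * pi * 1.1 * t1)
  w1 <- tail(estimate_phase(u1, ao_params(), fs = fs)$omega, 1)
  t2 <- seq(0, 30, by = 1 / (2 * fs))
  u2 <- sin(2 * pi * 1.1 * t2) # interpolated input = exact resample here
  w2 <- tail(estimate_phase(u2, ao_params(), fs = 2 * fs)$omega, 1)
  expect_lt(abs(w1 - w2) / w2, 0.01)
})

test_that("synthetic gait stride time is recovered across the cadence range", {
  for (T in c(0.8, 1.2, 1.6)) {
    g <- generate_trial(gait_template(stride_time = T, n_strides = ceiling(40 / T), seed = 17))
    cop <- compute_copx(g$trial)
    ph <- estimate_phase(cop)
    expect_lt(abs(2 * pi / tail(ph$omega, 1) - T) / T, 0.05,
              label = sprintf("stride time %.1f s", T))
  }
})

test_that("cycle spans sit just below 2*pi and insufficient cycles error", {
  g <- generate_trial(gait_template(n_strides = 30, seed = 23))
  cop <- compute_copx(g$trial)
  ph <- estimate_phase(cop)
  cs <- cycle_phase_stats(ph)
  expect_lt(cs$deficit, 0.1)
  expect_gt(cs$mean, 2 * pi - 0.1)
  expect_lte(max(cs$spans), 2 * pi)
  short <- ph[1:150, ]
  class(short) <- class(ph)
  expect_error(cycle_phase_stats(short), class = "gaitpolar_signal_error")
})

test_that("group phase-span statistics reproduce the reference table", {
  tab <- gait_phase_table()
  h <- tab$phase_mean[tab$group == "healthy"]
  s <- tab$phase_mean[tab$group == "stroke"]
  expect_equal(round(mean(h), 3), 6.275)
  expect_equal(round(sd(h), 3), 0.004)
  expect_equal(round(mean(s), 3), 6.262)
  expect_equal(round(sd(s), 3), 0.009)
  expect_lt(abs((2 * pi - mean(h)) - 0.008), 1e-3)
  expect_lt(abs((2 * pi - mean(s)) - 0.021), 1e-3)
})
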