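test_that("heel strikes are recovered at generator-truth times on clean trials", {
  g <- generate_trial(gait_template(n_strides = 10, seed = 3, noise_sd = 0))
  hs <- detect_heel_strikes(g$trial)
  expect_length(hs$t_R, 10)
  expect_length(hs$t_L, 10)
  # constant detection latency on both feet (cancels in interval-based indices)
  lag_R <- hs$t_R - g$truth$t_R
  lag_L <- hs$t_L - g$truth$t_L
  expect_lt(max(abs(lag_R - lag_R[1])), 1.5 / 100) # within a sample of constant
  expect_lt(max(abs(lag_L - lag_R[1])), 1.5 / 100)
  expect_lt(max(lag_R), 0.05)
})

test_that("square-pulse heel forces give exact onsets; silent channels error", {
  df <- make_trial(600)
  onsets <- c(50, 250, 450) # sample indices
  for (o in onsets) df$R5[o:(o + 30)] <- 10
  df$L5[c(150:180, 350:380)] <- 10
  tr <- grf_trial(df)
  hs <- detect_heel_strikes(tr)
  expect_equal(hs$t_R, (onsets - 1) / 100)
  expect_equal(hs$t_L, c(149, 349) / 100)
  expect_error(detect_heel_strikes(grf_trial(make_trial(600))),
               class = "gaitpolar_detection_error")
})

test_that("PCI matches hand-evaluated stepping phases", {
  # ideal symmetry: all phi = pi, PCI = 0
  r0 <- compute_pci(list(t_R = c(0, 1, 2), t_L = c(0.5, 1.5)))
  expect_equal(attr(r0, "phi_i"), c(pi, pi))
  expect_equal(r0$pci, 0)
  # constant 0.6 offset: phi = 1.2*pi, P_phi_ABS = 20, CV = 0, PCI = 20
  r1 <- compute_pci(list(t_R = c(0, 1, 2), t_L = c(0.6, 1.6)))
  expect_equal(attr(r1, "phi_i"), c(1.2 * pi, 1.2 * pi))
  expect_equal(r1$p_phi_abs, 20, tolerance = 1e-12)
  expect_equal(r1$phi_cv, 0)
  expect_equal(r1$pci, 20, tolerance = 1e-12)
  # literal (no square root) dispersion variant
  ev <- list(t_R = c(0, 1, 2, 3), t_L = c(0.5, 1.6, 2.5))
  std <- compute_pci(ev)
  lit <- compute_pci(ev, literal_cv = TRUE)
  phi <- attr(std, "phi_i")
  msd <- mean((mean(phi) - phi)^2)
  expect_equal(std$phi_cv, sqrt(msd) / mean(phi) * 100)
  expect_equal(lit$phi_cv, msd / mean(phi) * 100)
})

test_that("PCI is invariant to time shift and scale; unpairable strikes are dropped", {
  ev <- list(t_R = c(0, 1.1, 2.1, 3.3), t_L = c(0.6, 1.7, 2.6))
  a <- compute_pci(ev)
  b <- compute_pci(list(t_R = ev$t_R * 3 + 7, t_L = ev$t_L * 3 + 7))
  expect_equal(a$pci, b$pci, tolerance = 1e-12)
  expect_warning(
    d <- compute_pci(list(t_R = c(0, 1, 2, 3), t_L = c(0.5, 1.4, 1.6, 2.5))),
    class = "gaitpolar_pairing_warning"
  )
  expect_equal(d$n_strides, 2L)
  expect_error(compute_pci(list(t_R = 1, t_L = numeric(0))),
               class = "gaitpolar_pairing_error")
})

test_that("left-step offset is recovered as P_phi_ABS within 1 point (10 seeds each)", {
  for (q in c(0.5, 0.55, 0.6)) {
    target <- 100 * abs(2 * q - 1)
    got <- vapply(1:10, function(s) {
      g <- generate_trial(gait_template(left_offset_frac = q, n_strides = 25, seed = s))
      compute_pci(detect_heel_strikes(g$trial))$p_phi_abs
    }, numeric(1))
    expect_true(all(abs(got - target) <= 1),
                label = sprintf("P_phi_ABS within 1 point of %.0f for q=%.2f", target, q))
  }
})

test_that("PPD matches the closed form and its invariances", {
  df <- make_trial(100)
  df$R1 <- 3
  df$L1 <- 1
  r <- compute_ppd(grf_trial(df))
  expect_equal(r$ppd, 100) # 2|3-1|/(3+1)*100
  df$L1 <- 3
  expect_equal(compute_ppd(grf_trial(df))$ppd, 0)
  # scale invariance and foot-swap symmetry
  g <- generate_trial(gait_template(amplitude_R = 1.2, n_strides = 8, seed = 2))
  p1 <- compute_ppd(g$trial)
  scaled <- tibble::as_tibble(g$trial)
  scaled[-1] <- scaled[-1] * 2.5
  expect_equal(compute_ppd(grf_trial(scaled))$ppd, p1$ppd, tolerance = 1e-12)
  sw <- tibble::as_tibble(g$trial)[c("time", paste0("L", 1:5), paste0("R", 1:5))]
  names(sw) <- c("time", paste0("R", 1:5), paste0("L", 1:5))
  expect_equal(compute_ppd(grf_trial(sw))$ppd, p1$ppd, tolerance = 1e-12)
  expect_error(compute_ppd(grf_trial(make_trial(50)) ), class = "gaitpolar_undefined_index_error")
})
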