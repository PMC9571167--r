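test_that("polar area matches closed forms and refines to the analytic value", {
  # constant radius c over span pi: area = c^2 * pi / 2
  th <- seq(0, pi, length.out = 2001)
  expect_equal(closed_area(th, rep(3, length(th))), 0.5 * 9 * pi, tolerance = 1e-12)
  # r = sin(theta) on (0, pi): area -> pi/4
  expect_equal(closed_area(th, sin(th)), pi / 4, tolerance = 1e-3 * pi / 4)
  expect_error(closed_area(c(0, 1), c(1, 1)), class = "gaitpolar_format_error")
  expect_error(closed_area(c(0, 0.5, 0.2), c(1, 1, 1)), class = "gaitpolar_geometry_error")
  # literal variant carries the extra theta factor: int 1/2 c^2 theta dtheta
  expect_equal(closed_area(th, rep(1, length(th)), literal = TRUE),
               0.25 * pi^2, tolerance = 1e-6)
})

test_that("polar area agrees with the Cartesian shoelace oracle on random star curves", {
  set.seed(77)
  for (i in 1:20) {
    span <- runif(1, 1.5, pi)
    th0 <- runif(1, 0, pi)
    th <- seq(th0, th0 + span, length.out = 120)
    # random smooth positive radius (star-shaped about the origin)
    a <- runif(3, 0, 1)
    r <- 2 + a[1] * sin(2 * th) + a[2] * cos(3 * th) + a[3] * sin(th)
    expect_equal(closed_area(th, r), shoelace_area(th, r),
                 tolerance = 0.01, label = paste("curve", i))
  }
})

test_that("area ratios always sum to 100 and reproduce hand arithmetic", {
  expect_equal(area_ratio_index(1, 1)$ARI, 0)
  r <- area_ratio_index(3, 1)
  expect_equal(c(r$arearatio_R, r$arearatio_L, r$ARI), c(75, 25, 50))
  set.seed(5)
  for (i in 1:25) {
    ab <- runif(2, 0, 10)
    rr <- area_ratio_index(ab[1], ab[2])
    expect_equal(rr$arearatio_R + rr$arearatio_L, 100, tolerance = 1e-12)
  }
  expect_error(area_ratio_index(0, 0), class = "gaitpolar_undefined_index_error")
})

test_that("disorder bounds and side classification follow the threshold rule", {
  expect_equal(arearatio_disorder_bounds(10), c(lower = 45, upper = 55))
  # area ratio 60.9/39.1 (left below 45) -> disorder, left side affected
  c1 <- classify_disorder(tibble::tibble(arearatio_R = 60.9, arearatio_L = 39.1, ARI = 21.8))
  expect_equal(c1$verdict, "disorder")
  expect_equal(c1$affected_side, "left")
  # 36.0/64.0 -> right affected
  c2 <- classify_disorder(tibble::tibble(arearatio_R = 36, arearatio_L = 64, ARI = 28))
  expect_equal(c2$affected_side, "right")
  # symmetric -> normal
  c3 <- classify_disorder(tibble::tibble(arearatio_R = 50, arearatio_L = 50, ARI = 0))
  expect_equal(c3$verdict, "normal")
  expect_equal(c3$affected_side, "none")
})

test_that("tangent angle handles both conventions", {
  # zero numerator in the printed form
  expect_equal(tangent_angle(c(2, 1.0), c(1, 1.0), mode = "as-printed"), 0)
  # hand evaluation: |atan2(1 - 4, 2 - 1)| = 1.249...
  expect_equal(tangent_angle(c(2, 1.0), c(1, 4.0), mode = "as-printed"),
               abs(atan2(-3, 1)), tolerance = 1e-12)
  expect_equal(round(tangent_angle(c(2, 1.0), c(1, 4.0), mode = "as-printed"), 3), 1.249)
  # mirror-symmetric transfer points on the horizontal axis -> angle 0
  expect_equal(tangent_angle(c(2, pi), c(2, 0), mode = "cartesian"), 0, tolerance = 1e-12)
  # constructed geometry: points at (0, 1) and (0, -1) give a vertical chord
  expect_equal(tangent_angle(c(1, pi / 2), c(1, 3 * pi / 2), mode = "cartesian"),
               pi / 2, tolerance = 1e-12)
  expect_error(tangent_angle(c(1, 2), c(1, 2)), class = "gaitpolar_undefined_slope_error")
})

test_that("gaitogram construction keeps complete cycles with alternating sides", {
  g <- generate_trial(gait_template(n_strides = 10, seed = 31))
  cop <- compute_copx(g$trial)
  ph <- estimate_phase(cop)
  gg <- build_gaitogram(ph, cop, warmup_cycles = 0)
  expect_gte(attr(gg, "n_cycles"), 8)
  expect_lte(attr(gg, "n_cycles"), 10)
  # each cycle contains both sides and non-decreasing theta
  by_cycle <- split(as.data.frame(gg), gg$cycle)
  for (cy in by_cycle) {
    expect_setequal(unique(cy$side), c("R", "L"))
    expect_true(all(diff(cy$theta) >= 0))
  }
  expect_true(all(gg$r >= 0))
  short <- ph[1:120, ]
  class(short) <- class(ph)
  cop_s <- cop[1:120, ]
  class(cop_s) <- class(cop)
  expect_error(build_gaitogram(short, cop_s), class = "gaitpolar_signal_error")
})

test_that("an all-zero COPx series yields a degenerate gaitogram and undefined indices", {
  zero <- structure(tibble::tibble(t = seq(0, 9.99, by = 0.01), copx = 0, valid = TRUE),
                    class = c("copx_series", class(tibble::tibble())), fs = 100)
  ph <- estimate_phase(zero)
  gg <- build_gaitogram(ph, zero)
  expect_true(all(gg$r == 0))
  expect_error(gaitogram_indices(gg, ph, zero), class = "gaitpolar_undefined_index_error")
})

test_that("swapping feet swaps the closed-curve areas and preserves ARI", {
  g <- generate_trial(gait_template(duty_R = 0.72, duty_L = 0.6, n_strides = 15, seed = 13))
  cop <- compute_copx(g$trial)
  ph <- estimate_phase(cop)
  idx <- gaitogram_indices(build_gaitogram(ph, cop), ph, cop)
  # mirrored trial: negated COPx by construction
  tr <- tibble::as_tibble(g$trial)[c("time", paste0("L", 1:5), paste0("R", 1:5))]
  names(tr) <- c("time", paste0("R", 1:5), paste0("L", 1:5))
  cop_m <- compute_copx(grf_trial(tr))
  ph_m <- estimate_phase(cop_m)
  idx_m <- gaitogram_indices(build_gaitogram(ph_m, cop_m), ph_m, cop_m)
  expect_equal(idx_m$arearatio_R, idx$arearatio_L, tolerance = 0.02 * 100)
  expect_equal(idx_m$ARI, idx$ARI, tolerance = 2)
})

test_that("stance-duty ratio is recovered as an area-ratio share (10 seeds each)", {
  for (rho in c(1.0, 1.2, 1.5)) {
    target <- 100 * rho / (1 + rho)
    got <- vapply(1:10, function(s) {
      g <- generate_trial(gait_template(duty_R = 0.6 * rho, duty_L = 0.6,
                                        n_strides = 25, seed = s))
      cop <- compute_copx(g$trial)
      ph <- estimate_phase(cop)
      gaitogram_indices(build_gaitogram(ph, cop), ph, cop)$arearatio_R
    }, numeric(1))
    expect_true(all(abs(got - target) <= 2),
                label = sprintf("arearatio_R within 2 points of %.1f for rho=%.1f", target, rho))
  }
})
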