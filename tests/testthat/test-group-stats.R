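tab <- gait_index_table()

test_that("group summaries reproduce the reference average rows at printed rounding", {
  s <- summarize_group(tab)
  get <- function(g, ix, what) s[[what]][s$group == g & s$index == ix]
  # printed values are rounded to 1 dp (ratios, ARI) / 2 dp (others); agree
  # within half a unit in the last printed place
  printed <- list(
    healthy = list(arearatio_R = c(50.0, 2.0), arearatio_L = c(50.0, 2.0),
                   ARI = c(2.9, 2.6), ang_tangent = c(0.07, 0.05),
                   ppd = c(7.77, 1.51), pci = c(9.26, 2.68)),
    stroke = list(arearatio_R = c(54.0, 12.4), arearatio_L = c(46.0, 12.4),
                  ARI = c(22.1, 7.1), ang_tangent = c(0.26, 0.11),
                  ppd = c(22.71, 10.15), pci = c(13.81, 0.59))
  )
  half_ulp <- c(arearatio_R = 0.05, arearatio_L = 0.05, ARI = 0.05,
                ang_tangent = 0.005, ppd = 0.005, pci = 0.005)
  for (g in names(printed)) {
    for (ix in names(printed[[g]])) {
      expect_lte(abs(get(g, ix, "mean") - printed[[g]][[ix]][1]), half_ulp[[ix]] + 1e-9,
                 label = sprintf("%s %s mean", g, ix))
      expect_lte(abs(get(g, ix, "sd") - printed[[g]][[ix]][2]), half_ulp[[ix]] + 1e-9,
                 label = sprintf("%s %s sd", g, ix))
    }
  }
  expect_equal(get("healthy", "ARI", "label"), "2.9 ± 2.6")
  expect_equal(get("stroke", "ARI", "label"), "22.1 ± 7.1")
})

test_that("summaries handle degenerate input", {
  rep2 <- tibble::tibble(subject_id = 1:3, group = "healthy", ARI = c(4, 4, 4))
  s <- summarize_group(rep2)
  expect_equal(s$sd, 0)
  expect_error(summarize_group(rep2[1, ]), class = "gaitpolar_format_error")
  expect_error(summarize_group(tibble::tibble(group = c("a", "b"), x = 1:2)),
               class = "gaitpolar_format_error")
})

test_that("exact Mann-Whitney matches known small-sample results", {
  h <- tab$ARI[tab$group == "healthy"]
  s <- tab$ARI[tab$group == "stroke"]
  mw <- mann_whitney_exact(s, h)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p_value, 2 / choose(12, 4), tolerance = 1e-12) # 0.004
  expect_equal(round(mw$p_value, 3), 0.004)
  pci <- mann_whitney_exact(tab$pci[tab$group == "stroke"], tab$pci[tab$group == "healthy"])
  expect_equal(pci$p_value, 4 / choose(12, 4), tolerance = 1e-12) # 0.008
  # identical samples: no evidence of a shift (p at or near 1)
  same <- mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  expect_lte(same$p_value, 1)
  expect_error(mann_whitney_exact(numeric(0), 1:3), class = "gaitpolar_format_error")
})

test_that("exact p equals the brute-force enumeration oracle on random instances", {
  set.seed(99)
  for (i in 1:50) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- round(runif(n1), 6)
    y <- round(runif(n2), 6)
    if (any(duplicated(c(x, y)))) next
    got <- mann_whitney_exact(x, y)$p_value
    expect_equal(got, mw_enum_oracle(x, y), tolerance = 1e-10,
                 label = sprintf("instance %d (n1=%d, n2=%d)", i, n1, n2))
  }
  # and agrees with the standard exact Wilcoxon test
  w <- stats::wilcox.test(c(5, 6, 9), c(1, 2, 3), exact = TRUE)
  expect_equal(mann_whitney_exact(c(5, 6, 9), c(1, 2, 3))$p_value, w$p.value)
})

test_that("ties fall back to the midrank normal approximation", {
  x <- c(1, 2, 2, 5)
  y <- c(2, 3, 6, 7)
  mw <- mann_whitney_exact(x, y)
  expect_equal(mw$method, "normal")
  expect_gt(mw$p_value, 0)
  expect_lte(mw$p_value, 1)
})

test_that("group comparison reproduces separation structure and the ARI ratio", {
  cmp <- compare_groups(tab)
  tests <- tidy(cmp)
  ari <- tests[tests$index == "ARI", ]
  expect_true(ari$separated) # 6.9 < 10 < 12.2
  expect_equal(ari$healthy_max, 6.9)
  expect_equal(ari$stroke_min, 12.2)
  expect_false(tests$separated[tests$index == "pci"]) # 13.18 > 12.97 overlap
  expect_true(tests$separated[tests$index == "ppd"]) # 9.09 < 10 < 11.05
  expect_true(tests$separated[tests$index == "ang_tangent"]) # 0.14 < 0.155 < 0.17
  g <- glance(cmp)
  expect_equal(round(g$ari_mean_ratio, 1), 7.6)
  expect_equal(round(g$p_ari, 3), 0.004)
  expect_equal(round(g$p_pci, 3), 0.008)
  expect_error(compare_groups(tab[tab$group == "healthy", ]),
               class = "gaitpolar_format_error")
})
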