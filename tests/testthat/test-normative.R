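test_that("a constant outcome gives zero GA coefficients and zero R-squared", {
  g <- fit_growth_curve(seq(20, 40, length.out = 10), rep(5, 10))
  expect_equal(unname(g$coefficients[-1]), c(0, 0))
  expect_true(is.na(g$p_value))
  expect_equal(g$r_squared, 0)
})

test_that("an exact quadratic is recovered to 1e-8 with R-squared 1", {
  ga <- seq(20, 40, length.out = 25)
  y <- 410 - 2.3 * ga - 0.11 * ga^2
  g <- suppressWarnings(fit_growth_curve(ga, y))  # lm warns on perfect fits
  expect_equal(unname(g$coefficients), c(410, -2.3, -0.11), tolerance = 1e-8)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_growth_curve(ga[1:3], y[1:3]), "observations")
})

test_that("percentile table cells honour quantile conventions and edge cases", {
  rec <- data.frame(scan_id = 1:3, ga = c(20.5, 21, 21.5),
                    region = "white_matter",
                    mean_t2star_ms = c(100, 200, 300))
  tab <- make_percentile_table(rec)
  row <- tab[tab$bin_start == 20, ]
  expect_equal(row$p50, 200)
  expect_equal(row$mean, 200)
  expect_equal(row$n, 3L)
  # all-identical values collapse every statistic
  rec$mean_t2star_ms <- 7
  tab2 <- make_percentile_table(rec)
  row2 <- tab2[tab2$bin_start == 20, ]
  expect_equal(unlist(row2[c("mean", "p5", "p50", "p95")]),
               c(mean = 7, p5 = 7, p50 = 7, p95 = 7))
  # empty bins are emitted with n = 0 and undefined statistics
  empty <- tab[tab$bin_start == 30, ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("quantile ordering p5 <= p50 <= p95 holds on noisy cohorts", {
  for (seed in 1:3) {
    tab <- make_percentile_table(simulate_regional_cohort(seed = seed))
    ok <- tab$n > 0
    expect_true(all(tab$p5[ok] <= tab$p50[ok]))
    expect_true(all(tab$p50[ok] <= tab$p95[ok]))
    # bin counts sum to the cohort size within each region
    for (rg in unique(tab$region)) {
      expect_equal(sum(tab$n[tab$region == rg]), 92L)
    }
  }
})

test_that("centile lookup inverts the empirical distribution", {
  cohort <- simulate_regional_cohort(seed = 2)
  tab <- make_percentile_table(cohort)
  row <- tab[tab$region == "white_matter" & tab$bin_start == 28, ]
  expect_equal(evaluate_centile(tab, "white_matter", 29, row$p50), 0.5,
               tolerance = 1e-9)
  expect_equal(evaluate_centile(tab, "white_matter", 29, row$p95), 0.95,
               tolerance = 0.02)
  expect_equal(evaluate_centile(tab, "white_matter", 29, 1), 0)
  expect_equal(evaluate_centile(tab, "white_matter", 29, 1e5), 1)
  rec <- data.frame(scan_id = 1, ga = 21, region = "eCSF",
                    mean_t2star_ms = 300)
  tab1 <- make_percentile_table(rec)
  expect_warning(out <- evaluate_centile(tab1, "eCSF", 35, 300), "empty")
  expect_true(is.na(out))
})

test_that("noiseless reference cohorts decline in T2* and grow in volume", {
  cohort <- noiseless_cohort()
  growth <- fit_region_growth(cohort)
  vols <- fit_region_growth(cohort, outcome = "volume_ml")
  for (rg in names(growth)) {
    expect_lt(predict(growth[[rg]], 39), predict(growth[[rg]], 21))
    expect_gt(predict(vols[[rg]], 39), predict(vols[[rg]], 21))
  }
})

test_that("noiseless cohort bin means match the reference within bin-to-bin differences", {
  cohort <- noiseless_cohort()
  tab <- make_percentile_table(cohort)
  ref <- reference_t2star_table()
  for (rg in unique(tab$region)) {
    r_ref <- ref[ref$region == rg, ]
    tol <- max(abs(diff(r_ref$mean)))
    rows <- tab[tab$region == rg & tab$n > 0, ]
    for (i in seq_len(nrow(rows))) {
      expect_lt(abs(rows$mean[i] -
                    r_ref$mean[r_ref$bin_start == rows$bin_start[i]]), tol)
    }
  }
})
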