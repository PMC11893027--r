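test_that("noiseless three-echo fits are exact for both estimators", {
  s <- simulate_signal(1000, 250, TE3)
  ll <- fit_loglinear(s, TE3)
  expect_equal(ll$t2star, 250, tolerance = 1e-9)
  expect_equal(ll$s0, 1000, tolerance = 1e-6)
  expect_equal(ll$r_squared, 1)
  nl <- fit_nonlinear(s, TE3)
  expect_equal(nl$t2star, ll$t2star, tolerance = 1e-6)
  expect_equal(nl$s0, ll$s0, tolerance = 1e-6)
})

test_that("geometric halving per interval t gives T2* = t / ln 2", {
  t <- 100 * log(2)
  f <- fit_loglinear(c(500, 250, 125), c(0, t, 2 * t))
  expect_equal(f$t2star, t / log(2), tolerance = 1e-9)
  expect_equal(f$s0, 500, tolerance = 1e-9)
})

test_that("non-positive signals invalidate the log-domain fit", {
  expect_false(fit_loglinear(c(100, 0, 10), TE3)$valid)
  expect_false(fit_loglinear(c(100, -5, 10), TE3)$valid)
  expect_error(fit_loglinear(c(1, 2), TE3), "length")
})

test_that("nonlinear fit replaces an unusable init instead of failing", {
  s <- simulate_signal(800, 180, TE3)
  bad_init <- fit_loglinear(c(100, 0, 10), TE3)  # invalid
  f <- fit_nonlinear(s, TE3, init = bad_init)
  expect_true(f$valid)
  expect_equal(f$t2star, 180, tolerance = 1e-6)
})

test_that("under Rician noise the nonlinear estimator is competitive with log-linear", {
  s0 <- 1000; t2 <- 250
  clean <- simulate_signal(s0, t2, TE3)
  n <- 400
  noisy <- matrix(add_rician_noise(rep(clean, n), s0 / 20, seed = 21),
                  n, 3, byrow = TRUE)
  err_ll <- err_nl <- numeric(n)
  for (i in seq_len(n)) {
    ll <- fit_loglinear(noisy[i, ], TE3)
    nl <- fit_nonlinear(noisy[i, ], TE3, init = ll)
    err_ll[i] <- abs(ll$t2star - t2)
    err_nl[i] <- abs(nl$t2star - t2)
  }
  expect_lt(median(err_nl, na.rm = TRUE),
            1.1 * median(err_ll, na.rm = TRUE))
})

test_that("signal-squared weighting leaves noiseless fits exact", {
  s <- simulate_signal(900, 320, TE3)
  f <- fit_loglinear(s, TE3, weighting = "signal2")
  expect_equal(f$t2star, 320, tolerance = 1e-9)
})

test_that("the T2* map of a noiseless phantom is exact within regions", {
  scan <- small_scan()
  map <- compute_t2star_map(scan$volume, mask = scan$labels$labels > 0)
  for (l in 1:7) {
    idx <- scan$labels$labels == l
    expect_true(all(map$validity[idx]))
    expect_equal(max(abs(map$t2star[idx] - scan$tissue$t2star[l])), 0,
                 tolerance = 1e-6)
  }
})

test_that("background-only volumes yield all-invalid maps and empty masks error", {
  d <- c(8, 8, 8)
  vol <- structure(list(data = array(0, c(d, 3)), echo_times = TE3,
                        affine = diag(4), voxel_size = 1.2),
                   class = "multiecho_volume")
  map <- compute_t2star_map(vol)
  expect_false(any(map$validity))
  expect_error(compute_t2star_map(vol, mask = array(FALSE, d)), "empty")
})

test_that("T2* outside the configured bounds is excluded, never clamped", {
  scan <- small_scan()
  map <- compute_t2star_map(scan$volume, mask = scan$labels$labels > 0,
                            bounds = c(1, 300))
  vents <- scan$labels$labels == 5  # true T2* ~ 380 ms at GA 30
  expect_false(any(map$validity[vents]))
  expect_true(all(is.na(map$t2star[vents])))
})

test_that("the map is invariant to global signal scaling", {
  scan <- small_scan()
  v2 <- scan$volume
  v2$data <- v2$data * 3.7
  m1 <- compute_t2star_map(scan$volume, mask = scan$labels$labels > 0)
  m2 <- compute_t2star_map(v2, mask = scan$labels$labels > 0)
  expect_equal(m1$t2star, m2$t2star, tolerance = 1e-9)
})
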