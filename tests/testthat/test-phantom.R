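test_that("label volume contains the seven regions plus background and is deterministic", {
  lv1 <- build_label_volume(small_spec())
  lv2 <- build_label_volume(small_spec())
  expect_setequal(unique(as.integer(lv1$labels)), 0:7)
  expect_identical(lv1$labels, lv2$labels)
})

test_that("phantom brain volume grows strictly with gestational age", {
  counts <- vapply(seq(20, 40, by = 2), function(ga) {
    sum(build_label_volume(phantom_spec(ga, grid_shape = 48))$labels > 0)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("a grid too small to host the regions fails loudly", {
  expect_error(build_label_volume(phantom_spec(30, grid_shape = 16)),
               "too small")
})

test_that("reference lookup reproduces every bin mean at its midpoint", {
  ref <- reference_t2star_table()
  for (i in seq_len(nrow(ref))) {
    expect_identical(lookup_reference_t2star(ref$region[i], ref$midpoint[i]),
                     ref$mean[i])
  }
})

test_that("reference lookup interpolates linearly and extrapolates as a constant", {
  # halfway between the first two cerebellum bin means 315.8 and 337.4
  expect_equal(lookup_reference_t2star("cerebellum", 22), 326.6)
  # below the first midpoint the curve is flat
  expect_equal(lookup_reference_t2star("brainstem", 20),
               lookup_reference_t2star("brainstem", 21))
  expect_error(lookup_reference_t2star("brainstem", 19.5), "20, 40")
  expect_error(lookup_reference_t2star("brainstem", 41), "20, 40")
})

test_that("mono-exponential signal model is exact", {
  expect_equal(simulate_signal(1000, 250, 0), 1000)
  expect_equal(simulate_signal(1000, 107, 107), 1000 / exp(1))
  # frozen independent evaluation of 1000 * exp(-TE / 250)
  expect_equal(simulate_signal(1000, 250, TE3),
               c(845.3538346847, 651.8114147987, 502.5802250254),
               tolerance = 1e-10)
  expect_error(simulate_signal(1000, -5, TE3), "t2star")
  expect_error(simulate_signal(-1, 250, TE3), "s0")
})

test_that("Rician noise has the expected degenerate and asymptotic behaviour", {
  x <- matrix(seq(0, 100, length.out = 12), 3, 4)
  expect_identical(add_rician_noise(x, 0), x)
  expect_identical(add_rician_noise(x, 5, seed = 11),
                   add_rician_noise(x, 5, seed = 11))
  expect_error(add_rician_noise(x, -1), "sigma")
  # zero signal becomes Rayleigh with mean sigma * sqrt(pi / 2)
  s <- 7
  draws <- add_rician_noise(rep(0, 2e5), s, seed = 3)
  expect_equal(mean(draws), s * sqrt(pi / 2), tolerance = 0.01)
})

test_that("rendering fills regions uniformly with the exact decay ratio", {
  scan <- small_scan()
  vol <- scan$volume
  for (l in c(3, 7)) {
    idx <- scan$labels$labels == l
    for (e in 1:3) {
      vals <- vol$data[, , , e][idx]
      expect_equal(max(vals), min(vals))
    }
    ratio <- vol$data[, , , 3][idx][1] / vol$data[, , , 1][idx][1]
    expect_equal(ratio, exp(-(172 - 42) / scan$tissue$t2star[l]),
                 tolerance = 1e-12)
  }
  expect_true(all(vol$data[, , , 1][scan$labels$labels == 0] == 0))
})

test_that("rendering rejects labels without tissue parameters", {
  lv <- build_label_volume(small_spec())
  tissue <- tissue_params(30)[-3, ]
  expect_error(render_multiecho(lv, tissue, small_acq()), "label")
})

test_that("scaling S0 scales every echo and leaves decay ratios unchanged", {
  lv <- build_label_volume(small_spec())
  acq <- small_acq()
  v1 <- render_multiecho(lv, tissue_params(30), acq)
  v2 <- render_multiecho(lv, tissue_params(30, s0_scale = 2.5), acq)
  expect_equal(v2$data, 2.5 * v1$data, tolerance = 1e-12)
})

test_that("slice sampling has the right count, shared transforms and determinism", {
  scan <- small_scan()
  stacks <- scan$stacks
  geom <- stacks[[1]]$geometry
  expect_identical(dim(stacks[[1]]$data),
                   c(geom$nx, geom$ny, geom$n_slices, 2L))
  expect_equal(nrow(stacks[[1]]$transforms), geom$n_slices * 2)
  # echoes of one excitation share the motion state
  expect_identical(stacks[[1]]$transforms, stacks[[2]]$transforms)
  expect_identical(stacks[[1]]$transforms, stacks[[3]]$transforms)
  again <- sample_slice_stack(scan$volume, small_acq(),
                              motion_amplitude = c(0, 0), seed = 42)
  expect_identical(again[[1]]$data, stacks[[1]]$data)
  expect_error(sample_slice_stack(scan$volume, small_acq(),
                                  motion_amplitude = c(-1, 0)),
               "amplitude")
})

test_that("motion-free sampling reduces to the identity-transform slice model", {
  scan <- small_scan()
  expect_true(all(scan$stacks[[1]]$transforms$rx == 0))
  expect_true(all(scan$stacks[[1]]$transforms$tx == 0))
})

test_that("acquisition and phantom specifications validate their inputs", {
  expect_error(acquisition_spec(echo_times = c(100, 50)), "increasing")
  expect_error(acquisition_spec(n_dynamics = 0), "n_dynamics")
  expect_error(phantom_spec(15), "gestational_age")
  expect_error(phantom_spec(30, noise_sigma = -1), "noise_sigma")
})
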