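# reconstruction tests run on a 48^3 phantom with few dynamics to stay fast
fast_cfg <- function(...) {
  args <- utils::modifyList(list(n_outer_iterations = 1, n_cg_iterations = 8,
                                 regularization_weight = 3e-4), list(...))
  do.call(recon_config, args)
}

test_that("initialisation requires slices and flags uncovered voxels", {
  expect_error(initialize_volume(list()), "no slice stacks")
  scan <- small_scan()
  stacks <- scan$stacks
  # keep a single slice: voxels away from its plane get no weight
  one <- lapply(stacks, function(st) {
    st$data <- st$data[, , 10, 1, drop = FALSE]
    st$transforms <- st$transforms[st$transforms$slice == 10 &
                                     st$transforms$dynamic == 1, ]
    st$transforms$slice <- 1L
    st$transforms$dynamic <- 1L
    st$geometry$n_slices <- 1L
    st$geometry$z <- st$geometry$z[10]
    st
  })
  init <- initialize_volume(one, fast_cfg())
  zc <- (one[[1]]$geometry$z[1] - init$affine[3, 4]) / init$voxel_size + 1
  expect_true(any(init$valid[, , round(zc)]))
  far <- round(zc) + 8
  expect_false(any(init$valid[, , far]))
})

test_that("zero outer iterations returns the initialisation unchanged", {
  scan <- small_scan()
  init <- initialize_volume(scan$stacks, fast_cfg())
  rec <- super_resolve(scan$stacks, fast_cfg(n_outer_iterations = 0))
  expect_identical(rec$data, init$data)
})

test_that("transform sharing hands every echo an independent copy", {
  tfs <- scan_transforms <- small_scan()$stacks[[1]]$transforms
  copies <- share_transforms(tfs, 3)
  expect_length(copies, 3)
  expect_identical(copies[[1]], copies[[3]])
  copies[[2]]$rx[1] <- 99
  expect_identical(copies[[1]], tfs)   # other copies untouched
})

test_that("outlier rejection applies the slice threshold and the dynamic rule", {
  scores <- data.frame(slice = rep(1:10, 2), dynamic = rep(1:2, each = 10),
                       score = c(rep(0.95, 10), rep(c(0.5, 0.95), 5)))
  out <- reject_outliers(scores, threshold = 0.8)
  expect_true(all(out$include[out$dynamic == 1]))
  expect_true(all(out$include[out$dynamic == 2] ==
                    (scores$score[out$dynamic == 2] >= 0.8)))
  # > 50% bad slices drags the whole dynamic out
  scores$score[scores$dynamic == 2] <- c(rep(0.5, 6), rep(0.95, 4))
  out2 <- reject_outliers(scores, threshold = 0.8)
  expect_false(any(out2$include[out2$dynamic == 2]))
  # threshold -1 never excludes; undefined scores are kept
  scores$score[1] <- NA
  out3 <- reject_outliers(scores, threshold = -1)
  expect_true(all(out3$include))
  expect_error(reject_outliers(scores, threshold = 2), "threshold")
})

test_that("registration early-exits at identity for motion-free slices and flags degenerate ones", {
  scan <- small_scan()
  geom <- scan$stacks[[3]]$geometry
  samp <- fetalt2star:::recon_sampling(geom)
  vol <- scan$volume$data[, , , 3]
  k <- which.max(apply(scan$stacks[[3]]$data[, , , 1], 3, sd))
  b <- scan$stacks[[3]]$data[, , k, 1]
  fit <- register_slice_to_volume(b, vol, 1.2, samp$pts[[k]],
                                  samp$off$weights)
  expect_lt(max(abs(fit$par)), 1e-9)
  expect_gt(fit$score, 0.999)
  # constant slice: returned unchanged with undefined score
  flat <- register_slice_to_volume(rep(0, length(b)), vol, 1.2,
                                   samp$pts[[k]], samp$off$weights,
                                   init = c(1, 0, 0, 0, 0, 0))
  expect_identical(flat$par, c(1, 0, 0, 0, 0, 0))
  expect_true(is.na(flat$score))
})

test_that("through-plane translation is recovered and the optimum is self-consistent", {
  scan <- small_scan()
  geom <- scan$stacks[[3]]$geometry
  samp <- fetalt2star:::recon_sampling(geom)
  vol <- scan$volume$data[, , , 3]
  k <- which.max(apply(scan$stacks[[3]]$data[, , , 1], 3, sd))
  truth <- c(0, 0, 0, 0, 0, 2)   # 2 mm through-plane shift
  b <- fetalt2star:::project_slice(vol, 1.2, samp$pts[[k]],
                                   samp$off$weights,
                                   rigid_transform(truth[1:3], truth[4:6]))
  fit <- register_slice_to_volume(b, vol, 1.2, samp$pts[[k]],
                                  samp$off$weights)
  expect_lt(abs(fit$par[6] - 2), 0.5)
  expect_gt(fit$score, 0.99)
})

test_that("motion-free noiseless reconstruction keeps all slices and improves monotonically", {
  scan <- small_scan()
  cfg <- recon_config(n_outer_iterations = 2, n_cg_iterations = 10,
                      regularization_weight = 3e-4)
  rec <- super_resolve(scan$stacks, cfg)
  expect_true(all(rec$provenance$n_excluded == 0))
  expect_true(all(diff(rec$provenance$mean_ncc) > -1e-6))
  expect_gt(min(rec$provenance$mean_ncc), 0.99)

  # echo-consistency: interior white-matter voxels decay as
  # exp(-dTE / T2*) within 2% (90th percentile over the twice-eroded core,
  # away from partial-volume interfaces); evaluated with oracle transforms
  # so the volume-update property is not confounded by registration drift
  rec <- suppressWarnings(super_resolve(
    scan$stacks, fast_cfg(n_cg_iterations = 15),
    true_transforms = scan$stacks[[1]]$transforms))
  lab <- scan$labels$labels
  d <- dim(lab)
  erode6 <- function(m) {
    out <- array(FALSE, d)
    ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
    out[ix, iy, iz] <- m[ix, iy, iz] &
      m[ix - 1, iy, iz] & m[ix + 1, iy, iz] &
      m[ix, iy - 1, iz] & m[ix, iy + 1, iz] &
      m[ix, iy, iz - 1] & m[ix, iy, iz + 1]
    out
  }
  core <- erode6(erode6(lab == 3))
  expect_gt(sum(core), 100)
  ratio <- rec$data[, , , 3][core] / rec$data[, , , 1][core]
  expected <- exp(-(172 - 42) / scan$tissue$t2star[3])
  expect_lt(quantile(abs(ratio / expected - 1), 0.9), 0.02)
})

test_that("excluded slices have zero influence on the reconstruction", {
  spec <- small_spec()
  acq <- small_acq(n_dynamics = 5)
  sim <- simulate_scan(spec, acq)
  stacks <- sim$stacks
  # corrupt dynamic 2 after sampling: resample it under a large rigid
  # motion the assumed geometry cannot explain
  geom <- stacks[[1]]$geometry
  samp <- fetalt2star:::recon_sampling(geom)
  tf_bad <- rigid_transform(c(0, 0, 0), c(12, 12, 0))
  for (e in 1:3) {
    for (k in seq_len(geom$n_slices)) {
      stacks[[e]]$data[, , k, 2] <- fetalt2star:::project_slice(
        sim$volume$data[, , , e], 1.2, samp$pts[[k]], samp$off$weights,
        tf_bad)
    }
  }
  # threshold chosen to separate the corrupted dynamic (scores ~0.25-0.45)
  # from faint marginal slices, so the keep-set is unambiguous
  cfg <- recon_config(n_outer_iterations = 1, n_cg_iterations = 6,
                      regularization_weight = 3e-4,
                      similarity_threshold = 0.5)
  tf_true <- stacks[[1]]$transforms
  rec_a <- suppressWarnings(super_resolve(stacks, cfg, true_transforms = tf_true))
  expect_identical(unique(rec_a$provenance$exclusions$dynamic), 2L)
  expect_equal(nrow(rec_a$provenance$exclusions), geom$n_slices)

  removed <- lapply(stacks, function(st) {
    st$data <- st$data[, , , -2, drop = FALSE]
    st$transforms <- st$transforms[st$transforms$dynamic != 2, ]
    st
  })
  rec_b <- suppressWarnings(super_resolve(removed, cfg,
                                          true_transforms = removed[[1]]$transforms))
  expect_identical(rec_a$data, rec_b$data)
})
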