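make_raw_labels <- function() {
  # a toy 19-label volume covering every raw id at known counts
  d <- c(12, 12, 12)
  lab <- array(0L, dim = d)
  ids <- rep(1:19, times = 19:1)      # id k occupies 20 - k voxels
  lab[seq_along(ids)] <- ids
  structure(list(labels = lab, affine = diag(c(1.2, 1.2, 1.2, 1)),
                 voxel_size = 1.2, label_names = region_names()),
            class = "label_volume")
}

test_that("the default mapping is total over the 19 raw labels", {
  m <- default_label_mapping()
  expect_setequal(names(m), as.character(1:19))
  expect_true(all(m %in% 0:7))
  expect_setequal(unique(unname(m)), 1:7)
})

test_that("merging conserves voxel counts per category", {
  raw <- make_raw_labels()
  m <- default_label_mapping()
  merged <- merge_labels(raw, m)
  raw_counts <- table(factor(raw$labels[raw$labels > 0], levels = 1:19))
  for (cat in 1:7) {
    expect_equal(sum(merged$labels == cat),
                 sum(raw_counts[m[as.character(1:19)] == cat]))
  }
  expect_equal(sum(merged$labels > 0), sum(raw$labels > 0))
})

test_that("identity mapping on an already-merged phantom is a no-op", {
  lv <- build_label_volume(small_spec())
  m <- setNames(1:7, as.character(1:7))
  expect_identical(merge_labels(lv, m)$labels, lv$labels)
})

test_that("an unmapped raw label raises an error naming the id", {
  raw <- make_raw_labels()
  m <- default_label_mapping()
  expect_error(merge_labels(raw, m[names(m) != "13"]), "13")
})

test_that("relabelling raw ids (with the mapping updated) leaves stats unchanged", {
  raw <- make_raw_labels()
  m <- default_label_mapping()
  # permute raw ids: k -> 20 - k
  perm <- raw
  nz <- raw$labels > 0
  perm$labels[nz] <- 20L - raw$labels[nz]
  m_perm <- setNames(m[as.character(20 - as.integer(names(m)))], names(m))
  s1 <- regional_volume(merge_labels(raw, m))
  s2 <- regional_volume(merge_labels(perm, m_perm))
  expect_equal(s1, s2)
})

test_that("regional volumes follow the affine determinant", {
  d <- c(20, 10, 10)
  lab <- array(0L, dim = d)
  lab[seq_len(1000)] <- 3L
  lv <- structure(list(labels = lab, affine = diag(c(1.2, 1.2, 1.2, 1)),
                       voxel_size = 1.2), class = "label_volume")
  expect_equal(regional_volume(lv)$volume_ml[3], 1.728)
  lab2 <- array(0L, dim = d)
  lab2[seq_len(100)] <- 1L
  lv2 <- structure(list(labels = lab2, affine = diag(c(3, 3, 3, 1)),
                        voxel_size = 3), class = "label_volume")
  rv <- regional_volume(lv2)
  expect_equal(rv$volume_ml[1], 2.7)
  expect_equal(rv$volume_ml[2], 0)
  lv_bad <- lv
  lv_bad$affine[1, 1] <- 0
  expect_error(regional_volume(lv_bad), "singular")
})

test_that("regional means average valid voxels only and respect bounds", {
  d <- c(10, 10, 10)
  lab <- array(0L, dim = d)
  lab[1:200] <- 2L
  lv <- structure(list(labels = lab, affine = diag(c(1.2, 1.2, 1.2, 1)),
                       voxel_size = 1.2), class = "label_volume")
  t2 <- array(NA_real_, d)
  t2[1:100] <- 200; t2[101:200] <- 400
  validity <- array(FALSE, d); validity[1:200] <- TRUE
  map <- structure(list(t2star = t2, validity = validity,
                        bounds = c(1, 1000)), class = "t2star_map")
  st <- regional_mean_t2star(map, lv)
  expect_equal(st$mean_t2star_ms[st$region == "gray_matter"], 300)
  # half the voxels invalid: mean over the valid half only
  map$validity[101:200] <- FALSE
  st2 <- regional_mean_t2star(map, lv)
  row <- st2[st2$region == "gray_matter", ]
  expect_equal(row$mean_t2star_ms, 200)
  expect_equal(row$voxel_count, 200)
  expect_equal(row$n_valid_voxels, 100)
  # a category with zero valid voxels is flagged, not dropped
  expect_true(all(!st2$defined[st2$region == "brainstem"]))
  expect_true(is.na(st2$mean_t2star_ms[st2$region == "brainstem"]))
})

test_that("category volumes sum exactly to the total labelled volume", {
  lv <- build_label_volume(small_spec())
  rv <- regional_volume(lv)
  expect_equal(sum(rv$voxel_count), sum(lv$labels > 0))
  expect_equal(sum(rv$volume_ml), sum(lv$labels > 0) * 1.2^3 / 1000)
})
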