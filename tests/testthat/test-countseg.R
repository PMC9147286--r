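test_that("the forward pass splits channels and returns rectified density", {
  m <- build_countseg(countseg_config(seed = 3, input_side_px = 64,
                                      shared_channels = 60))
  expect_equal(ncol(m$head_class$w), 1)
  expect_equal(nrow(m$head_class$w), 30)   # half of 60 channels per branch
  expect_equal(nrow(m$head_density$w), 30)
  tile <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fw <- countseg_forward(m, tile)
  expect_equal(dim(fw$confidence_map), c(16, 16))
  expect_equal(dim(fw$density$values), c(16, 16))
  expect_true(all(fw$density$values >= 0))
  expect_equal(fw$class_score, max(fw$confidence_map))
  expect_true(fw$class_prob >= 0 && fw$class_prob <= 1)
  # all-zero input: finite outputs, nonnegative density sum
  fz <- countseg_forward(m, array(0, c(64, 64, 3)))
  expect_true(all(is.finite(fz$density$values)))
  expect_gte(sum(fz$density$values), 0)
  # evaluation-mode determinism
  expect_identical(countseg_forward(m, tile)$density$values, fw$density$values)
})

test_that("the class loss is binary cross-entropy on the pooled score", {
  expect_equal(loss_class(Inf, "present"), 0)
  expect_equal(loss_class(0, "present"), log(2))
  expect_equal(loss_class(0, "absent"), log(2))
  withr::with_seed(4, {
    for (p in runif(10, 0.05, 0.95)) {
      s <- qlogis(p)
      expect_equal(loss_class(s, "absent"), -log(1 - p), tolerance = 1e-12)
      expect_equal(loss_class(s, "present"), -log(p), tolerance = 1e-12)
    }
  })
})

test_that("the global loss is exact in range and hinge-only beyond", {
  d4 <- density_map(matrix(0.25, 4, 4), 4)  # sums to 4
  expect_identical(loss_global(d4, 4L), 0)
  d2 <- matrix(0.125, 4, 4)                 # sums to 2
  expect_equal(loss_global(d2, 4L), 4)
  d12 <- matrix(0.75, 4, 4)                 # sums to 12 >= 11: hinge inactive
  expect_identical(loss_global(d12, 13L), 0)
  d8 <- matrix(0.5, 4, 4)                   # sums to 8 < 11: hinge (11-8)^2
  expect_equal(loss_global(d8, 13L), 9)
  expect_error(loss_global(d2, 16L), "dnc")
  expect_error(loss_global(d2, -1L), "nonnegative")
})

test_that("pseudo ground truth marks the count strongest separated maxima", {
  expect_identical(make_pseudo_ground_truth(matrix(1, 8, 8), 0),
                   matrix(FALSE, 8, 8))
  centres <- rbind(c(3, 3), c(3, 12), c(12, 7))
  m <- bump_map(16, 16, centres)
  pm <- make_pseudo_ground_truth(m, 3, peak_neighborhood_px = 3)
  expect_equal(sum(pm), 3)
  expect_true(all(pm[centres]))
  # brute-force local-maxima oracle agrees with the marked apices
  bm <- brute_local_maxima(m)
  expect_true(all(apply(which(pm, arr.ind = TRUE), 1, function(p) {
    any(bm[, 1] == p[1] & bm[, 2] == p[2])
  })))
  # fewer maxima than requested: all marked, with a warning
  expect_warning(pm2 <- make_pseudo_ground_truth(m, 12, peak_neighborhood_px = 3),
                 "local maxima")
  expect_lt(sum(pm2), 12)
  expect_true(all(pm2[centres]))
})

test_that("the spatial loss rewards mass on the pseudo peaks", {
  pm <- matrix(FALSE, 4, 4); pm[2, 2] <- TRUE; pm[3, 4] <- TRUE
  perfect <- matrix(0, 4, 4); perfect[pm] <- 1
  expect_identical(loss_spatial(perfect, pm), 0)
  uniform <- matrix(0.5, 4, 4)
  expect_gt(loss_spatial(uniform, pm), 0)
  # moving density mass from a non-peak cell to a peak cell lowers the loss
  # (the map keeps its min/max anchors so the normalization is unchanged)
  before <- matrix(0, 4, 4); before[2, 2] <- 1; before[3, 4] <- 0.5; before[4, 1] <- 0.5
  after <- before; after[3, 4] <- 0.7; after[4, 1] <- 0.3
  expect_lt(loss_spatial(after, pm), loss_spatial(before, pm))
  expect_error(loss_spatial(matrix(0, 3, 3), pm), "shape")
})

test_that("the combined loss is exactly the sum of the three terms", {
  withr::with_seed(11, {
    for (i in 1:25) {
      v <- matrix(runif(64, 0, 0.5), 8, 8)
      pm <- matrix(runif(64) < 0.1, 8, 8)
      cl <- countseg_loss(rnorm(1), sample(c("present", "absent"), 1),
                          density_map(v, 4), pm, sample(0:15, 1))
      expect_identical(cl$total, cl$l_class + cl$l_spatial + cl$l_global)
      expect_gte(cl$l_class, 0); expect_gte(cl$l_spatial, 0); expect_gte(cl$l_global, 0)
    }
  })
})

test_that("the ILC trainer refuses point supervision and dnc tiles", {
  b <- get_benchmark()
  m <- build_countseg(countseg_config(seed = 1))
  expect_error(train_countseg(m, b$train[, c("image", "count", "points")]),
               "point supervision")
  dnc <- tibble::tibble(image = b$train$image[1], count = 17L)
  expect_error(train_countseg(m, dnc), "dnc")
})

test_that("peak_instances finds separated bumps and is monotone in the threshold", {
  centres <- rbind(c(4, 4), c(4, 13), c(13, 8))
  dm <- density_map(bump_map(16, 16, centres), stride_px = 4)
  pk <- peak_instances(dm, threshold = 0.5)
  expect_equal(nrow(pk), 3)
  # peaks map to the bump centres within one cell (cell centres, stride 4)
  exp_x <- (centres[, 2] - 1) * 4 + 1.5
  exp_y <- (centres[, 1] - 1) * 4 + 1.5
  for (k in 1:3) {
    d <- sqrt((pk$x - exp_x[k])^2 + (pk$y - exp_y[k])^2)
    expect_lte(min(d), 4)
  }
  expect_equal(nrow(peak_instances(density_map(matrix(0, 8, 8), 4), 0)), 0)
  ths <- seq(0, 1, by = 0.1)
  ns <- vapply(ths, function(t) nrow(peak_instances(dm, t)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("trained CountSeg consumed counts only within the subitizing range", {
  m <- get_trained("countseg", 1L)
  expect_true(all(c("class_labels", "counts_within_subitizing") %in% m$supervision_log))
  expect_false("points" %in% m$supervision_log)
  # prediction equals the density-map sum by construction
  b <- get_benchmark()
  tile <- b$test$image[[1]]
  fw <- countseg_forward(m, tile)
  pr <- predict_countseg(m, tile)
  expect_equal(pr$count_real, sum(fw$density$values))
  expect_equal(pr$count_int, max(0L, as.integer(floor(pr$count_real + 0.5))))
})
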