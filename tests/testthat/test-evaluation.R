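test_that("rmse matches hand arithmetic and a brute-force oracle", {
  expect_equal(rmse(c(2, 4), c(2, 4)), 0)
  expect_equal(rmse(c(0, 3), c(1, 5)), sqrt(2.5))
  withr::with_seed(5, {
    for (i in 1:100) {
      n <- sample(2:30, 1)
      gt <- sample(0:15, n, replace = TRUE)
      pr <- gt + sample(-3:3, n, replace = TRUE)
      acc <- 0
      for (j in seq_len(n)) acc <- acc + (gt[j] - pr[j])^2
      expect_equal(rmse(gt, pr), sqrt(acc / n), tolerance = 1e-12)
    }
  })
  expect_error(rmse(1:3, 1:2), "equal")
  expect_error(rmse(numeric(0), numeric(0)), "nonzero")
})

test_that("median_prediction uses the lower median for even runs", {
  expect_equal(median_prediction(c(3, 5, 4, 4, 9)), 4)
  expect_equal(median_prediction(7), 7)
  expect_equal(median_prediction(c(1, 2, 3, 4)), 2)
  expect_error(median_prediction(numeric(0)), "nonempty")
})

test_that("error histogram follows the truth-minus-prediction convention", {
  eh <- error_histogram(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eh$histogram$error, 0)
  expect_equal(eh$histogram$n, 3)
  expect_equal(eh$fraction_within_3, 1)
  eh2 <- error_histogram(5, 1)
  expect_equal(eh2$histogram$error, 4)  # under-counting is positive
  expect_equal(eh2$fraction_within_3, 0)
  withr::with_seed(6, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      gt <- sample(0:15, n, replace = TRUE)
      pr <- sample(0:15, n, replace = TRUE)
      got <- error_histogram(gt, pr)
      cnt <- 0
      for (j in seq_len(n)) if (abs(gt[j] - pr[j]) <= 3) cnt <- cnt + 1
      expect_equal(got$fraction_within_3, cnt / n, tolerance = 1e-12)
      expect_equal(sum(got$histogram$n), n)
    }
  })
})

test_that("least_squares_fit reproduces exact lines and the normal equations", {
  f1 <- least_squares_fit(0:10, 0:10)
  expect_equal(f1$slope, 1); expect_equal(f1$intercept, 0)
  expect_equal(f1$r_squared, 1)
  f2 <- least_squares_fit(0:10, 2 * (0:10) + 1)
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 1)
  withr::with_seed(9, {
    for (i in 1:100) {
      n <- sample(5:40, 1)
      x <- sample(0:15, n, replace = TRUE)
      if (length(unique(x)) < 2) next
      y <- 0.8 * x + rnorm(n)
      got <- least_squares_fit(x, y)
      # closed-form normal equations
      sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      ic <- mean(y) - sl * mean(x)
      r2 <- 1 - sum((y - sl * x - ic)^2) / sum((y - mean(y))^2)
      expect_equal(got$slope, sl, tolerance = 1e-9)
      expect_equal(got$intercept, ic, tolerance = 1e-9)
      expect_equal(got$r_squared, r2, tolerance = 1e-9)
    }
  })
  expect_error(least_squares_fit(rep(3, 5), 1:5), "constant")
})

test_that("the repeated-runs report summarizes perfect and degenerate models", {
  truths <- c(rep(0, 10), rep(3, 10))
  ids <- sprintf("t%02d", 1:20)
  perfect <- tidyr::expand_grid(run = 1:5, i = 1:20) |>
    dplyr::mutate(tile_id = ids[i], truth = truths[i], pred = truths[i]) |>
    dplyr::select(-i)
  rp <- evaluate_predictions(perfect)
  expect_equal(rp$overall$mean_rmse, 0)
  expect_equal(rp$overall$sd_rmse, 0)  # identical deterministic runs
  expect_equal(rp$fraction_within_3, 1)
  expect_true(all(rp$by_bin$mean_rmse == 0))
  expect_equal(rp$fit$r_squared, 1)

  zero <- dplyr::mutate(perfect, pred = 0L)
  rz <- evaluate_predictions(zero)
  expect_equal(rz$overall$mean_rmse, sqrt(90 / 20))
  expect_equal(rz$by_bin$mean_rmse[rz$by_bin$bin == "zero"], 0)
  expect_equal(rz$by_bin$mean_rmse[rz$by_bin$bin == "b1_5"], 3)
  # empty bins are absent from the report, not NaN rows
  expect_false(any(is.na(rz$by_bin$mean_rmse)))
  expect_setequal(as.character(rz$by_bin$bin), c("zero", "b1_5"))

  g <- glance(rz)
  expect_equal(g$overall_rmse, sqrt(4.5))
  expect_s3_class(tidy(rz), "tbl_df")
})

test_that("overall RMSE is bracketed by the per-bin extremes", {
  withr::with_seed(12, {
    for (i in 1:20) {
      n <- 40
      truth <- sample(0:12, n, replace = TRUE)
      pred <- pmax(0, truth + sample(-4:4, n, replace = TRUE))
      df <- tibble::tibble(tile_id = sprintf("t%02d", 1:n), truth = truth,
                           run = 1L, pred = pred)
      rp <- evaluate_predictions(df)
      expect_gte(rp$overall$mean_rmse, min(rp$by_bin$mean_rmse) - 1e-12)
      expect_lte(rp$overall$mean_rmse, max(rp$by_bin$mean_rmse) + 1e-12)
    }
  })
})

test_that("evaluate_model and evaluate_plants run fitted models end to end", {
  b <- get_benchmark()
  m <- get_trained("scount", 1L)
  rp <- evaluate_model(m, b$test[1:20, ])
  expect_equal(rp$k_runs, 1)
  expect_true(is.finite(rp$overall$mean_rmse))

  # plant-level: ground truth recomputed from points equals the point total
  cfg <- scene_config(image_height_px = 128, image_width_px = 128,
                      count_range = c(6, 12), blob_radius_range_px = c(3, 6),
                      seed = 77)
  plant <- generate_scene(cfg)
  plants <- tibble::tibble(plant_id = "p1", image = list(plant$image),
                           points = list(plant$points))
  pr <- evaluate_plants(m, plants, tile_size_px = 64)
  expect_equal(pr$summary$truth, plant$count)
  expect_equal(nrow(pr$totals), 1)
  expect_gte(pr$summary$mean_total, 0)
  expect_equal(pr$summary$sd_total, 0)
})

test_that("report plots build without error", {
  df <- tibble::tibble(tile_id = sprintf("t%02d", 1:20),
                       truth = rep(0:4, 4), run = 1L,
                       pred = rep(0:4, 4) + rep(c(0, 1), 10))
  rp <- evaluate_predictions(df)
  expect_s3_class(autoplot(rp, "histogram"), "ggplot")
  expect_s3_class(autoplot(rp, "fit"), "ggplot")
  dm <- density_map(matrix(runif(64), 8, 8), 4)
  expect_s3_class(autoplot(dm), "ggplot")
  sc <- generate_scene(scene_config(image_height_px = 32, image_width_px = 32,
                                    count_range = c(2, 2),
                                    blob_radius_range_px = c(3, 4), seed = 1))
  expect_s3_class(autoplot(sc), "ggplot")
})
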