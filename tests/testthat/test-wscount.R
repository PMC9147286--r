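test_that("split_multiscale yields 1 + 4 + 16 patches that partition the tile", {
  tile <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ms <- split_multiscale(tile)
  expect_length(ms$patches, 21)
  expect_equal(dim(ms$full[[1]]), c(64, 64, 3))
  expect_true(all(vapply(ms$quarters, function(p) all(dim(p) == c(32, 32, 3)), TRUE)))
  expect_true(all(vapply(ms$sixteenths, function(p) all(dim(p) == c(16, 16, 3)), TRUE)))
  # reassembling the quarters reproduces the tile bit-exactly
  top <- abind_cols(ms$quarters[[1]], ms$quarters[[2]])
  bottom <- abind_cols(ms$quarters[[3]], ms$quarters[[4]])
  expect_identical(abind_rows(top, bottom), tile)
  # 500-style arithmetic at a divisible size
  ms2 <- split_multiscale(array(0, c(500, 500, 3)))
  expect_equal(dim(ms2$quarters[[1]])[1:2], c(250, 250))
  expect_equal(dim(ms2$sixteenths[[1]])[1:2], c(125, 125))
  expect_error(split_multiscale(array(0, c(63, 63, 3))), "divisible")
})

test_that("classifier-consistency loss matches its closed form", {
  consistent0 <- list(counts = rep(0, 21), presence_probs = rep(0, 21))
  expect_identical(loss_pac_consistency(consistent0), 0)
  consistent1 <- list(counts = rep(2, 21), presence_probs = rep(1, 21))
  expect_identical(loss_pac_consistency(consistent1), 0)

  # single inconsistent branch contributions, all others consistent
  one <- list(counts = c(0, rep(1, 20)), presence_probs = rep(1, 21))
  expect_equal(loss_pac_consistency(one), 1 / 21)
  two <- list(counts = c(2, rep(0, 20)), presence_probs = rep(0, 21))
  expect_equal(loss_pac_consistency(two), 2 / 21)

  expect_error(loss_pac_consistency(list(counts = rep(1, 21),
                                         presence_probs = rep(1.5, 21))),
               "\\[0, 1\\]")
})

test_that("spatial-consistency loss compares the three scale totals", {
  mk <- function(c1, q, s) list(counts = c(c1, rep(q / 4, 4), rep(s / 16, 16)),
                                presence_probs = rep(1, 21))
  expect_identical(loss_spatial_consistency(mk(5, 5, 5)), 0)
  expect_equal(loss_spatial_consistency(mk(4, 2, 2)), 4)
  # positive homogeneity of degree one
  withr::with_seed(14, co <- runif(21, 0, 3))
  out <- list(counts = co, presence_probs = rep(0.5, 21))
  expect_equal(loss_spatial_consistency(list(counts = 2.5 * co,
                                             presence_probs = out$presence_probs)),
               2.5 * loss_spatial_consistency(out))
  expect_error(loss_spatial_consistency(list(counts = 1:5,
                                             presence_probs = rep(1, 5))), "21")
})

test_that("the combined loss is exactly the sum of its two terms", {
  withr::with_seed(7, {
    for (i in 1:50) {
      out <- list(counts = runif(21, 0, 6), presence_probs = runif(21))
      l <- wscount_loss(out)
      expect_identical(l$total, l$l_pac_c + l$l_sp_c)
      expect_gte(l$l_pac_c, 0)
      expect_gte(l$l_sp_c, 0)
    }
  })
})

test_that("pac_forward returns probabilities and is deterministic in eval mode", {
  m <- build_wscount(wscount_config(seed = 4))
  imgs <- list(array(0, c(64, 64, 3)), array(runif(64 * 64 * 3), c(64, 64, 3)))
  p <- pac_forward(m, imgs)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(pac_forward(m, imgs), p)
})

test_that("the weak trainer refuses count supervision", {
  b <- get_benchmark()
  m <- build_wscount(wscount_config(seed = 1))
  expect_error(train_wscount(m, b$train[, c("image", "class_label", "count")]),
               "count supervision")
  expect_error(train_wscount(m, b$train[, c("image", "count")]),
               "count supervision")
  # counting stage requires a trained PAC first
  expect_error(train_wscount(m, b$train[, c("image", "class_label")],
                             stage = "count"), "stage 1")
})

test_that("trained WS-Count consumed only class labels and predicts sanely", {
  m <- get_trained("wscount", 1L)
  expect_true("class_labels" %in% m$supervision_log)
  expect_false(any(c("counts", "points") %in% m$supervision_log))

  b <- get_benchmark()
  # an empty tile predicts zero
  empty <- b$test$image[[which(b$test$count == 0)[1]]]
  expect_equal(predict_wscount(m, empty)$count_int, 0L)
  # prediction is invariant to batch context and never negative
  one <- predict(m, b$test$image[[1]])
  batch <- predict(m, b$test$image[1:3])
  expect_equal(batch$count_real[1], one$count_real)
  expect_true(all(predict(m, b$test[1:10, ])$count_int >= 0))
  # PAC separates presence from absence on held-out tiles
  p <- pac_forward(m, b$test$image)
  acc <- mean((p > 0.5) == (b$test$class_label == "present"))
  expect_gte(acc, 0.95)
})

test_that("the spatial-consistency component decreases over training, averaged over seeds", {
  first <- numeric(3); last <- numeric(3)
  for (s in 1:3) {
    tr <- get_trained("wscount", s)$loss_trace
    tr <- tr[tr$stage == "count", ]
    first[s] <- tr$l_sp_c[1]
    last[s] <- tail(tr$l_sp_c, 1)
  }
  expect_lt(mean(last), mean(first))
})
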