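test_that("scene generation is deterministic and honors forced counts", {
  cfg <- scene_config(image_height_px = 64, image_width_px = 64,
                      count_range = c(3, 3), blob_radius_range_px = c(4, 8),
                      occlusion_probability = 0, seed = 7)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$points, b$points)
  expect_equal(a$count, 3)
  expect_length(a$masks, 3)
  expect_equal(nrow(a$points), 3)

  empty <- generate_scene(scene_config(image_height_px = 64, image_width_px = 64,
                                       count_range = c(0, 0), seed = 1))
  expect_equal(empty$count, 0)
  expect_equal(nrow(empty$points), 0)
  expect_length(empty$masks, 0)
})

test_that("ground truth is closed: counts, points, masks agree and points sit inside masks", {
  for (seed in 1:5) {
    cfg <- bench_scene_config(seed)
    cfg$count_range <- c(0L, 8L)
    cfg$seed <- seed
    sc <- generate_scene(cfg)
    expect_equal(length(sc$masks), sc$count)
    expect_equal(nrow(sc$points), sc$count)
    expect_true(all(sc$image >= 0 & sc$image <= 1))
    for (j in seq_len(sc$count)) {
      x <- sc$points$x[j]; y <- sc$points$y[j]
      expect_true(sc$masks[[j]][floor(y) + 1, floor(x) + 1])
    }
  }
})

test_that("zero occlusion probability yields pairwise-disjoint masks", {
  cfg <- scene_config(image_height_px = 96, image_width_px = 96,
                      count_range = c(6, 6), blob_radius_range_px = c(5, 9),
                      occlusion_probability = 0, seed = 11)
  sc <- generate_scene(cfg)
  for (i in seq_len(sc$count - 1)) {
    for (j in (i + 1):sc$count) {
      expect_false(any(sc$masks[[i]] & sc$masks[[j]]))
    }
  }
})

test_that("every blob keeps at least a quarter of its area visible under occlusion", {
  cfg <- scene_config(image_height_px = 96, image_width_px = 96,
                      count_range = c(8, 8), blob_radius_range_px = c(6, 10),
                      occlusion_probability = 1, seed = 3)
  sc <- generate_scene(cfg)
  owner <- matrix(0L, 96, 96)
  for (j in seq_len(sc$count)) owner[sc$masks[[j]]] <- j
  for (j in seq_len(sc$count)) {
    full <- pi * sc$blobs$a[j] * sc$blobs$b[j]
    expect_gte(sum(owner == j), 0.25 * full)
  }
})

test_that("impossible placements fail with an actionable error", {
  cfg <- scene_config(image_height_px = 32, image_width_px = 32,
                      count_range = c(6, 6), blob_radius_range_px = c(14, 15),
                      occlusion_probability = 0, seed = 2)
  expect_error(generate_scene(cfg), "loosen")
})

test_that("dataset bin frequencies converge to the requested weights", {
  cfg <- bench_scene_config(5L)
  w <- c(zero = 0.25, b1_5 = 0.5, b6_10 = 0.2, b11_15 = 0.05)
  scenes <- generate_dataset(1000, w, cfg)
  expect_length(scenes, 1000)
  bins <- bin_count(vapply(scenes, `[[`, integer(1), "count"))
  freq <- table(factor(bins, levels = names(w))) / 1000
  expect_true(all(abs(as.numeric(freq) - w) <= 0.03))
  chi <- suppressWarnings(chisq.test(table(factor(bins, levels = names(w))), p = w))
  expect_gt(chi$p.value, 0.001)

  zeros <- generate_dataset(10, c(zero = 1), cfg)
  expect_length(zeros, 10)
  expect_true(all(vapply(zeros, `[[`, integer(1), "count") == 0))
  expect_error(generate_dataset(0, w, cfg), "positive")
})

test_that("scenes round-trip through the VIA writer and reader", {
  cfg <- bench_scene_config(9L)
  cfg$count_range <- c(0L, 6L)
  scenes <- generate_dataset(6, c(zero = 0.3, b1_5 = 0.7), cfg)
  dir <- withr::local_tempdir()
  paths <- write_scenes(scenes, dir)
  ann <- read_via_export(paths$json_path)
  expect_equal(nrow(ann), 6)
  for (i in seq_along(scenes)) {
    expect_equal(ann$count[i], scenes[[i]]$count)
    if (scenes[[i]]$count > 0) {
      expect_equal(ann$points[[i]]$x, scenes[[i]]$points$x, tolerance = 1e-6)
      expect_equal(ann$points[[i]]$y, scenes[[i]]$points$y, tolerance = 1e-6)
      expect_equal(ann$class_label[i], "present")
      expect_length(ann$polygons[[i]], scenes[[i]]$count)
    } else {
      expect_equal(ann$class_label[i], "absent")
    }
  }
})
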