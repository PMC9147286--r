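test_that("class labels derive from counts with zero as the boundary", {
  expect_equal(derive_class_label(0), "absent")
  expect_equal(derive_class_label(5), "present")
  expect_equal(derive_class_label(1), "present")
  expect_error(derive_class_label(-1), "nonnegative")
})

test_that("count binning matches the standard ranges including boundaries", {
  expect_equal(as.character(bin_count(c(0, 3, 10, 15))),
               c("zero", "b1_5", "b6_10", "b11_15"))
  expect_equal(as.character(bin_count(16)), "dnc")
  expect_equal(as.character(bin_count(11)), "b11_15")
  expect_equal(as.character(bin_count(5)), "b1_5")
  expect_equal(as.character(bin_count(6)), "b6_10")
  expect_error(bin_count(-2), "nonnegative")
})

make_via_doc <- function() {
  list(
    "a.png123" = list(filename = "a.png", size = 123, regions = list(
      list(shape_attributes = list(name = "point", cx = 10.5, cy = 20.25),
           region_attributes = list(class = "boll")),
      list(shape_attributes = list(name = "point", cx = 30, cy = 40),
           region_attributes = list(class = "boll"))
    ), file_attributes = list()),
    "b.png45" = list(filename = "b.png", size = 45, regions = list(),
                     file_attributes = list())
  )
}

test_that("the VIA reader maps points to counts and labels", {
  ann <- read_via_export(make_via_doc())
  expect_equal(ann$count, c(2, 0))
  expect_equal(ann$class_label, c("present", "absent"))
  expect_equal(as.character(ann$count_bin), c("b1_5", "zero"))
  expect_equal(ann$points[[1]]$x, c(10.5, 30))
  expect_equal(ann$points[[1]]$instance_id, 1:2)
})

test_that("the VIA reader warns on unknown shapes and errors on broken regions", {
  doc <- make_via_doc()
  doc[["a.png123"]]$regions[[3]] <- list(
    shape_attributes = list(name = "circle", cx = 1, cy = 1, r = 5),
    region_attributes = list())
  expect_warning(ann <- read_via_export(doc), "unknown shape")
  expect_equal(ann$count[1], 2)  # skipped region does not change the count

  doc2 <- make_via_doc()
  doc2[["a.png123"]]$regions[[1]]$shape_attributes$cx <- NULL
  expect_error(read_via_export(doc2), "a\\.png")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_via_export(bad), "malformed")
})

test_that("rotation of points and pixels commute", {
  cfg <- scene_config(image_height_px = 64, image_width_px = 64,
                      count_range = c(4, 4), blob_radius_range_px = c(3, 5),
                      occlusion_probability = 0, seed = 21)
  sc <- generate_scene(cfg)
  for (k in 1:3) {
    rimg <- rotate_image_90(sc$image, k)
    rpts <- rotate_points_90(sc$points, 64, k)
    rmask <- rotate_image_90(array(sc$masks[[1]], c(64, 64, 1)), k)[, , 1]
    p1 <- rotate_points_90(sc$points[1, ], 64, k)
    # the rotated point lands on the rotated blob's own mask pixel
    expect_true(rmask[floor(p1$y) + 1, floor(p1$x) + 1] > 0)
    # and on a bright (boll) pixel of the rotated image
    for (j in seq_len(4)) {
      expect_gt(rimg[floor(rpts$y[j]) + 1, floor(rpts$x[j]) + 1, 1], 0.5)
    }
  }
  # one-hot pixel check of the convention (x, y) -> (y, side - 1 - x)
  oh <- array(0, c(8, 8, 3)); oh[3, 6, ] <- 1  # x = 5, y = 2
  r <- rotate_image_90(oh, 1)
  p <- rotate_points_90(tibble::tibble(x = 5, y = 2), 8, 1)
  expect_equal(c(p$x, p$y), c(2, 2))
  expect_equal(r[p$y + 1, p$x + 1, 1], 1)
})

test_that("rotation balancing augments target bins without changing labels", {
  cfg <- bench_scene_config(31L)
  cfg$count_range <- c(0L, 8L)
  scenes <- generate_dataset(12, c(zero = 0.3, b1_5 = 0.4, b6_10 = 0.3), cfg)
  ds <- scenes_to_tiles(scenes)
  n_target <- sum(ds$count_bin == "b6_10")
  aug <- balance_by_rotation(ds, target_bins = "b6_10")
  expect_equal(nrow(aug), nrow(ds) + 3 * n_target)
  rot <- aug[grepl("_rot", aug$tile_id), ]
  expect_true(all(rot$count_bin == "b6_10"))
  orig <- ds[match(sub("_rot(90|180|270)$", "", rot$tile_id), ds$tile_id), ]
  expect_equal(rot$count, orig$count)
  expect_equal(rot$class_label, orig$class_label)

  # no tiles in the target bins: unchanged
  unchanged <- balance_by_rotation(ds, target_bins = "b11_15")
  expect_identical(unchanged, ds)

  # non-square tiles are rejected
  bad <- ds[1, ]
  bad$image <- list(array(0, c(10, 20, 3)))
  bad$count_bin <- factor("b6_10", levels = levels(ds$count_bin))
  expect_error(balance_by_rotation(bad, "b6_10"), "square")
})

test_that("training-split manifests carry id, count, label and bin", {
  cfg <- bench_scene_config(41L)
  ds <- scenes_to_tiles(generate_dataset(4, c(zero = 0.5, b1_5 = 0.5), cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  man <- write_manifest(ds, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("tile_id", "count", "class_label", "count_bin"))
  expect_equal(back$count, ds$count)
  expect_equal(back$class_label, ds$class_label)
})
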