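# Shared synthetic benchmark and cached trained models.
#
# The benchmark mirrors the package's scaled-down study conditions: 64 x 64
# tiles with 0-5 well-separated bright blobs over a foliage-like background,
# 200 training and 50 held-out tiles. Models are trained once per
# (kind, seed) and reused across test files.

.bench_cache <- new.env(parent = emptyenv())

bench_scene_config <- function(seed) {
  scene_config(
    image_height_px = 64L, image_width_px = 64L,
    blob_radius_range_px = c(2.5, 5),
    blob_eccentricity_range = c(0, 0.5),
    blob_intensity_range = c(0.75, 1),
    background_texture = "foliage-like",
    occlusion_probability = 0,   # well-separated blobs
    shadow_probability = 0.1,
    seed = seed
  )
}

# counts uniform on 0..5: zero bin w=1/6, counts 1-5 w=5/6
get_benchmark <- function(seed = 101L) {
  key <- paste0("bench_", seed)
  got <- .bench_cache[[key]]
  if (!is.null(got)) return(got)
  cfg <- bench_scene_config(seed)
  train <- scenes_to_tiles(generate_dataset(200, c(zero = 1/6, b1_5 = 5/6), cfg))
  cfg$seed <- seed + 1L
  test <- scenes_to_tiles(generate_dataset(50, c(zero = 1/6, b1_5 = 5/6), cfg))
  out <- list(train = train, test = test)
  assign(key, out, envir = .bench_cache)
  out
}

# desk-scale training settings for the benchmark (see the methods vignette)
get_trained <- function(kind, seed = 1L) {
  key <- paste0(kind, "_", seed)
  got <- .bench_cache[[key]]
  if (!is.null(got)) return(got)
  b <- get_benchmark()
  model <- switch(kind,
    scount = train_scount(
      build_scount(scount_config(seed = seed, epochs = 20L)),
      b$train[, c("image", "count")]),
    wscount = train_wscount(
      build_wscount(wscount_config(seed = seed, pac_epochs = 8L,
                                   count_epochs = 10L, learning_rate = 1e-3)),
      b$train[, c("image", "class_label")]),
    countseg = train_countseg(
      build_countseg(countseg_config(seed = seed, epochs = 12L,
                                     optimizer = "adam", learning_rate = 1e-3)),
      b$train[, c("image", "count")]),
    stop("unknown kind"))
  assign(key, model, envir = .bench_cache)
  model
}

bench_rmse <- function(kind, seed = 1L) {
  b <- get_benchmark()
  m <- get_trained(kind, seed)
  rmse(b$test$count, predict(m, b$test)$count_int)
}
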