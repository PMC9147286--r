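# Seeded synthetic plant scenes with exact ground truth (points, masks, counts).

#' Configuration for the synthetic scene generator
#'
#' Describes one family of synthetic plant-scene tiles: bright, roughly
#' convex "boll" blobs (soft-edged ellipses) over a darker textured
#' background, with optional partial occlusion and cast shadows. Defaults
#' mirror the field conditions the package targets: 500x500 tiles holding
#' 0-15 bolls of variable size and shape.
#'
#' @param image_height_px,image_width_px Tile size in pixels.
#' @param count_range Inclusive integer pair; the scene count is drawn
#'   uniformly from this range.
#' @param blob_radius_range_px Semi-major axis range of the elliptical blobs,
#'   in pixels.
#' @param blob_eccentricity_range Eccentricity range in `[0, 1)`; 0 gives
#'   circles.
#' @param blob_intensity_range Peak blob brightness range in `[0, 1]`.
#' @param background_texture One of `"foliage-like"` (green-dominant base
#'   modulated by low-frequency multiplicative noise), `"noise"` (per-pixel
#'   noise) or `"flat"`.
#' @param occlusion_probability Probability that a newly placed blob is
#'   allowed to overlap (partially occlude) earlier blobs. Occluded blobs
#'   remain counted; every blob keeps at least 25% of its full area visible.
#' @param shadow_probability Per-blob probability of a dark cast-shadow
#'   ellipse painted beside the blob.
#' @param seed Integer seed; `(config, seed)` fully determines the output.
#' @return A `scene_config` object (a validated list).
#' @examples
#' cfg <- scene_config(image_height_px = 64, image_width_px = 64,
#'                     count_range = c(0, 5), blob_radius_range_px = c(4, 8))
#' @export
scene_config <- function(image_height_px = 500L,
                         image_width_px = 500L,
                         count_range = c(0L, 15L),
                         blob_radius_range_px = c(12, 40),
                         blob_eccentricity_range = c(0, 0.6),
                         blob_intensity_range = c(0.7, 1),
                         background_texture = c("foliage-like", "noise", "flat"),
                         occlusion_probability = 0.3,
                         shadow_probability = 0.2,
                         seed = 1L) {
  background_texture <- match.arg(background_texture)
  stopifnot(image_height_px >= 8, image_width_px >= 8)
  if (length(count_range) != 2 || count_range[1] < 0 || count_range[2] < count_range[1]) {
    abort("`count_range` must be an inclusive pair with min >= 0.")
  }
  if (any(blob_radius_range_px <= 0)) abort("`blob_radius_range_px` must be positive.")
  if (any(blob_eccentricity_range < 0) || any(blob_eccentricity_range >= 1)) {
    abort("`blob_eccentricity_range` must lie in [0, 1).")
  }
  if (any(blob_intensity_range < 0) || any(blob_intensity_range > 1)) {
    abort("`blob_intensity_range` must lie in [0, 1].")
  }
  for (p in c(occlusion_probability, shadow_probability)) {
    if (p < 0 || p > 1) abort("probability fields must lie in [0, 1].")
  }
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    count_range = as.integer(count_range),
    blob_radius_range_px = as.numeric(blob_radius_range_px),
    blob_eccentricity_range = as.numeric(blob_eccentricity_range),
    blob_intensity_range = as.numeric(blob_intensity_range),
    background_texture = background_texture,
    occlusion_probability = occlusion_probability,
    shadow_probability = shadow_probability,
    seed = as.integer(seed)
  ), class = "scene_config")
}

runif1 <- function(rng) runif(1, rng[1], rng[2])

make_background <- function(cfg) {
  h <- cfg$image_height_px; w <- cfg$image_width_px
  base <- c(0.16, 0.30, 0.12)  # green-dominant foliage base colour
  img <- array(rep(base, each = h * w), c(h, w, 3))
  if (cfg$background_texture == "flat") return(img)
  if (cfg$background_texture == "noise") {
    img <- img + array(runif(h * w * 3, -0.06, 0.06), c(h, w, 3))
    return(clamp01(img))
  }
  # foliage-like: low-frequency multiplicative field (coarse grid, bilinear
  # upsample) plus faint per-pixel noise
  gh <- max(3L, h %/% 16L); gw <- max(3L, w %/% 16L)
  coarse <- matrix(runif(gh * gw, 0.55, 1.45), gh, gw)
  field <- resize_image(coarse, h, w)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * field
  img <- img + array(runif(h * w * 3, -0.02, 0.02), c(h, w, 3))
  clamp01(img)
}

# rasterize one elliptical blob over its bounding box; returns linear pixel
# indices of the mask and the soft alpha values used for compositing
raster_blob <- function(cx, cy, a, b, ang, h, w) {
  r <- ceiling(a) + 2L
  rows <- max(1L, floor(cy + 1 - r)):min(h, ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(w, ceiling(cx + 1 + r))
  px <- rep(cols - 1, each = length(rows))  # 0-based x
  py <- rep.int(rows - 1, length(cols))     # 0-based y
  dx <- px - cx; dy <- py - cy
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  rad <- sqrt((u / a)^2 + (v / b)^2)
  alpha <- 1 / (1 + exp((rad - 1) / 0.07))
  lin <- rep((cols - 1) * h, each = length(rows)) + rep.int(rows, length(cols))
  keep <- alpha > 1e-3 | rad <= 1
  list(lin = lin[keep], alpha = alpha[keep], inside = rad[keep] <= 1)
}

#' Generate one synthetic scene
#'
#' Draws a boll count uniformly from `count_range`, places soft-edged
#' elliptical blobs with rejection sampling so that every blob (including
#' partially occluded ones, which remain counted) keeps at least 25% of its
#' full elliptical area visible, and composites them over the configured
#' background. The same `(config, seed)` always yields a bit-identical scene.
#'
#' @param config A [scene_config()].
#' @return A `boll_scene`: list with `image` (`H x W x 3` in `[0,1]`),
#'   `points` (tibble of 0-based `x`, `y` blob centres), `masks` (list of
#'   logical `H x W` instance masks), `count`, and `blobs` (tibble of ellipse
#'   parameters, used by the annotation writer).
#' @examples
#' sc <- generate_scene(scene_config(image_height_px = 64, image_width_px = 64,
#'                                   count_range = c(3, 3), seed = 7))
#' sc$count
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, draw_scene(config))
}

draw_scene <- function(cfg) {
  h <- cfg$image_height_px; w <- cfg$image_width_px
  count <- if (cfg$count_range[1] == cfg$count_range[2]) cfg$count_range[1] else
    sample(seq(cfg$count_range[1], cfg$count_range[2]), 1L)
  img <- make_background(cfg)
  owner <- matrix(0L, h, w)           # which blob currently owns each pixel
  blobs <- vector("list", count)
  rasters <- vector("list", count)
  full_area <- numeric(count)
  i <- 1L
  while (i <= count) {
    placed <- FALSE
    for (try in seq_len(250L)) {
      a <- runif1(cfg$blob_radius_range_px)
      ecc <- runif1(cfg$blob_eccentricity_range)
      b <- a * sqrt(1 - ecc^2)
      ang <- runif(1, 0, pi)
      cx <- runif(1, 0, w - 1)
      cy <- runif(1, 0, h - 1)
      allow_overlap <- runif(1) < cfg$occlusion_probability
      rb <- raster_blob(cx, cy, a, b, ang, h, w)
      in_mask <- rb$lin[rb$inside]
      area <- pi * a * b
      if (length(in_mask) < 0.25 * area) next       # too much clipped away
      prev <- owner[in_mask]
      if (!allow_overlap && any(prev > 0L)) next
      if (any(prev > 0L)) {
        # check every earlier blob keeps >= 25% of its full area visible
        lost <- table(prev[prev > 0L])
        ok <- TRUE
        for (nm in names(lost)) {
          j <- as.integer(nm)
          vis_after <- sum(owner == j) - lost[[nm]]
          if (vis_after < 0.25 * full_area[j]) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      owner[in_mask] <- i
      blobs[[i]] <- tibble(cx = cx, cy = cy, a = a, b = b, angle = ang)
      rasters[[i]] <- rb
      full_area[i] <- area
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(paste0("could not place blob ", i, " of ", count, " after 250 tries; ",
                   "loosen `count_range`, shrink `blob_radius_range_px`, or raise ",
                   "`occlusion_probability`."))
    }
    i <- i + 1L
  }
  # composite in placement order (later blobs paint over earlier ones)
  shadow_flags <- if (count > 0) runif(count) < cfg$shadow_probability else logical(0)
  for (i in seq_len(count)) {
    bl <- blobs[[i]]
    if (shadow_flags[i]) {
      sb <- raster_blob(bl$cx + 0.6 * bl$a, bl$cy + 0.8 * bl$b, bl$a, bl$b,
                        bl$angle, h, w)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[sb$lin] <- pl[sb$lin] * (1 - 0.45 * sb$alpha)
        img[, , ch] <- pl
      }
    }
    inten <- runif1(cfg$blob_intensity_range)
    col <- inten * c(1, 0.985, 0.92)  # warm off-white boll colour
    rb <- rasters[[i]]
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[rb$lin] <- pl[rb$lin] * (1 - rb$alpha) + col[ch] * rb$alpha
      img[, , ch] <- pl
    }
  }
  masks <- lapply(seq_len(count), function(i) {
    m <- matrix(FALSE, h, w)
    m[rasters[[i]]$lin[rasters[[i]]$inside]] <- TRUE
    m
  })
  points <- if (count > 0) {
    dplyr::bind_rows(blobs)[, c("cx", "cy")] |> stats::setNames(c("x", "y")) |> as_tibble()
  } else tibble(x = numeric(0), y = numeric(0))
  structure(list(
    image = clamp01(img),
    points = points,
    masks = masks,
    count = count,
    blobs = if (count > 0) dplyr::bind_rows(blobs) else
      tibble(cx = numeric(0), cy = numeric(0), a = numeric(0), b = numeric(0),
             angle = numeric(0)),
    config = cfg
  ), class = "boll_scene")
}

#' @export
print.boll_scene <- function(x, ...) {
  cat(sprintf("<boll_scene> %d x %d px, %d boll(s)\n",
              nrow(x$image), ncol(x$image), x$count))
  invisible(x)
}

# count-bin definitions shared with the annotations module
bin_ranges <- function(subitizing_max = 10L, discard_above = 15L) {
  list(zero = c(0L, 0L),
       b1_5 = c(1L, 5L),
       b6_10 = c(6L, subitizing_max),
       b11_15 = c(subitizing_max + 1L, discard_above),
       dnc = c(discard_above + 1L, discard_above + 5L))
}

#' Generate a dataset of synthetic scenes with controlled count-bin weights
#'
#' Scene counts are drawn by first sampling a count bin from the normalized
#' `bin_weights` (multinomially) and then a count uniformly within the bin,
#' so empirical bin frequencies converge to the weights as `n_scenes` grows.
#' The default weights reproduce the count-bin imbalance typical of field
#' tiles, where counts 1-5 dominate (about half the tiles).
#'
#' @param n_scenes Number of scenes (must be positive).
#' @param bin_weights Named nonnegative weights over
#'   `c("zero","b1_5","b6_10","b11_15","dnc")` (missing names get weight 0;
#'   not all zero).
#' @param config A [scene_config()]; its `count_range` is overridden per
#'   scene by the sampled count, and its `seed` seeds the whole dataset.
#' @return List of `boll_scene` objects.
#' @export
generate_dataset <- function(n_scenes,
                             bin_weights = c(zero = 0.248, b1_5 = 0.499,
                                             b6_10 = 0.191, b11_15 = 0.062),
                             config = scene_config()) {
  if (!is.numeric(n_scenes) || n_scenes <= 0) abort("`n_scenes` must be positive.")
  n_scenes <- as.integer(n_scenes)
  br <- bin_ranges()
  wts <- setNames(numeric(length(br)), names(br))
  if (is.null(names(bin_weights)) || !all(names(bin_weights) %in% names(br))) {
    abort(paste("`bin_weights` must be named with bins among:",
                paste(names(br), collapse = ", ")))
  }
  wts[names(bin_weights)] <- bin_weights
  if (any(wts < 0) || sum(wts) <= 0) abort("`bin_weights` must be nonnegative, not all zero.")
  wts <- wts / sum(wts)
  withr::with_seed(config$seed, {
    bins <- sample(names(wts), n_scenes, replace = TRUE, prob = wts)
    counts <- vapply(bins, function(b) {
      rg <- br[[b]]
      if (rg[1] == rg[2]) rg[1] else sample(seq(rg[1], rg[2]), 1L)
    }, integer(1), USE.NAMES = FALSE)
    seeds <- sample.int(2147483600L, n_scenes)
    lapply(seq_len(n_scenes), function(i) {
      cfg_i <- config
      cfg_i$count_range <- c(counts[i], counts[i])
      cfg_i$seed <- seeds[i]
      generate_scene(cfg_i)
    })
  })
}

#' Convert scenes into a model-ready tile table
#'
#' @param scenes List of `boll_scene` objects.
#' @param ids Optional character tile ids (default `scene_001`, ...).
#' @return Tibble with columns `tile_id`, `image` (list), `points` (list),
#'   `count`, `class_label`, `count_bin`.
#' @export
scenes_to_tiles <- function(scenes, ids = NULL) {
  ids <- ids %||% sprintf("scene_%03d", seq_along(scenes))
  tibble(
    tile_id = ids,
    image = purrr::map(scenes, "image"),
    points = purrr::map(scenes, "points"),
    count = purrr::map_int(scenes, "count"),
    class_label = derive_class_label(purrr::map_int(scenes, "count")),
    count_bin = bin_count(purrr::map_int(scenes, "count"))
  )
}

#' Write scenes as PNG images plus a VGG Image Annotator JSON export
#'
#' Emits one PNG per scene and a single `annotations.json` in the VIA export
#' dialect: each image entry carries one `point` region per boll centre and
#' one `polygon` region per boll outline (the rasterized ellipse boundary),
#' so synthetic data round-trips through [read_via_export()].
#'
#' @param scenes List of `boll_scene` objects.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix for the PNGs.
#' @return Invisibly, a list with `png_paths` and `json_path`.
#' @export
write_scenes <- function(scenes, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- list()
  png_paths <- character(length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    fn <- sprintf("%s_%03d.png", prefix, i)
    path <- file.path(dir, fn)
    png::writePNG(sc$image, path)
    png_paths[i] <- path
    size <- file.info(path)$size
    regions <- list()
    for (j in seq_len(sc$count)) {
      regions[[length(regions) + 1L]] <- list(
        shape_attributes = list(name = "point",
                                cx = sc$points$x[j], cy = sc$points$y[j]),
        region_attributes = list(class = "boll")
      )
      bl <- sc$blobs[j, ]
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      vx <- bl$cx + bl$a * cos(th) * cos(bl$angle) - bl$b * sin(th) * sin(bl$angle)
      vy <- bl$cy + bl$a * cos(th) * sin(bl$angle) + bl$b * sin(th) * cos(bl$angle)
      regions[[length(regions) + 1L]] <- list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = pmin(pmax(vx, 0), ncol(sc$image) - 1),
          all_points_y = pmin(pmax(vy, 0), nrow(sc$image) - 1)),
        region_attributes = list(class = "boll")
      )
    }
    doc[[paste0(fn, size)]] <- list(
      filename = fn, size = size, regions = regions,
      file_attributes = stats::setNames(list(), character(0))
    )
  }
  json_path <- file.path(dir, "annotations.json")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(png_paths = png_paths, json_path = json_path))
}
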