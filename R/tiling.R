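# Decompose full-plant images into fixed-size zero-padded tiles; aggregate
# per-tile counts back to plant level.

#' Tile an image into fixed-size zero-padded windows
#'
#' Splits an `H x W x 3` image into non-overlapping `tile_size_px` square
#' tiles laid out on a grid of `ceiling(H / T)` rows by `ceiling(W / T)`
#' columns. Tile `(r, c)` (0-based) covers the half-open pixel window
#' `[c*T, (c+1)*T) x [r*T, (r+1)*T)`; pixels beyond the source extent are
#' zero in all channels, so padding appears only along the bottom and right
#' borders.
#'
#' @param image `H x W x 3` numeric array.
#' @param tile_size_px Tile side in pixels (default 500, the standard input
#'   window for the counting models).
#' @param source_id Identifier recorded on each tile.
#' @return List with `grid` (a `tile_grid`: source size, tile size, grid
#'   shape, pad widths) and `tiles` (list of `image_tile`s, each with
#'   `pixels`, 0-based `grid_row`/`grid_col`, and `origin_xy`, the 0-based
#'   `(x0, y0)` offset of the tile in the source image), in row-major order.
#' @examples
#' img <- array(runif(64 * 96 * 3), c(64, 96, 3))
#' tl <- tile_image(img, 32)
#' tl$grid$n_rows; tl$grid$n_cols
#' @export
tile_image <- function(image, tile_size_px = 500L, source_id = "image") {
  stop_if_not_image(image)
  tsz <- as.integer(tile_size_px)
  if (tsz < 1) abort("`tile_size_px` must be >= 1.")
  h <- dim(image)[1]; w <- dim(image)[2]
  n_rows <- ceiling(h / tsz); n_cols <- ceiling(w / tsz)
  grid <- structure(list(
    source_height_px = h, source_width_px = w, tile_size_px = tsz,
    n_rows = n_rows, n_cols = n_cols,
    pad_bottom_px = n_rows * tsz - h, pad_right_px = n_cols * tsz - w,
    source_id = source_id
  ), class = "tile_grid")
  tiles <- vector("list", n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      k <- k + 1L
      px <- array(0, c(tsz, tsz, 3))
      rows <- (r * tsz + 1L):min((r + 1L) * tsz, h)
      cols <- (cc * tsz + 1L):min((cc + 1L) * tsz, w)
      px[seq_along(rows), seq_along(cols), ] <- image[rows, cols, , drop = FALSE]
      tiles[[k]] <- structure(list(
        pixels = px, grid_row = r, grid_col = cc,
        origin_xy = c(cc * tsz, r * tsz), source_id = source_id
      ), class = "image_tile")
    }
  }
  list(grid = grid, tiles = tiles)
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d px source -> %d x %d tiles of %d px (pad %d bottom, %d right)\n",
              x$source_height_px, x$source_width_px, x$n_rows, x$n_cols,
              x$tile_size_px, x$pad_bottom_px, x$pad_right_px))
  invisible(x)
}

#' Assign annotation points to tiles
#'
#' Each point goes to exactly one tile by the half-open window rule
#' (`floor(x / T)`, `floor(y / T)`), so a point exactly on a boundary
#' belongs to the higher-index tile and per-tile counts always sum to the
#' total number of points.
#'
#' @param points Data frame with 0-based pixel columns `x`, `y`.
#' @param grid A `tile_grid` from [tile_image()].
#' @return Tibble with one row per grid cell: `grid_row`, `grid_col`,
#'   `count` (rows in row-major grid order, including zero-count tiles).
#' @export
assign_points_to_tiles <- function(points, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  x <- points$x; y <- points$y
  bad <- which(x < 0 | y < 0 | x >= grid$source_width_px | y >= grid$source_height_px)
  if (length(bad)) {
    abort(sprintf("point(s) outside the source extent: %s",
                  paste(sprintf("(%g, %g)", x[bad], y[bad]), collapse = ", ")))
  }
  tsz <- grid$tile_size_px
  gr <- floor(y / tsz); gc <- floor(x / tsz)
  cells <- tidyr::expand_grid(grid_row = seq_len(grid$n_rows) - 1L,
                              grid_col = seq_len(grid$n_cols) - 1L)
  if (length(x) == 0) return(dplyr::mutate(cells, count = 0L))
  tab <- tibble(grid_row = as.integer(gr), grid_col = as.integer(gc)) |>
    dplyr::count(.data$grid_row, .data$grid_col, name = "count")
  dplyr::left_join(cells, tab, by = c("grid_row", "grid_col")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L))
}

#' Sum per-tile counts to a plant-level total
#'
#' @param tile_counts Numeric vector of nonnegative per-tile counts.
#' @return Their arithmetic sum (0 for an empty vector).
#' @export
aggregate_plant_count <- function(tile_counts) {
  if (length(tile_counts) == 0) return(0)
  if (any(!is.finite(tile_counts)) || any(tile_counts < 0)) {
    abort("`tile_counts` must be finite and nonnegative.")
  }
  sum(tile_counts)
}

#' Reassemble tiles into the source image
#'
#' Inverse of [tile_image()]: stitches tiles in grid order and crops the
#' bottom/right zero padding, reproducing the source image exactly.
#'
#' @param tiles List of `image_tile`s.
#' @param grid The matching `tile_grid`.
#' @return `H x W x 3` array.
#' @export
stitch_tiles <- function(tiles, grid) {
  tsz <- grid$tile_size_px
  full <- array(0, c(grid$n_rows * tsz, grid$n_cols * tsz, 3))
  for (tl in tiles) {
    rows <- (tl$grid_row * tsz + 1L):((tl$grid_row + 1L) * tsz)
    cols <- (tl$grid_col * tsz + 1L):((tl$grid_col + 1L) * tsz)
    full[rows, cols, ] <- tl$pixels
  }
  full[seq_len(grid$source_height_px), seq_len(grid$source_width_px), , drop = FALSE]
}
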