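# Shared helpers: seed derivation, image resizing, exact 90-degree rotations.

#' Derive a per-stage random seed from a global seed
#'
#' One global seed fans out to independent per-stage seeds by a fixed integer
#' derivation, so that pipeline stages (scene synthesis, model training for
#' each method, evaluation shuffling) are individually reproducible. The
#' result is always a positive integer below 2^31.
#'
#' @param seed Integer global seed.
#' @param label Character stage label, e.g. `"scount"` or `"synth"`.
#' @return A single positive integer seed.
#' @examples
#' derive_seed(1, "scount")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  s <- (abs(as.numeric(seed)) %% 94906249) * 22639 + h * 7919 + 17
  as.integer(s %% 2147483629 + 1)
}

#' Resize an image array with bilinear interpolation
#'
#' Thin wrapper over [EBImage::resize()] operating on plain `H x W x 3` (or
#' `H x W`) arrays of values in `[0, 1]`.
#'
#' @param img Numeric array, `H x W x C` or `H x W`.
#' @param height,width Target size in pixels.
#' @return Resized array with the same number of channels.
#' @export
resize_image <- function(img, height, width) {
  d <- dim(img)
  if (d[1] == height && d[2] == width) return(img)
  out <- EBImage::resize(img, w = height, h = width, filter = "bilinear")
  # EBImage returns an Image or array; coerce to a plain array
  a <- as.numeric(out)
  dim(a) <- dim(out)
  a
}

#' Rotate an image array by a multiple of 90 degrees
#'
#' Rotation is exact (an index permutation, no interpolation) and
#' counter-clockwise in image coordinates (origin top-left, y down). One
#' quarter turn maps the pixel at 0-based `(x, y)` to `(y, W - 1 - x)`; the
#' matching point transform is [rotate_points_90()].
#'
#' @param img `H x W` matrix or `H x W x C` array (square for `k != 0`).
#' @param k Number of counter-clockwise quarter turns (0-3).
#' @return Rotated array of the same shape.
#' @seealso [rotate_points_90()]
#' @export
rotate_image_90 <- function(img, k = 1L) {
  k <- as.integer(k) %% 4L
  if (k == 0L) return(img)
  d <- dim(img)
  if (d[1] != d[2]) abort("rotate_image_90() requires a square image.")
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  rotm <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (length(d) == 2) return(rotm(img))
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- rotm(img[, , ch])
  out
}

#' Rotate point coordinates with the image rotation convention
#'
#' Applies the same counter-clockwise quarter-turn convention as
#' [rotate_image_90()]: one turn maps `(x, y) -> (y, side - 1 - x)` in 0-based
#' pixel coordinates, so a point annotated on a blob lands on the same blob
#' pixel after the image array is rotated.
#'
#' @param points Data frame with numeric columns `x`, `y`.
#' @param side Side length of the (square) image in pixels.
#' @param k Number of counter-clockwise quarter turns (0-3).
#' @return The data frame with rotated `x`, `y`.
#' @export
rotate_points_90 <- function(points, side, k = 1L) {
  k <- as.integer(k) %% 4L
  x <- points$x; y <- points$y
  for (i in seq_len(k)) {
    tmp <- x
    x <- y
    y <- side - 1 - tmp
  }
  points$x <- x
  points$y <- y
  points
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# round-half-up on nonnegative reals, clipped at zero: the package's single
# rule for turning a real-valued count into an integer count
count_to_int <- function(x) pmax(0L, as.integer(floor(x + 0.5)))

stop_if_not_image <- function(img, arg = "image") {
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3)) {
    abort(sprintf("`%s` must be an H x W x 3 array (3-channel RGB).", arg))
  }
  invisible(img)
}
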