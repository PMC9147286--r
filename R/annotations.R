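# Annotation handling: VGG Image Annotator (VIA) JSON import/export, label
# derivation from point counts, count binning, rotation-based balancing.

#' Derive presence/absence class labels from counts
#'
#' The class label used by the weakly supervised models is always derived
#' from the point-label count, never stored independently: a count greater
#' than zero is `"present"`, a count of zero is `"absent"`.
#'
#' @param count Integer vector of nonnegative counts.
#' @return Character vector of `"present"` / `"absent"`.
#' @examples
#' derive_class_label(c(0, 5, 1))
#' @export
derive_class_label <- function(count) {
  if (any(count < 0)) abort("`count` must be nonnegative.")
  ifelse(count > 0, "present", "absent")
}

#' Bin counts into the standard counting ranges
#'
#' Counts are grouped into the ranges used throughout training and
#' evaluation: `zero` (0), `b1_5` (1-5), `b6_10` (6 to `subitizing_max`),
#' `b11_15` (`subitizing_max + 1` to `discard_above`, the challenging
#' examples beyond the subitizing range), and `dnc` ("did not count",
#' above `discard_above`; such tiles are flagged and excluded from training
#' but never silently deleted).
#'
#' @param count Integer vector of nonnegative counts.
#' @param subitizing_max Upper end of the subitizing range (default 10).
#' @param discard_above Counts above this are `dnc` (default 15).
#' @return Factor with levels `zero, b1_5, b6_10, b11_15, dnc`.
#' @examples
#' bin_count(c(0, 3, 10, 15, 16))
#' @export
bin_count <- function(count, subitizing_max = 10L, discard_above = 15L) {
  if (any(count < 0)) abort("`count` must be nonnegative.")
  lv <- c("zero", "b1_5", "b6_10", "b11_15", "dnc")
  out <- ifelse(count == 0, "zero",
         ifelse(count <= 5, "b1_5",
         ifelse(count <= subitizing_max, "b6_10",
         ifelse(count <= discard_above, "b11_15", "dnc"))))
  factor(out, levels = lv)
}

#' Read a VGG Image Annotator JSON export
#'
#' Parses the VIA export structure (a map from image key to `filename`,
#' `size` and a list of `regions`, each with `shape_attributes` of type
#' `"point"` or `"polygon"`). Unknown region shapes are skipped with a
#' warning; a region missing its coordinates is an error naming the image.
#' The count, class label and count bin of each tile are derived from its
#' point regions.
#'
#' @param json Path to a VIA JSON export, or an already-parsed list.
#' @param subitizing_max,discard_above Passed to [bin_count()].
#' @return Tibble with one row per image: `tile_id`, `points` (list of
#'   tibbles `x`, `y`, `instance_id`), `polygons` (list of vertex tibbles),
#'   `count`, `class_label`, `count_bin`.
#' @export
read_via_export <- function(json, subitizing_max = 10L, discard_above = 15L) {
  doc <- if (is.character(json)) {
    tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
             error = function(e) abort(paste("malformed VIA JSON:", conditionMessage(e))))
  } else json
  rows <- purrr::imap(doc, function(entry, key) {
    fname <- entry$filename %||% key
    pts <- list(); polys <- list()
    for (rg in entry$regions %||% list()) {
      sa <- rg$shape_attributes
      if (is.null(sa$name)) abort(sprintf("region without shape type in image '%s'", fname))
      if (sa$name == "point") {
        if (is.null(sa$cx) || is.null(sa$cy)) {
          abort(sprintf("point region missing coordinates in image '%s'", fname))
        }
        pts[[length(pts) + 1L]] <- c(x = as.numeric(sa$cx), y = as.numeric(sa$cy))
      } else if (sa$name == "polygon") {
        if (is.null(sa$all_points_x) || is.null(sa$all_points_y)) {
          abort(sprintf("polygon region missing coordinates in image '%s'", fname))
        }
        polys[[length(polys) + 1L]] <- tibble(
          x = as.numeric(unlist(sa$all_points_x)),
          y = as.numeric(unlist(sa$all_points_y)))
      } else {
        warn(sprintf("skipping region of unknown shape '%s' in image '%s'", sa$name, fname))
      }
    }
    points <- if (length(pts)) {
      m <- do.call(rbind, pts)
      tibble(x = m[, "x"], y = m[, "y"], instance_id = seq_len(nrow(m)))
    } else tibble(x = numeric(0), y = numeric(0), instance_id = integer(0))
    n_pts <- nrow(points)
    tibble(tile_id = fname, points = list(points), polygons = list(polys),
           count = n_pts)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(tile_id = character(0), points = list(), polygons = list(),
                  count = integer(0), class_label = character(0),
                  count_bin = bin_count(integer(0))))
  }
  out$class_label <- derive_class_label(out$count)
  out$count_bin <- bin_count(out$count, subitizing_max, discard_above)
  out
}

#' Balance a tile dataset by rotation augmentation
#'
#' Mirrors the standard balancing step for count-imbalanced tile sets: each
#' selected tile from the target (under-represented) count bins contributes
#' three additional copies rotated by 90, 180 and 270 degrees. Point
#' coordinates are rotated with the same convention as the pixels
#' ([rotate_points_90()]), so counts, class labels and bins are unchanged.
#'
#' @param dataset Tile tibble as returned by [scenes_to_tiles()] (columns
#'   `tile_id`, `image`, `points`, `count`, `class_label`, `count_bin`).
#' @param target_bins Count bins to augment (default the sparse upper bins).
#' @param n_sample Optional number of tiles to sample (with a seeded RNG)
#'   from the target bins; default uses all of them.
#' @param seed Seed for the sampling step.
#' @return The dataset with the rotated copies appended (`tile_id` gains a
#'   `_rot90/_rot180/_rot270` suffix).
#' @export
balance_by_rotation <- function(dataset, target_bins = c("b6_10", "b11_15"),
                                n_sample = NULL, seed = 1L) {
  sel <- which(as.character(dataset$count_bin) %in% target_bins)
  if (length(sel) == 0) return(dataset)
  if (!is.null(n_sample)) {
    n_sample <- min(n_sample, length(sel))
    sel <- withr::with_seed(seed, sample(sel, n_sample))
  }
  extra <- purrr::map(sel, function(i) {
    img <- dataset$image[[i]]
    d <- dim(img)
    if (d[1] != d[2]) abort(sprintf("tile '%s' is not square; cannot rotate.",
                                    dataset$tile_id[i]))
    purrr::map(1:3, function(k) {
      row <- dataset[i, ]
      row$tile_id <- paste0(row$tile_id, "_rot", 90 * k)
      row$image <- list(rotate_image_90(img, k))
      row$points <- list(rotate_points_90(dataset$points[[i]], d[1], k))
      row
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  dplyr::bind_rows(dataset, extra)
}

#' Write a training-split manifest
#'
#' @param dataset Tile tibble (see [scenes_to_tiles()]).
#' @param path CSV output path.
#' @return The manifest tibble (`tile_id`, `count`, `class_label`,
#'   `count_bin`), invisibly.
#' @export
write_manifest <- function(dataset, path) {
  man <- dplyr::select(dataset, "tile_id", "count", "class_label", "count_bin")
  write.csv(man, path, row.names = FALSE)
  invisible(man)
}
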