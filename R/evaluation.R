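# Evaluation protocol: RMSE per count bin over repeated training runs,
# median-of-runs error histograms, least-squares calibration against the
# ground truth, and plant-level totals.

#' Root mean squared error
#'
#' @param ground_truth,predicted Equal-length nonempty numeric vectors.
#' @return `sqrt(mean((ground_truth - predicted)^2))`.
#' @examples
#' rmse(c(0, 3), c(1, 5))
#' @export
rmse <- function(ground_truth, predicted) {
  if (length(ground_truth) != length(predicted) || length(ground_truth) == 0) {
    abort("`ground_truth` and `predicted` must have equal nonzero length.")
  }
  sqrt(mean((ground_truth - predicted)^2))
}

#' Median of repeated-run predictions
#'
#' For an odd number of runs this is the ordinary median; for an even
#' number the lower median is taken, so the result is always one of the
#' observed integer counts.
#'
#' @param runs Nonempty numeric vector of per-run predictions for one tile.
#' @return A single count.
#' @examples
#' median_prediction(c(3, 5, 4, 4, 9))
#' median_prediction(c(1, 2, 3, 4))  # lower median: 2
#' @export
median_prediction <- function(runs) {
  if (length(runs) == 0) abort("`runs` must be nonempty.")
  s <- sort(runs)
  s[ceiling(length(s) / 2)]
}

#' Signed-error histogram and the within-±3 fraction
#'
#' Errors follow the convention `error = ground truth - prediction`, so
#' positive errors signify under-counting.
#'
#' @param ground_truth,predicted Equal-length numeric vectors.
#' @return List with `histogram` (tibble `error`, `n` at integer
#'   resolution) and `fraction_within_3` (share of tiles with
#'   `|error| <= 3`).
#' @export
error_histogram <- function(ground_truth, predicted) {
  if (length(ground_truth) != length(predicted)) abort("length mismatch.")
  err <- round(ground_truth - predicted)
  hist <- tibble(error = err) |>
    dplyr::count(.data$error, name = "n") |>
    dplyr::arrange(.data$error)
  list(histogram = hist, fraction_within_3 = mean(abs(err) <= 3))
}

#' Least-squares calibration line
#'
#' Ordinary least squares of the predictions on the ground truth, with the
#' coefficient of determination; a perfectly calibrated counter attains the
#' identity line Y = X with R-squared 1.
#'
#' @param ground_truth,predicted Equal-length numeric vectors;
#'   `ground_truth` must take at least two distinct values.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
least_squares_fit <- function(ground_truth, predicted) {
  if (length(ground_truth) != length(predicted) || length(ground_truth) < 2) {
    abort("need equal-length vectors with at least 2 points.")
  }
  if (length(unique(ground_truth)) < 2) {
    abort("`ground_truth` is constant; the least-squares fit is degenerate.")
  }
  fit <- lm(predicted ~ ground_truth)
  # summary.lm warns on an exactly collinear fit; R^2 is still well defined
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Evaluate repeated training runs on a test set
#'
#' Implements the repeated-runs protocol: each of `K` independently trained
#' models predicts every test tile; RMSE is computed per run (overall and
#' per count bin) and summarized as mean ± sd across runs, while the error
#' histogram, within-±3 fraction, least-squares calibration and bubble-plot
#' data use the per-tile median of the `K` predictions.
#'
#' @param predictions Long tibble with columns `tile_id`, `truth`, `run`,
#'   `pred` (integer counts; use [evaluate_model()] to produce it from
#'   fitted models).
#' @param subitizing_max,discard_above Bin edges for [bin_count()].
#' @return An `eval_report`: list with `by_bin`, `overall`, `histogram`,
#'   `fraction_within_3`, `fit`, `bubble`, `median_pred`, `k_runs`.
#' @export
evaluate_predictions <- function(predictions, subitizing_max = 10L,
                                 discard_above = 15L) {
  need <- c("tile_id", "truth", "run", "pred")
  if (!all(need %in% names(predictions))) {
    abort(paste("`predictions` needs columns:", paste(need, collapse = ", ")))
  }
  predictions <- dplyr::mutate(predictions,
    bin = bin_count(.data$truth, subitizing_max, discard_above))
  per_run_bin <- predictions |>
    dplyr::group_by(.data$run, .data$bin) |>
    dplyr::summarise(rmse = rmse(.data$truth, .data$pred), .groups = "drop")
  by_bin <- per_run_bin |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     sd_rmse = if (dplyr::n() > 1) sd(.data$rmse) else 0,
                     .groups = "drop")
  per_run <- predictions |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(rmse = rmse(.data$truth, .data$pred), .groups = "drop")
  overall <- tibble(mean_rmse = mean(per_run$rmse),
                    sd_rmse = if (nrow(per_run) > 1) sd(per_run$rmse) else 0)
  med <- predictions |>
    dplyr::group_by(.data$tile_id, .data$truth) |>
    dplyr::summarise(pred = median_prediction(.data$pred), .groups = "drop")
  eh <- error_histogram(med$truth, med$pred)
  fit <- if (length(unique(med$truth)) >= 2) {
    least_squares_fit(med$truth, med$pred)
  } else NULL
  bubble <- med |> dplyr::count(.data$truth, .data$pred, name = "n_tiles")
  structure(list(by_bin = by_bin, overall = overall,
                 histogram = eh$histogram,
                 fraction_within_3 = eh$fraction_within_3,
                 fit = fit, bubble = bubble, median_pred = med,
                 per_run = per_run, k_runs = length(unique(predictions$run))),
            class = "eval_report")
}

#' @rdname evaluate_predictions
#' @param models A fitted counting model or a list of `K` of them (the
#'   repeated runs); anything with a `predict` method returning `count_int`.
#' @param test_set Tibble with list-column `image`, integer `count` and
#'   optionally `tile_id`.
#' @param round_counts If `TRUE` (default) RMSE is computed on rounded
#'   integer predictions, consistent with count semantics; `FALSE` uses the
#'   real-valued predictions.
#' @export
evaluate_model <- function(models, test_set, subitizing_max = 10L,
                           discard_above = 15L, round_counts = TRUE) {
  if (!is.list(models) || inherits(models, "count_model")) models <- list(models)
  ids <- test_set$tile_id %||% sprintf("tile_%03d", seq_len(nrow(test_set)))
  preds <- purrr::imap(models, function(m, k) {
    pr <- predict(m, test_set)
    tibble(tile_id = ids, truth = test_set$count, run = k,
           pred = if (round_counts) pr$count_int else pr$count_real)
  }) |> dplyr::bind_rows()
  evaluate_predictions(preds, subitizing_max, discard_above)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d run(s); overall RMSE %.3f +/- %.3f; %.1f%% of errors within +/-3\n",
              x$k_runs, x$overall$mean_rmse, x$overall$sd_rmse,
              100 * x$fraction_within_3))
  if (!is.null(x$fit)) {
    cat(sprintf("  calibration: pred = %.3f * truth + %.3f (R^2 = %.3f)\n",
                x$fit$slope, x$fit$intercept, x$fit$r_squared))
  }
  print(x$by_bin)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$by_bin

#' @export
glance.eval_report <- function(x, ...) {
  tibble(k_runs = x$k_runs,
         overall_rmse = x$overall$mean_rmse,
         sd_rmse = x$overall$sd_rmse,
         fraction_within_3 = x$fraction_within_3,
         slope = if (is.null(x$fit)) NA_real_ else x$fit$slope,
         intercept = if (is.null(x$fit)) NA_real_ else x$fit$intercept,
         r_squared = if (is.null(x$fit)) NA_real_ else x$fit$r_squared)
}

#' Plant-level evaluation: tile, predict, sum
#'
#' Each full plant image is tiled, every tile is predicted by every run's
#' model, and per-tile counts are summed to a plant total, reported as
#' mean ± sd across runs next to the ground-truth total.
#'
#' @param models A fitted model or list of `K` fitted models.
#' @param plants Tibble with `plant_id`, list-column `image`, and either
#'   `truth` (integer totals) or list-column `points` (0-based `x`, `y`;
#'   totals are recomputed by tile assignment).
#' @param tile_size_px Tile side (default 500).
#' @return A `plant_report`: list with `totals` (long tibble) and `summary`
#'   (per plant mean ± sd, truth).
#' @export
evaluate_plants <- function(models, plants, tile_size_px = 500L) {
  if (!is.list(models) || inherits(models, "count_model")) models <- list(models)
  rows <- purrr::pmap(list(seq_len(nrow(plants))), function(i) {
    img <- plants$image[[i]]
    tl <- tile_image(img, tile_size_px, source_id = plants$plant_id[i])
    truth <- if ("truth" %in% names(plants)) plants$truth[i] else {
      sum(assign_points_to_tiles(plants$points[[i]], tl$grid)$count)
    }
    tiles <- purrr::map(tl$tiles, "pixels")
    purrr::imap(models, function(m, k) {
      tibble(plant_id = plants$plant_id[i], truth = truth, run = k,
             total = aggregate_plant_count(predict(m, tiles)$count_int))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summary <- rows |>
    dplyr::group_by(.data$plant_id, .data$truth) |>
    dplyr::summarise(mean_total = mean(.data$total),
                     sd_total = if (dplyr::n() > 1) sd(.data$total) else 0,
                     .groups = "drop")
  structure(list(totals = rows, summary = summary,
                 k_runs = length(models), tile_size_px = tile_size_px),
            class = "plant_report")
}

#' @export
print.plant_report <- function(x, ...) {
  cat(sprintf("<plant_report> %d plant(s), %d run(s), tile size %d px\n",
              nrow(x$summary), x$k_runs, x$tile_size_px))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.plant_report <- function(x, ...) x$summary
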