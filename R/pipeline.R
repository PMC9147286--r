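# End-to-end orchestration: tile -> predict -> aggregate -> evaluate, with
# seeded reproducibility and a manifest sufficient to reproduce the run.

#' Read a run configuration (YAML or JSON)
#'
#' Flags given programmatically override file keys; defaults fill the rest.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @param ... Key overrides.
#' @return A `run_config` list.
#' @export
read_run_config <- function(config = list(), ...) {
  base <- if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: '%s'", config))
    if (grepl("\\.json$", config)) jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  over <- list(...)
  cfg <- modifyList(list(
    model = "scount", tile_size_px = 500L, subitizing_max = 10L,
    discard_above = 15L, seed = 1L, checkpoints = NULL, images = NULL,
    annotations = NULL, synth = NULL, output_dir = tempfile("run_")
  ), modifyList(as.list(base), over))
  cfg$tile_size_px <- as.integer(cfg$tile_size_px)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

stage_abort <- function(stage, msg) {
  abort(sprintf("stage '%s' failed: %s", stage, msg))
}

load_plants <- function(cfg) {
  if (!is.null(cfg$images)) {
    missing <- cfg$images[!file.exists(cfg$images)]
    if (length(missing)) {
      stage_abort("load", paste("image file(s) not found:", paste(missing, collapse = ", ")))
    }
    imgs <- lapply(cfg$images, function(p) {
      a <- png::readPNG(p)
      if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
      a[, , 1:3, drop = FALSE]
    })
    pts <- NULL
    if (!is.null(cfg$annotations)) {
      ann <- read_via_export(cfg$annotations)
      pts <- lapply(basename(cfg$images), function(fn) {
        row <- ann[ann$tile_id == fn, ]
        if (nrow(row) == 0) tibble(x = numeric(0), y = numeric(0)) else row$points[[1]]
      })
    }
    tibble(plant_id = basename(cfg$images), image = imgs,
           points = pts %||% purrr::map(imgs, function(...) tibble(x = numeric(0), y = numeric(0))))
  } else if (!is.null(cfg$synth)) {
    sy <- cfg$synth
    n_plants <- sy$n_plants %||% 3L
    sc_args <- sy[setdiff(names(sy), "n_plants")]
    seeds <- (derive_seed(cfg$seed, "synth") + seq_len(n_plants)) %% 2147483600L
    plants <- purrr::map(seq_len(n_plants), function(i) {
      args <- modifyList(sc_args, list(seed = seeds[i]))
      generate_scene(do.call(scene_config, args))
    })
    tibble(plant_id = sprintf("plant_%02d", seq_len(n_plants)),
           image = purrr::map(plants, "image"),
           points = purrr::map(plants, "points"))
  } else {
    stage_abort("load", "config must provide `images` or `synth`.")
  }
}

#' Run the counting workflow end to end
#'
#' Executes tile -> predict -> aggregate -> evaluate for one or more full
#' plant images against one or more frozen model checkpoints, writing every
#' artifact (tile manifest, per-tile predictions, plant report, run
#' manifest with config hash and seed) under `output_dir`. A rerun with the
#' same config and seed reproduces the reports byte-identically for
#' deterministic (frozen) models.
#'
#' @param config A [read_run_config()] input: path, list, or `run_config`.
#'   Keys: `model`, `checkpoints` (paths to saved models, the K runs),
#'   `images` + optional `annotations` (VIA JSON) or `synth` (scene-config
#'   fields + `n_plants`), `tile_size_px`, `seed`, `output_dir`.
#' @param ... Overrides passed to [read_run_config()].
#' @return List with `plant_report`, `tile_predictions` and `paths` of the
#'   written artifacts.
#' @export
run_end2end <- function(config = list(), ...) {
  cfg <- read_run_config(config, ...)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cfg$checkpoints)) stage_abort("load", "no `checkpoints` given.")
  models <- lapply(cfg$checkpoints, function(p) {
    if (!file.exists(p)) stage_abort("load", sprintf("model checkpoint not found: '%s'", p))
    load_count_model(p)
  })
  plants <- load_plants(cfg)

  # tile + per-tile predictions
  tile_rows <- list()
  grids <- list()
  for (i in seq_len(nrow(plants))) {
    tl <- tryCatch(tile_image(plants$image[[i]], cfg$tile_size_px,
                              source_id = plants$plant_id[i]),
                   error = function(e) stage_abort("tile", conditionMessage(e)))
    grids[[plants$plant_id[i]]] <- tl$grid
    tile_counts <- assign_points_to_tiles(plants$points[[i]], tl$grid)
    for (k in seq_along(models)) {
      pr <- tryCatch(predict(models[[k]], purrr::map(tl$tiles, "pixels")),
                     error = function(e) stage_abort("predict", conditionMessage(e)))
      tile_rows[[length(tile_rows) + 1L]] <- tibble(
        plant_id = plants$plant_id[i],
        grid_row = purrr::map_int(tl$tiles, "grid_row"),
        grid_col = purrr::map_int(tl$tiles, "grid_col"),
        truth = tile_counts$count, run = k, pred = pr$count_int)
    }
  }
  tile_pred <- dplyr::bind_rows(tile_rows)

  totals <- tile_pred |>
    dplyr::group_by(.data$plant_id, .data$run) |>
    dplyr::summarise(truth = sum(.data$truth),
                     total = aggregate_plant_count(.data$pred), .groups = "drop")
  summary <- totals |>
    dplyr::group_by(.data$plant_id, .data$truth) |>
    dplyr::summarise(mean_total = mean(.data$total),
                     sd_total = if (dplyr::n() > 1) sd(.data$total) else 0,
                     .groups = "drop")
  plant_report <- structure(list(totals = dplyr::select(totals, -"truth") |>
                                   dplyr::left_join(dplyr::distinct(totals, .data$plant_id, .data$truth),
                                                    by = "plant_id"),
                                 summary = summary, k_runs = length(models),
                                 tile_size_px = cfg$tile_size_px),
                            class = "plant_report")

  # artifacts
  cfg_path <- file.path(cfg$output_dir, "config.json")
  cfg_out <- unclass(cfg)
  cfg_out$output_dir <- NULL  # path varies between reruns; keep reports stable
  jsonlite::write_json(cfg_out, cfg_path, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("bollcount")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    tile_grids = lapply(grids, function(g) unclass(g)),
    supervision = lapply(models, function(m) m$supervision_log)
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  report_path <- file.path(cfg$output_dir, "report.json")
  jsonlite::write_json(list(
    plant_totals = summary,
    per_run_totals = totals,
    tile_predictions = tile_pred
  ), report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  list(plant_report = plant_report, tile_predictions = tile_pred,
       paths = list(config = cfg_path, manifest = manifest_path,
                    report = report_path))
}

# ---- minimal command-line front end (used by inst/cli/weakcount.R) ----

parse_cli_flags <- function(args) {
  flags <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- gsub("^--", "", a)
      if (i < length(args) && !grepl("^--", args[i + 1L])) {
        flags[[gsub("-", "_", key)]] <- args[i + 1L]
        i <- i + 2L
      } else {
        flags[[gsub("-", "_", key)]] <- TRUE
        i <- i + 1L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, pos = pos)
}

cli_main <- function(args) {
  if (length(args) == 0) {
    cat("usage: weakcount <synth|tile|train|predict|evaluate|end2end> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  pa <- parse_cli_flags(args[-1])
  f <- pa$flags
  seed <- as.integer(f$seed %||% 1L)
  switch(cmd,
    synth = {
      out <- f$out %||% "synth_out"
      n <- as.integer(f$n %||% 10L)
      side <- as.integer(f$side %||% 500L)
      cfg <- scene_config(image_height_px = side, image_width_px = side,
                          seed = derive_seed(seed, "synth"))
      scenes <- generate_dataset(n, config = cfg)
      write_scenes(scenes, out)
      cat(sprintf("wrote %d scenes + annotations.json to %s\n", n, out))
      invisible(0L)
    },
    tile = {
      out <- f$out %||% "tiles_out"
      tsz <- as.integer(f$tile_size %||% 500L)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (p in pa$pos) {
        img <- png::readPNG(p)[, , 1:3, drop = FALSE]
        tl <- tile_image(img, tsz, source_id = basename(p))
        for (t in tl$tiles) {
          png::writePNG(t$pixels, file.path(out, sprintf("%s_r%d_c%d.png",
            tools::file_path_sans_ext(basename(p)), t$grid_row, t$grid_col)))
        }
        jsonlite::write_json(c(unclass(tl$grid),
                               list(origins = lapply(tl$tiles, function(t)
                                 c(t$origin_xy, t$grid_row, t$grid_col)))),
                             file.path(out, sprintf("%s_manifest.json",
                               tools::file_path_sans_ext(basename(p)))),
                             auto_unbox = TRUE, digits = NA)
      }
      cat(sprintf("tiled %d image(s) into %s\n", length(pa$pos), out))
      invisible(0L)
    },
    train = {
      model_kind <- pa$pos[1] %||% "scount"
      data_dir <- f$data %||% abort("train: --data <dir with PNGs + annotations.json> required")
      out <- f$out %||% paste0(model_kind, ".rds")
      epochs <- as.integer(f$epochs %||% 10L)
      side <- as.integer(f$input_side %||% 64L)
      ann <- read_via_export(file.path(data_dir, "annotations.json"))
      imgs <- lapply(file.path(data_dir, ann$tile_id), function(p)
        png::readPNG(p)[, , 1:3, drop = FALSE])
      ds <- tibble(image = imgs, count = ann$count, class_label = ann$class_label)
      ds <- ds[bin_count(ds$count) != "dnc", ]
      model <- switch(model_kind,
        scount = train_scount(build_scount(scount_config(input_side_px = side,
                   epochs = epochs, seed = derive_seed(seed, "scount"))),
                 dplyr::select(ds, "image", "count")),
        wscount = train_wscount(build_wscount(wscount_config(
                   seed = derive_seed(seed, "wscount"))),
                 dplyr::select(ds, "image", "class_label"),
                 pac_epochs = epochs, count_epochs = epochs),
        countseg = train_countseg(build_countseg(countseg_config(input_side_px = side,
                   seed = derive_seed(seed, "countseg"))),
                 dplyr::select(ds, "image", "count"), epochs = epochs),
        abort(sprintf("unknown model '%s'", model_kind)))
      save_count_model(model, out)
      cat(sprintf("trained %s on %d tiles -> %s\n", model_kind, nrow(ds), out))
      invisible(0L)
    },
    predict = {
      model <- load_count_model(f$checkpoint %||% abort("predict: --checkpoint required"))
      for (p in pa$pos) {
        img <- png::readPNG(p)[, , 1:3, drop = FALSE]
        pr <- predict(model, img)
        cat(sprintf("%s\t%d\t%.3f\n", basename(p), pr$count_int, pr$count_real))
      }
      invisible(0L)
    },
    evaluate = {
      model <- load_count_model(f$checkpoint %||% abort("evaluate: --checkpoint required"))
      data_dir <- f$data %||% abort("evaluate: --data required")
      ann <- read_via_export(file.path(data_dir, "annotations.json"))
      imgs <- lapply(file.path(data_dir, ann$tile_id), function(p)
        png::readPNG(p)[, , 1:3, drop = FALSE])
      rep <- evaluate_model(model, tibble(tile_id = ann$tile_id, image = imgs,
                                          count = ann$count))
      print(rep)
      if (!is.null(f$out)) {
        jsonlite::write_json(list(by_bin = rep$by_bin, overall = rep$overall,
                                  fraction_within_3 = rep$fraction_within_3),
                             f$out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      }
      invisible(0L)
    },
    end2end = {
      res <- run_end2end(f$config %||% list(),
                         seed = seed,
                         output_dir = f$out %||% "end2end_out")
      print(res$plant_report)
      invisible(0L)
    },
    {
      cat(sprintf("unknown command '%s'\n", cmd))
      invisible(1L)
    }
  )
}
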