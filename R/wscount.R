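# WS-Count: weakly supervised counting. A presence-absence classifier (PAC),
# trained on image-level class labels only, supervises a multi-branch count
# regressor applied to 21 multi-scale patches of each tile (the full tile,
# its 4 quarters, and its 16 sixteenths). Training minimizes a classifier
# consistency loss (presence implies count >= 1, absence implies count 0)
# plus a spatial consistency loss tying the total count across the three
# scales. Ground-truth counts are never consumed.

#' Configuration for the weakly supervised multi-branch counter
#'
#' @param backbone `"tiny_cnn"` or `"resnet"` for the counting branches.
#' @param n_response_maps Feature-map count N for both sub-networks
#'   (default 6).
#' @param input_side_px Common input side to which every patch is resized
#'   (default 32; must be divisible by 8).
#' @param count_margin Margin of the classifier-consistency hinge: a branch
#'   flagged "present" should count at least this many objects (default 1).
#' @param w_pac,w_sp Weights of the two consistency terms in the training
#'   objective (`w_pac * L_PAC-C + w_sp * L_SP-C`). The default `w_pac = 21`
#'   makes the classifier term effectively branch-summed so its per-branch
#'   gradient can balance the spatial term; reported losses always use the
#'   canonical unweighted forms.
#' @param prediction_mode `"scale1"` (default; report the full-tile branch)
#'   or `"scale_avg"` (average of the three per-scale totals).
#' @param learning_rate,optimizer Stage-2 training parameters (default Adam
#'   at 1e-4).
#' @param pac_epochs,count_epochs,batch_size Training schedule.
#' @param fine_tune_pac If `TRUE`, the PAC keeps learning during stage 2;
#'   by default it is frozen after stage 1.
#' @param seed Seed for initialization and shuffling.
#' @return A `wscount_config` list.
#' @export
wscount_config <- function(backbone = c("tiny_cnn", "resnet"),
                           n_response_maps = 6L,
                           input_side_px = 32L,
                           count_margin = 1,
                           w_pac = 21, w_sp = 1,
                           prediction_mode = c("scale1", "scale_avg"),
                           learning_rate = 1e-4,
                           optimizer = c("adam", "sgd"),
                           pac_epochs = 10L,
                           count_epochs = 8L,
                           batch_size = 16L,
                           fine_tune_pac = FALSE,
                           seed = 1L) {
  backbone <- match.arg(backbone)
  optimizer <- match.arg(optimizer)
  prediction_mode <- match.arg(prediction_mode)
  if (input_side_px %% 8 != 0) abort("`input_side_px` must be divisible by 8.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(backbone = backbone, n_response_maps = as.integer(n_response_maps),
                 input_side_px = as.integer(input_side_px),
                 count_margin = count_margin, w_pac = w_pac, w_sp = w_sp,
                 prediction_mode = prediction_mode,
                 learning_rate = learning_rate, optimizer = optimizer,
                 pac_epochs = as.integer(pac_epochs),
                 count_epochs = as.integer(count_epochs),
                 batch_size = as.integer(batch_size),
                 fine_tune_pac = isTRUE(fine_tune_pac),
                 seed = as.integer(seed)),
            class = "wscount_config")
}

build_pac_layers <- function(n_maps) {
  # conv features -> N maps -> 1 evidence map -> global max pool -> logit;
  # global max pooling makes presence detection translation invariant and
  # tolerant of the blob-scale change across the three patch scales
  list(ly_conv3(3L, 8L), ly_bn(8L), ly_relu(), ly_pool(),
       ly_conv3(8L, 16L), ly_bn(16L), ly_relu(), ly_pool(),
       ly_conv1(16L, n_maps), ly_bn(n_maps), ly_relu(),
       ly_conv1(n_maps, 1L), ly_gmax())
}

#' Build a WS-Count model (PAC + multi-branch counter)
#'
#' One shared PAC and one shared counter are applied to all 21 patches
#' (resized to a common input side) rather than 21 independent networks.
#'
#' @param config A [wscount_config()].
#' @return A `wscount_model` object.
#' @export
build_wscount <- function(config = wscount_config()) {
  if (!inherits(config, "wscount_config")) abort("`config` must be a wscount_config.")
  built <- withr::with_seed(config$seed, {
    pac <- build_pac_layers(config$n_response_maps)
    counter <- build_regressor_layers(config$input_side_px, config$n_response_maps,
                                      config$backbone, final = "softplus")
    list(pac = pac, counter = counter)
  })
  structure(list(config = config, pac = built$pac,
                 counter = built$counter$layers,
                 pac_trained = FALSE, count_trained = FALSE,
                 loss_trace = tibble(epoch = integer(0), stage = character(0),
                                     l_pac_c = numeric(0), l_sp_c = numeric(0),
                                     loss = numeric(0)),
                 supervision_log = character(0)),
            class = c("wscount_model", "count_model"))
}

#' Split a tile into the 21 multi-scale patches
#'
#' Returns the whole tile, its 4 quarters (2x2 even split) and its 16
#' sixteenths (4x4 even split) in fixed row-major order, 21 patches total.
#' The quarters and sixteenths each partition the tile exactly.
#'
#' @param tile Square `S x S x 3` array with `S` divisible by 4.
#' @return List with `full` (list of 1), `quarters` (list of 4),
#'   `sixteenths` (list of 16) and `patches` (all 21 in order).
#' @export
split_multiscale <- function(tile) {
  stop_if_not_image(tile, "tile")
  s <- dim(tile)[1]
  if (dim(tile)[2] != s) abort("`tile` must be square.")
  if (s %% 4 != 0) abort("tile side must be divisible by 4.")
  cut_grid <- function(k) {
    sz <- s %/% k
    out <- vector("list", k * k)
    idx <- 0L
    for (r in seq_len(k) - 1L) for (cc in seq_len(k) - 1L) {
      idx <- idx + 1L
      out[[idx]] <- tile[(r * sz + 1L):((r + 1L) * sz),
                         (cc * sz + 1L):((cc + 1L) * sz), , drop = FALSE]
    }
    out
  }
  quarters <- cut_grid(2L)
  sixteenths <- cut_grid(4L)
  list(full = list(tile), quarters = quarters, sixteenths = sixteenths,
       patches = c(list(tile), quarters, sixteenths))
}

pac_probs <- function(pac_layers, imgs, side) {
  imgs <- prep_images(imgs, side)
  out <- numeric(length(imgs))
  for (bl in batch_blocks(length(imgs), 32L)) {
    fw <- seq_fwd(pac_layers, images_to_batch(imgs[bl]), training = FALSE)
    out[bl] <- 1 / (1 + exp(-fw$out$x[, 1]))
  }
  out
}

#' Presence probability from the presence-absence classifier
#'
#' @param model A `wscount_model` (trained or freshly built).
#' @param patch One `H x W x 3` array or a list of them; patches are resized
#'   to the PAC input side.
#' @return Numeric vector of probabilities in `[0, 1]`; deterministic in
#'   evaluation mode.
#' @export
pac_forward <- function(model, patch) {
  stopifnot(inherits(model, "wscount_model"))
  imgs <- normalize_newdata(patch)
  pac_probs(model$pac, imgs, model$config$input_side_px)
}

check_branch_outputs <- function(outputs) {
  co <- outputs$counts; pr <- outputs$presence_probs
  if (is.null(co) || is.null(pr) || length(co) != length(pr)) {
    abort("`outputs` must carry equal-length `counts` and `presence_probs`.")
  }
  if (any(pr < 0 | pr > 1)) abort("presence probabilities must lie in [0, 1].")
  invisible(outputs)
}

#' Classifier consistency loss
#'
#' Mean over branches of `(1 - p) * |c| + p * max(0, margin - c)`: a branch
#' whose classifier says "absent" is penalized for any count, and one whose
#' classifier says "present" is penalized for counting fewer than `margin`
#' (one boll, by default) objects. Zero exactly iff every branch is
#' presence/count consistent.
#'
#' @param outputs List (or tibble) with `counts` and `presence_probs`, one
#'   entry per branch in the fixed 21-branch order.
#' @param margin Consistency margin (default 1).
#' @return Nonnegative scalar.
#' @export
loss_pac_consistency <- function(outputs, margin = 1) {
  check_branch_outputs(outputs)
  co <- outputs$counts; pr <- outputs$presence_probs
  mean((1 - pr) * abs(co) + pr * pmax(0, margin - co))
}

#' Spatial consistency loss across the three scales
#'
#' With `C1` the full-tile count, `C4` the sum over quarters and `C16` the
#' sum over sixteenths, returns `|C1 - C4| + |C1 - C16| + |C4 - C16|`:
#' zero exactly iff the three per-scale totals agree.
#'
#' @param outputs As in [loss_pac_consistency()], with 21 branch counts in
#'   the fixed order (full, 4 quarters, 16 sixteenths).
#' @return Nonnegative scalar.
#' @export
loss_spatial_consistency <- function(outputs) {
  co <- outputs$counts
  if (length(co) != 21) abort("expected 21 branch counts (1 + 4 + 16).")
  c1 <- co[1]; c4 <- sum(co[2:5]); c16 <- sum(co[6:21])
  abs(c1 - c4) + abs(c1 - c16) + abs(c4 - c16)
}

#' Combined WS-Count loss
#'
#' @inheritParams loss_pac_consistency
#' @return List with `l_pac_c`, `l_sp_c` and `total = l_pac_c + l_sp_c`.
#' @export
wscount_loss <- function(outputs, margin = 1) {
  l1 <- loss_pac_consistency(outputs, margin)
  l2 <- loss_spatial_consistency(outputs)
  list(l_pac_c = l1, l_sp_c = l2, total = l1 + l2)
}

assert_weak_dataset <- function(dataset) {
  banned <- intersect(names(dataset), c("count", "counts", "points"))
  if (length(banned)) {
    abort(paste0("count supervision passed to the weak trainer (column(s): ",
                 paste(banned, collapse = ", "),
                 "); WS-Count consumes only `image` and `class_label`."))
  }
  if (!all(c("image", "class_label") %in% names(dataset))) {
    abort("`dataset` must have columns `image` and `class_label`.")
  }
  invisible(dataset)
}

#' Train a WS-Count model
#'
#' Stage 1 trains the PAC with binary cross-entropy on tile-level
#' presence/absence labels (for absent tiles, all sub-patches are also
#' absent, so they are added as additional negatives — a label-sound
#' augmentation). Stage 2 trains the counting branches against the frozen
#' PAC by minimizing the combined consistency loss; ground-truth counts are
#' never read, and passing a dataset that carries count columns is an error.
#'
#' @param model A `wscount_model` from [build_wscount()].
#' @param dataset Tibble with list-column `image` (square tiles, side
#'   divisible by 4) and `class_label` (`"present"`/`"absent"`). Any
#'   `count`/`points` column is rejected.
#' @param stage `"all"` (default), `"pac"` or `"count"`.
#' @param pac_epochs,count_epochs,learning_rate Optional overrides.
#' @return The trained model with a per-epoch `$loss_trace`.
#' @export
train_wscount <- function(model, dataset, stage = c("all", "pac", "count"),
                          pac_epochs = NULL, count_epochs = NULL,
                          learning_rate = NULL) {
  stopifnot(inherits(model, "wscount_model"))
  stage <- match.arg(stage)
  assert_weak_dataset(dataset)
  if (nrow(dataset) == 0) abort("`dataset` is empty.")
  cfg <- model$config
  if (stage %in% c("all", "pac")) {
    model <- train_pac_stage(model, dataset, pac_epochs %||% cfg$pac_epochs)
  }
  if (stage %in% c("all", "count")) {
    if (!model$pac_trained) abort("PAC must be trained (stage 1) before the counting stage.")
    model <- train_count_stage(model, dataset, count_epochs %||% cfg$count_epochs,
                               learning_rate %||% cfg$learning_rate)
  }
  model$supervision_log <- union(model$supervision_log, c("images", "class_labels"))
  model
}

train_pac_stage <- function(model, dataset, epochs) {
  cfg <- model$config
  side <- cfg$input_side_px
  imgs <- prep_images(dataset$image, side)
  y <- as.numeric(dataset$class_label == "present")
  # label-sound negative augmentation: every patch of an absent tile is absent
  for (i in which(y == 0)) {
    ms <- split_multiscale(dataset$image[[i]])
    extra <- prep_images(ms$patches[c(2, 4, 7, 12, 18, 21)], side)
    imgs <- c(imgs, extra)
    y <- c(y, numeric(length(extra)))
  }
  layers <- model$pac
  state <- opt_init(layers, "adam", 1e-3)
  trace <- numeric(epochs)
  withr::with_seed(derive_seed(cfg$seed, "pac-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(imgs))
      tot <- 0
      for (bl in batch_blocks(length(imgs), cfg$batch_size)) {
        ids <- ord[bl]
        fw <- seq_fwd(layers, images_to_batch(imgs[ids]), training = TRUE)
        layers <- fw$layers
        p <- 1 / (1 + exp(-fw$out$x[, 1]))
        yy <- y[ids]
        tot <- tot + sum(-yy * log(pmax(p, 1e-12)) - (1 - yy) * log(pmax(1 - p, 1e-12)))
        gy <- matrix((p - yy) / length(ids), ncol = 1)
        bw <- seq_bwd(layers, fw$caches, gy)
        st <- opt_step(layers, bw$grads, state)
        layers <- st$layers
        state <- st$state
      }
      trace[ep] <- tot / length(imgs)
    }
  })
  model$pac <- layers
  model$pac_trained <- TRUE
  model$loss_trace <- dplyr::bind_rows(model$loss_trace,
    tibble(epoch = seq_len(epochs), stage = "pac",
           l_pac_c = NA_real_, l_sp_c = NA_real_, loss = trace))
  model
}

train_count_stage <- function(model, dataset, epochs, lr) {
  cfg <- model$config
  side <- cfg$input_side_px
  n <- nrow(dataset)
  # precompute the 21 resized patches per tile and (for a frozen PAC) the
  # branch presence probabilities
  patch_sets <- lapply(dataset$image, function(img) {
    prep_images(split_multiscale(img)$patches, side)
  })
  probs <- NULL
  if (!cfg$fine_tune_pac) {
    probs <- lapply(patch_sets, function(ps) pac_probs(model$pac, ps, side))
  }
  counter <- model$counter
  state <- opt_init(counter, cfg$optimizer, lr)
  pac_layers <- model$pac
  pac_state <- if (cfg$fine_tune_pac) opt_init(pac_layers, cfg$optimizer, lr) else NULL
  tr_pac <- numeric(epochs); tr_sp <- numeric(epochs)
  tiles_per_batch <- 4L  # 84 patches per optimizer step
  withr::with_seed(derive_seed(cfg$seed, "wscount-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      s1 <- 0; s2 <- 0
      for (bl in batch_blocks(n, tiles_per_batch)) {
        ids <- ord[bl]
        nt <- length(ids)
        t0 <- images_to_batch(do.call(c, patch_sets[ids]))
        if (cfg$fine_tune_pac) {
          pfw <- seq_fwd(pac_layers, t0, training = FALSE)
          p <- 1 / (1 + exp(-pfw$out$x[, 1]))
        } else {
          p <- unlist(probs[ids])
        }
        fw <- seq_fwd(counter, t0, training = TRUE)
        counter <- fw$layers
        co_all <- fw$out$x[, 1]
        gc_all <- numeric(21L * nt)
        gp_all <- numeric(21L * nt)
        for (j in seq_len(nt)) {
          sl <- (j - 1L) * 21L + 1:21
          co <- co_all[sl]; pj <- p[sl]
          out <- list(counts = co, presence_probs = pj)
          l1 <- loss_pac_consistency(out, cfg$count_margin)
          l2 <- loss_spatial_consistency(out)
          s1 <- s1 + l1; s2 <- s2 + l2
          # d l_pac-c / d c_b
          gcj <- cfg$w_pac * ((1 - pj) * sign(co) - pj * (co < cfg$count_margin)) / 21
          # d l_sp-c / d c_b through the three per-scale totals
          c1 <- co[1]; c4 <- sum(co[2:5]); c16 <- sum(co[6:21])
          gcj[1] <- gcj[1] + cfg$w_sp * (sign(c1 - c4) + sign(c1 - c16))
          gcj[2:5] <- gcj[2:5] + cfg$w_sp * (-sign(c1 - c4) + sign(c4 - c16))
          gcj[6:21] <- gcj[6:21] + cfg$w_sp * (-sign(c1 - c16) - sign(c4 - c16))
          gc_all[sl] <- gcj / nt
          if (cfg$fine_tune_pac) {
            gp_all[sl] <- ((-abs(co) + pmax(0, cfg$count_margin - co)) / 21) / nt
          }
        }
        bw <- seq_bwd(counter, fw$caches, matrix(gc_all, ncol = 1))
        st <- opt_step(counter, bw$grads, state)
        counter <- st$layers
        state <- st$state
        if (cfg$fine_tune_pac) {
          glogit <- gp_all * p * (1 - p)
          pbw <- seq_bwd(pac_layers, pfw$caches, matrix(glogit, ncol = 1))
          pst <- opt_step(pac_layers, pbw$grads, pac_state)
          pac_layers <- pst$layers
          pac_state <- pst$state
        }
      }
      tr_pac[ep] <- s1 / n
      tr_sp[ep] <- s2 / n
    }
  })
  model$counter <- counter
  model$pac <- pac_layers
  model$count_trained <- TRUE
  model$loss_trace <- dplyr::bind_rows(model$loss_trace,
    tibble(epoch = seq_len(epochs), stage = "count",
           l_pac_c = tr_pac, l_sp_c = tr_sp, loss = tr_pac + tr_sp))
  model
}

wscount_branch_counts <- function(model, tile) {
  side <- model$config$input_side_px
  ps <- prep_images(split_multiscale(tile)$patches, side)
  fw <- seq_fwd(model$counter, images_to_batch(ps), training = FALSE)
  fw$out$x[, 1]
}

#' Predict a count with a trained WS-Count model
#'
#' By default the reported count is the full-tile (scale-1) branch;
#' `prediction_mode = "scale_avg"` in the config averages the three
#' per-scale totals instead.
#'
#' @param model A trained `wscount_model`.
#' @param tile Square `H x W x 3` array.
#' @return A `count_prediction` with `count_real` and `count_int`.
#' @export
predict_wscount <- function(model, tile) {
  stopifnot(inherits(model, "wscount_model"))
  co <- wscount_branch_counts(model, tile)
  raw <- if (model$config$prediction_mode == "scale_avg") {
    (co[1] + sum(co[2:5]) + sum(co[6:21])) / 3
  } else co[1]
  structure(list(count_real = max(raw, 0), count_int = count_to_int(raw),
                 response_maps = NULL),
            class = "count_prediction")
}

#' @export
predict.wscount_model <- function(object, newdata, ...) {
  imgs <- normalize_newdata(newdata)
  preds <- purrr::map(imgs, function(img) predict_wscount(object, img))
  tibble(count_real = purrr::map_dbl(preds, "count_real"),
         count_int = purrr::map_int(preds, "count_int"))
}
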