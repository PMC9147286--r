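# CountSeg: weakly supervised density-map counting. A shared backbone feeds
# a 1x1 convolution whose channels are split in half between a
# classification branch (presence/absence, trained on class labels) and a
# density branch (a nonnegative map whose sum is the predicted count).
# Training is joint under image-level lower-count (ILC) supervision: exact
# counts inside the subitizing range, a lower-bound hinge beyond it, and
# never any point locations. The classification branch's confidence map,
# capped by the known count, provides pseudo ground truth peaks that the
# spatial loss uses to localize instances.

#' Configuration for the density-map counting model
#'
#' @param backbone `"tiny_cnn"` (default) or `"resnet"`.
#' @param shared_channels Channels of the shared 1x1 convolution, split in
#'   half across the two branches (default 60, i.e. 30 each; must be even).
#' @param subitizing_max Upper end of the subitizing range (default 10);
#'   beyond it only the lower-bound hinge applies.
#' @param discard_above Counts above this are `dnc` and rejected (default 15).
#' @param peak_neighborhood_px Non-maximum-suppression radius (in map cells)
#'   for pseudo ground truth peaks (default 3).
#' @param input_side_px Model input side (default 64; divisible by 4).
#' @param learning_rate,optimizer Training parameters (default SGD at 0.001).
#' @param w_class,w_spatial,w_global Loss-term weights (default unit).
#' @param epochs,batch_size,seed Training schedule and seed.
#' @return A `countseg_config` list.
#' @export
countseg_config <- function(backbone = c("tiny_cnn", "resnet"),
                            shared_channels = 60L,
                            subitizing_max = 10L,
                            discard_above = 15L,
                            peak_neighborhood_px = 3L,
                            input_side_px = 64L,
                            learning_rate = 0.001,
                            optimizer = c("sgd", "adam"),
                            w_class = 1, w_spatial = 1, w_global = 1,
                            epochs = 15L,
                            batch_size = 8L,
                            seed = 1L) {
  backbone <- match.arg(backbone)
  optimizer <- match.arg(optimizer)
  if (shared_channels %% 2 != 0) abort("`shared_channels` must be even (half per branch).")
  if (subitizing_max < 1) abort("`subitizing_max` must be >= 1.")
  if (input_side_px %% 4 != 0) abort("`input_side_px` must be divisible by 4.")
  structure(list(backbone = backbone, shared_channels = as.integer(shared_channels),
                 subitizing_max = as.integer(subitizing_max),
                 discard_above = as.integer(discard_above),
                 peak_neighborhood_px = as.integer(peak_neighborhood_px),
                 input_side_px = as.integer(input_side_px),
                 learning_rate = learning_rate, optimizer = optimizer,
                 w_class = w_class, w_spatial = w_spatial, w_global = w_global,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "countseg_config")
}

#' Build a CountSeg model
#'
#' @param config A [countseg_config()].
#' @return A `countseg_model`; the density map has stride 4 relative to the
#'   input (two pooling stages).
#' @export
build_countseg <- function(config = countseg_config()) {
  if (!inherits(config, "countseg_config")) abort("`config` must be a countseg_config.")
  half <- config$shared_channels %/% 2L
  built <- withr::with_seed(config$seed, {
    backbone <- if (config$backbone == "tiny_cnn") {
      list(ly_conv3(3L, 12L), ly_bn(12L), ly_relu(), ly_pool(),
           ly_conv3(12L, 24L), ly_bn(24L), ly_relu(), ly_pool(),
           ly_conv1(24L, config$shared_channels), ly_bn(config$shared_channels),
           ly_relu())
    } else {
      list(ly_conv3(3L, 16L), ly_bn(16L), ly_relu(), ly_pool(),
           ly_resblock(16L), ly_pool(),
           ly_conv1(16L, config$shared_channels), ly_bn(config$shared_channels),
           ly_relu())
    }
    head_density <- ly_conv1(half, 1L, wscale = 0.1)
    # start the density map near zero (softplus(-4) ~ 0.018/cell) so the
    # global-count term does not explode on the first batches
    head_density$b[] <- -4
    list(backbone = backbone,
         head_class = ly_conv1(half, 1L, wscale = 0.5),
         head_density = head_density)
  })
  structure(list(config = config, backbone = built$backbone,
                 head_class = built$head_class, head_density = built$head_density,
                 stride_px = 4L, trained = FALSE,
                 loss_trace = tibble(epoch = integer(0), l_class = numeric(0),
                                     l_spatial = numeric(0), l_global = numeric(0),
                                     loss = numeric(0)),
                 supervision_log = character(0)),
            class = c("countseg_model", "count_model"))
}

#' Construct a density map object
#'
#' @param values Nonnegative numeric `h x w` matrix; its sum is the global
#'   count.
#' @param stride_px Pixels per map cell in the source image.
#' @return A `density_map`.
#' @export
density_map <- function(values, stride_px = 1L) {
  if (any(values < 0)) abort("density values must be nonnegative.")
  structure(list(values = values, stride_px = as.integer(stride_px)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d cells (stride %d px), global count %.3f\n",
              nrow(x$values), ncol(x$values), x$stride_px, sum(x$values)))
  invisible(x)
}

# batched internal forward; returns per-image confidence maps, density
# matrices, pooled class scores, plus caches for backward
countseg_fwd_batch <- function(model, imgs, training) {
  t0 <- images_to_batch(imgs)
  half <- model$config$shared_channels %/% 2L
  fb <- seq_fwd(model$backbone, t0, training)
  feat <- fb$out
  xc <- feat; xc$x <- feat$x[, seq_len(half), drop = FALSE]; xc$c <- half
  xd <- feat; xd$x <- feat$x[, half + seq_len(half), drop = FALSE]; xd$c <- half
  fc <- layer_fwd(model$head_class, xc, training)
  fd <- layer_fwd(model$head_density, xd, training)
  conf <- fc$out
  dens_raw <- fd$out
  # softplus rectification keeps the map nonnegative without the dead
  # gradient of a hard ReLU on the output layer
  dsp <- layer_fwd(ly_softplus(), dens_raw, training)
  dens <- dsp$out
  n <- conf$n; hw <- conf$h * conf$w
  scores <- numeric(n); arg <- integer(n)
  conf_maps <- vector("list", n); dens_maps <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * hw + 1):(i * hw)
    v <- conf$x[rows, 1]
    arg[i] <- rows[which.max(v)]
    scores[i] <- v[which.max(v)]
    conf_maps[[i]] <- batch_channel_map(conf, i, 1L)
    dens_maps[[i]] <- batch_channel_map(dens, i, 1L)
  }
  list(backbone = fb, fc = fc, fd = fd, conf = conf, dens_raw = dens_raw,
       dens = dens, dens_sig = dsp$cache$sig, scores = scores, argmax = arg,
       conf_maps = conf_maps, dens_maps = dens_maps, half = half)
}

#' Forward pass of the CountSeg network
#'
#' @param model A `countseg_model`.
#' @param tile `H x W x 3` array (resized to the model input side).
#' @return List with `class_score` (spatial maximum of the confidence map),
#'   `class_prob` (its sigmoid), `confidence_map` (`h x w` matrix) and
#'   `density` (a [density_map()], rectified so all values are nonnegative).
#' @export
countseg_forward <- function(model, tile) {
  stopifnot(inherits(model, "countseg_model"))
  imgs <- prep_images(list(tile), model$config$input_side_px)
  fw <- countseg_fwd_batch(model, imgs, training = FALSE)
  list(class_score = fw$scores[1],
       class_prob = 1 / (1 + exp(-fw$scores[1])),
       confidence_map = fw$conf_maps[[1]],
       density = density_map(fw$dens_maps[[1]], model$stride_px))
}

# exact-zero binary cross-entropy: terms where the prediction equals the
# target contribute exactly 0 (only the lower clamp guards the log)
bce_terms <- function(p, t, eps = 1e-12) {
  ifelse(t >= 0.5, -log(pmax(p, eps)), -log(pmax(1 - p, eps)))
}

#' Classification-branch loss
#'
#' Binary cross-entropy of the sigmoid of the pooled class score against the
#' presence/absence label.
#'
#' @param class_score Pooled (spatial-maximum) raw class score.
#' @param class_label `"present"` or `"absent"`.
#' @return Nonnegative scalar.
#' @export
loss_class <- function(class_score, class_label) {
  t <- as.numeric(class_label == "present")
  p <- 1 / (1 + exp(-class_score))
  bce_terms(p, t)
}

#' Global count loss under ILC supervision
#'
#' Inside the subitizing range the density sum is regressed to the exact
#' count with a squared error; beyond it (the lower-count regime) only
#' underestimation is penalized, with the hinge
#' `max(0, (subitizing_max + 1) - sum)^2`.
#'
#' @param density A [density_map()] or nonnegative matrix.
#' @param count Ground-truth integer count (not `dnc`).
#' @param subitizing_max Upper end of the subitizing range.
#' @param discard_above Counts above this are `dnc` and an error.
#' @return Nonnegative scalar.
#' @export
loss_global <- function(density, count, subitizing_max = 10L, discard_above = 15L) {
  v <- if (inherits(density, "density_map")) density$values else density
  if (count < 0) abort("`count` must be nonnegative.")
  if (count > discard_above) abort("dnc tile (count above the discard threshold) passed to loss_global().")
  s <- sum(v)
  if (count <= subitizing_max) (s - count)^2 else pmax(0, (subitizing_max + 1) - s)^2
}

local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  ok <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & (m >= pad[(2:(h + 1)) + dy, (2:(w + 1)) + dx])
  }
  which(ok, arr.ind = TRUE)
}

nms_peaks <- function(m, cand, radius, k = Inf, threshold = -Inf) {
  if (nrow(cand) == 0) return(cand[0, , drop = FALSE])
  vals <- m[cand]
  keepv <- vals > threshold
  cand <- cand[keepv, , drop = FALSE]; vals <- vals[keepv]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(0L, 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) >= k) break
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        all(pmax(abs(kept[, 1] - p[1]), abs(kept[, 2] - p[2])) >= radius)) {
      kept <- rbind(kept, p)
    }
  }
  kept
}

#' Pseudo ground truth peaks from a confidence map
#'
#' Marks the `count` strongest local maxima of the classification branch's
#' confidence map (after non-maximum suppression within
#' `peak_neighborhood_px` cells) as pseudo instance locations for the
#' spatial loss. If fewer maxima exist than `count`, all are marked and a
#' warning is logged. The construction is gradient-free.
#'
#' @param confidence_map `h x w` numeric matrix.
#' @param count Number of peaks to keep (the known lower count).
#' @param peak_neighborhood_px NMS radius in map cells (default 3).
#' @return Logical `h x w` peak mask.
#' @export
make_pseudo_ground_truth <- function(confidence_map, count, peak_neighborhood_px = 3L) {
  if (count < 0) abort("`count` must be nonnegative.")
  mask <- matrix(FALSE, nrow(confidence_map), ncol(confidence_map))
  if (count == 0) return(mask)
  cand <- local_maxima(confidence_map)
  kept <- nms_peaks(confidence_map, cand, peak_neighborhood_px, k = count)
  if (nrow(kept) < count) {
    warn(sprintf("only %d local maxima available for pseudo ground truth (count %d).",
                 nrow(kept), count))
  }
  mask[kept] <- TRUE
  mask
}

#' Spatial localization loss
#'
#' Binary cross-entropy between the min-max-normalized density map and the
#' pseudo peak mask, averaged over map cells. A density that is exactly 1 at
#' the peak cells and 0 elsewhere attains loss 0; moving density mass from
#' non-peak to peak cells lowers the loss.
#'
#' @param density A [density_map()] or matrix.
#' @param peak_mask Logical matrix of the same shape
#'   (see [make_pseudo_ground_truth()]).
#' @return Nonnegative scalar.
#' @export
loss_spatial <- function(density, peak_mask) {
  v <- if (inherits(density, "density_map")) density$values else density
  if (!all(dim(v) == dim(peak_mask))) abort("density and peak mask shapes differ.")
  rg <- max(v) - min(v)
  vhat <- if (rg > 0) (v - min(v)) / rg else matrix(0, nrow(v), ncol(v))
  mean(bce_terms(vhat, as.numeric(peak_mask)))
}

#' Train a CountSeg model with ILC supervision
#'
#' The trainer consumes images, class labels derived from counts, and the
#' integer counts themselves only within the subitizing range (beyond it the
#' hinge of [loss_global()] uses the range bound alone). Point coordinates
#' are never accepted: a dataset carrying a `points` column is an error,
#' which keeps the supervision contract checkable.
#'
#' @param model A `countseg_model`.
#' @param dataset Tibble with list-column `image` and integer `count`
#'   (no `dnc` tiles, no `points` column).
#' @param epochs,batch_size,learning_rate Optional overrides.
#' @return The trained model with per-epoch loss-component traces.
#' @export
train_countseg <- function(model, dataset, epochs = NULL, batch_size = NULL,
                           learning_rate = NULL) {
  stopifnot(inherits(model, "countseg_model"))
  if ("points" %in% names(dataset)) {
    abort("point supervision passed to the ILC trainer; CountSeg consumes only class labels and counts.")
  }
  if (!all(c("image", "count") %in% names(dataset))) {
    abort("`dataset` must have columns `image` and `count`.")
  }
  if (nrow(dataset) == 0) abort("`dataset` is empty.")
  cfg <- model$config
  if (any(dataset$count > cfg$discard_above)) {
    abort("dataset contains dnc tiles; drop them before training.")
  }
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  imgs <- prep_images(dataset$image, cfg$input_side_px)
  cnt <- as.integer(dataset$count)
  lab <- as.numeric(cnt > 0)
  smax <- cfg$subitizing_max
  layers <- c(model$backbone, list(model$head_class, model$head_density))
  # optimizer state over backbone + the two heads, updated jointly
  state <- opt_init(layers, cfg$optimizer, lr)
  n_all <- length(imgs)
  trc <- matrix(0, epochs, 3, dimnames = list(NULL, c("l_class", "l_spatial", "l_global")))
  withr::with_seed(derive_seed(cfg$seed, "countseg-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(n_all)
      acc <- c(l_class = 0, l_spatial = 0, l_global = 0)
      for (bl in batch_blocks(n_all, batch_size)) {
        ids <- ord[bl]
        nb <- length(ids)
        fw <- countseg_fwd_batch(model, imgs[ids], training = TRUE)
        model$backbone <- fw$backbone$layers
        hw <- fw$conf$h * fw$conf$w
        gconf <- matrix(0, nrow(fw$conf$x), 1)
        gdens <- matrix(0, nrow(fw$dens$x), 1)
        for (j in seq_len(nb)) {
          i <- ids[j]
          rows <- ((j - 1) * hw + 1):(j * hw)
          # class term (through the spatial max)
          pj <- 1 / (1 + exp(-fw$scores[j]))
          acc["l_class"] <- acc["l_class"] + cfg$w_class * bce_terms(pj, lab[i])
          gconf[fw$argmax[j], 1] <- cfg$w_class * (pj - lab[i]) / nb
          # global term
          dm <- fw$dens_maps[[j]]
          s <- sum(dm)
          if (cnt[i] <= smax) {
            acc["l_global"] <- acc["l_global"] + cfg$w_global * (s - cnt[i])^2
            gs <- cfg$w_global * 2 * (s - cnt[i]) / nb
          } else {
            m1 <- smax + 1
            acc["l_global"] <- acc["l_global"] + cfg$w_global * pmax(0, m1 - s)^2
            gs <- if (s < m1) -cfg$w_global * 2 * (m1 - s) / nb else 0
          }
          gd <- matrix(gs, nrow(dm), ncol(dm))
          # spatial term on positive tiles; min/max of the normalization are
          # treated as constants in the gradient
          if (cnt[i] > 0) {
            pm <- make_pseudo_ground_truth(fw$conf_maps[[j]], min(cnt[i], smax),
                                           cfg$peak_neighborhood_px)
            ls <- loss_spatial(dm, pm)
            acc["l_spatial"] <- acc["l_spatial"] + cfg$w_spatial * ls
            rgj <- max(dm) - min(dm)
            if (rgj > 0) {
              vh <- pmin(pmax((dm - min(dm)) / rgj, 1e-4), 1 - 1e-4)
              gvh <- (-pm / vh + (1 - pm) / (1 - vh)) / length(dm)
              # min/max are treated as constants; the denominator is floored
              # at 1 so a near-flat early map cannot blow up the step
              gd <- gd + cfg$w_spatial * gvh / max(rgj, 1) / nb
            }
          }
          # back to row-major channel column (transpose of the map layout)
          gdens[rows, 1] <- as.vector(t(gd))
        }
        # backward: density head through its softplus, class head, backbone
        gdens_raw <- gdens * fw$dens_sig
        bc <- layer_bwd(model$head_class, fw$fc$cache, gconf)
        bd <- layer_bwd(model$head_density, fw$fd$cache, gdens_raw)
        gfeat <- cbind(bc$gx, bd$gx)
        bb <- seq_bwd(model$backbone, fw$backbone$caches, gfeat)
        grads <- c(bb$grads, list(bc$grads, bd$grads))
        layers <- c(model$backbone, list(model$head_class, model$head_density))
        st <- opt_step(layers, grads, state)
        state <- st$state
        nlay <- length(model$backbone)
        model$backbone <- st$layers[seq_len(nlay)]
        model$head_class <- st$layers[[nlay + 1L]]
        model$head_density <- st$layers[[nlay + 2L]]
      }
      trc[ep, ] <- acc / n_all
    }
  })
  model$trained <- TRUE
  model$loss_trace <- tibble(epoch = seq_len(epochs),
                             l_class = trc[, 1], l_spatial = trc[, 2],
                             l_global = trc[, 3],
                             loss = rowSums(trc))
  model$supervision_log <- union(model$supervision_log,
                                 c("images", "class_labels", "counts_within_subitizing"))
  model
}

#' Combined CountSeg loss for one tile
#'
#' @param class_score,class_label As in [loss_class()].
#' @param density,peak_mask As in [loss_spatial()].
#' @param count,subitizing_max As in [loss_global()].
#' @return List with `l_class`, `l_spatial`, `l_global` and
#'   `total = l_class + l_spatial + l_global`.
#' @export
countseg_loss <- function(class_score, class_label, density, peak_mask, count,
                          subitizing_max = 10L) {
  lc <- loss_class(class_score, class_label)
  ls <- loss_spatial(density, peak_mask)
  lg <- loss_global(density, count, subitizing_max)
  list(l_class = lc, l_spatial = ls, l_global = lg, total = lc + ls + lg)
}

#' Predict a count with a trained CountSeg model
#'
#' The real-valued count is the sum of the density map; the integer count
#' rounds it, clipped at zero.
#'
#' @param model A trained `countseg_model`.
#' @param tile `H x W x 3` array.
#' @return A `count_prediction`.
#' @export
predict_countseg <- function(model, tile) {
  fw <- countseg_forward(model, tile)
  s <- sum(fw$density$values)
  structure(list(count_real = max(s, 0), count_int = count_to_int(s),
                 response_maps = NULL),
            class = "count_prediction")
}

#' @export
predict.countseg_model <- function(object, newdata, ...) {
  imgs <- normalize_newdata(newdata)
  side <- object$config$input_side_px
  out_real <- numeric(length(imgs))
  imgs <- prep_images(imgs, side)
  for (bl in batch_blocks(length(imgs), 32L)) {
    fw <- countseg_fwd_batch(object, imgs[bl], training = FALSE)
    out_real[bl] <- vapply(fw$dens_maps, sum, numeric(1))
  }
  tibble(count_real = pmax(out_real, 0), count_int = count_to_int(out_real))
}

#' Instance locations from a density map
#'
#' Local maxima of the density map above a threshold, after non-maximum
#' suppression, mapped back to image pixel coordinates through the map
#' stride (cell centres).
#'
#' @param density A [density_map()].
#' @param threshold Minimum density value for a peak (>= 0).
#' @param nms_radius NMS radius in map cells (default 2).
#' @return Tibble with 0-based pixel coordinates `x`, `y` and the peak
#'   `value`, strongest first.
#' @export
peak_instances <- function(density, threshold, nms_radius = 2L) {
  stopifnot(inherits(density, "density_map"))
  if (threshold < 0) abort("`threshold` must be >= 0.")
  v <- density$values
  cand <- local_maxima(v)
  kept <- nms_peaks(v, cand, nms_radius, threshold = threshold)
  if (nrow(kept) == 0) {
    return(tibble(x = numeric(0), y = numeric(0), value = numeric(0)))
  }
  st <- density$stride_px
  tibble(x = (kept[, 2] - 1) * st + (st - 1) / 2,
         y = (kept[, 1] - 1) * st + (st - 1) / 2,
         value = v[kept])
}
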