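# S-Count: fully supervised convolutional count regression. A convolutional
# backbone is topped by a 1x1 convolution producing N response maps, which a
# fully connected head regresses to the boll count; hidden layers use ReLU
# with batch normalization and the output layer is linear. Training minimizes
# mean squared error against point-label counts.

#' Configuration for the supervised count-regression model
#'
#' @param backbone `"tiny_cnn"` (default; four convolution blocks, suited to
#'   CPU-scale training) or `"resnet"` (a reduced-depth residual backbone
#'   behind the same interface).
#' @param n_response_maps Number N of response maps produced by the final
#'   1x1 convolution (default 6).
#' @param input_side_px Model input side; tiles of other sizes are resized
#'   bilinearly at prediction time. Must be divisible by 8.
#' @param learning_rate,optimizer,epochs,batch_size Training parameters.
#' @param seed Seed for parameter initialization and data shuffling.
#' @return An `scount_config` list.
#' @export
scount_config <- function(backbone = c("tiny_cnn", "resnet"),
                          n_response_maps = 6L,
                          input_side_px = 64L,
                          learning_rate = 1e-3,
                          optimizer = c("adam", "sgd"),
                          epochs = 30L,
                          batch_size = 16L,
                          seed = 1L) {
  backbone <- match.arg(backbone)
  optimizer <- match.arg(optimizer)
  if (n_response_maps < 1) abort("`n_response_maps` must be >= 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (input_side_px %% 8 != 0) abort("`input_side_px` must be divisible by 8.")
  structure(list(backbone = backbone, n_response_maps = as.integer(n_response_maps),
                 input_side_px = as.integer(input_side_px),
                 learning_rate = learning_rate, optimizer = optimizer,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "scount_config")
}

# backbone + N response maps + fully connected head; final activation
# "linear" (count regression) or "softplus" (nonnegative branch counts)
build_regressor_layers <- function(input_side, n_maps, backbone, final = "linear") {
  s8 <- input_side %/% 8L
  layers <- if (backbone == "tiny_cnn") {
    list(ly_conv3(3L, 8L), ly_bn(8L), ly_relu(), ly_pool(),
         ly_conv3(8L, 16L), ly_bn(16L), ly_relu(), ly_pool(),
         ly_conv3(16L, 32L), ly_bn(32L), ly_relu(), ly_pool(),
         ly_conv1(32L, n_maps), ly_bn(n_maps), ly_relu())
  } else {
    list(ly_conv3(3L, 16L), ly_bn(16L), ly_relu(), ly_pool(),
         ly_resblock(16L), ly_pool(),
         ly_resblock(16L), ly_pool(),
         ly_conv1(16L, n_maps), ly_bn(n_maps), ly_relu())
  }
  map_layer <- length(layers)  # output of this layer = N response maps
  layers <- c(layers, list(ly_flatten(), ly_dense(s8 * s8 * n_maps, 1L, wscale = 0.5)))
  if (final == "softplus") layers <- c(layers, list(ly_softplus()))
  list(layers = layers, map_layer = map_layer)
}

#' Build an S-Count model
#'
#' @param config An [scount_config()]; parameter initialization is seeded,
#'   so two builds with the same seed have identical parameters.
#' @return An `scount_model` object.
#' @export
build_scount <- function(config = scount_config()) {
  if (!inherits(config, "scount_config")) abort("`config` must be an scount_config.")
  built <- withr::with_seed(config$seed,
    build_regressor_layers(config$input_side_px, config$n_response_maps,
                           config$backbone))
  structure(list(config = config, layers = built$layers,
                 map_layer = built$map_layer, trained = FALSE,
                 loss_trace = tibble(epoch = integer(0), loss = numeric(0)),
                 supervision_log = character(0)),
            class = c("scount_model", "count_model"))
}

#' Mean squared error
#'
#' @param predicted,target Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @examples
#' mse_loss(c(1, 2, 3), c(3, 2, 1))
#' @export
mse_loss <- function(predicted, target) {
  if (length(predicted) != length(target) || length(predicted) < 1) {
    abort("`predicted` and `target` must have equal length >= 1.")
  }
  mean((predicted - target)^2)
}

prep_images <- function(images, side) {
  lapply(images, function(img) {
    stop_if_not_image(img)
    resize_image(img, side, side)
  })
}

#' Train an S-Count model with MSE loss
#'
#' Count targets are not clamped during training (the clamp at zero is
#' applied only at prediction), and `dnc` tiles (counts above the discard
#' threshold) must have been removed from the dataset beforehand.
#'
#' @param model An `scount_model` from [build_scount()].
#' @param dataset Tibble with list-column `image` and integer `count`.
#' @param epochs,batch_size,learning_rate,optimizer Optional overrides of
#'   the model's config.
#' @param discard_above Counts above this value are `dnc` and rejected.
#' @return The trained model, with `$loss_trace` (tibble `epoch`, `loss`)
#'   and a supervision log recording that integer counts were consumed.
#' @export
train_scount <- function(model, dataset, epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, optimizer = NULL,
                         discard_above = 15L) {
  stopifnot(inherits(model, "scount_model"))
  if (nrow(dataset) == 0) abort("`dataset` is empty.")
  if (any(dataset$count > discard_above)) {
    abort("dataset contains dnc tiles (count above the discard threshold); drop them first.")
  }
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  opt_kind <- optimizer %||% cfg$optimizer
  imgs <- prep_images(dataset$image, cfg$input_side_px)
  y <- as.numeric(dataset$count)
  layers <- model$layers
  state <- opt_init(layers, opt_kind, lr)
  trace <- numeric(epochs)
  withr::with_seed(derive_seed(cfg$seed, "scount-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(imgs))
      tot <- 0
      for (bl in batch_blocks(length(imgs), batch_size)) {
        ids <- ord[bl]
        t0 <- images_to_batch(imgs[ids])
        fw <- seq_fwd(layers, t0, training = TRUE)
        layers <- fw$layers
        pred <- fw$out$x[, 1]
        err <- pred - y[ids]
        tot <- tot + sum(err^2)
        gy <- matrix(2 * err / length(ids), ncol = 1)
        bw <- seq_bwd(layers, fw$caches, gy)
        st <- opt_step(layers, bw$grads, state)
        layers <- st$layers
        state <- st$state
      }
      trace[ep] <- tot / length(imgs)
    }
  })
  model$layers <- layers
  model$trained <- TRUE
  model$loss_trace <- tibble(epoch = seq_len(epochs), loss = trace)
  model$supervision_log <- union(model$supervision_log, c("images", "counts"))
  model
}

forward_counts <- function(layers, imgs, side) {
  imgs <- prep_images(imgs, side)
  out <- numeric(length(imgs))
  for (bl in batch_blocks(length(imgs), 32L)) {
    fw <- seq_fwd(layers, images_to_batch(imgs[bl]), training = FALSE)
    out[bl] <- fw$out$x[, 1]
  }
  out
}

#' Predict counts for image tiles
#'
#' @param object A trained `scount_model`.
#' @param newdata A single `H x W x 3` array or a list of them (or a tibble
#'   with an `image` list-column).
#' @param ... Unused.
#' @return Tibble with `count_real` (clamped at zero) and `count_int`
#'   (rounded).
#' @export
predict.scount_model <- function(object, newdata, ...) {
  imgs <- normalize_newdata(newdata)
  raw <- forward_counts(object$layers, imgs, object$config$input_side_px)
  tibble(count_real = pmax(raw, 0), count_int = count_to_int(raw))
}

normalize_newdata <- function(newdata) {
  if (is.array(newdata)) return(list(newdata))
  if (is.data.frame(newdata)) return(newdata$image)
  newdata
}

#' Predict one tile and return the full count prediction
#'
#' @param model A trained `scount_model`.
#' @param tile `H x W x 3` array.
#' @param response_maps If `TRUE`, include the N response maps.
#' @return A `count_prediction`: list with `count_real`, `count_int` and
#'   optionally `response_maps` (`N x h x w` array).
#' @export
predict_scount <- function(model, tile, response_maps = FALSE) {
  stopifnot(inherits(model, "scount_model"))
  img <- prep_images(list(tile), model$config$input_side_px)
  t0 <- images_to_batch(img)
  maps <- NULL
  t <- t0
  layers <- model$layers
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], t, training = FALSE)
    t <- r$out
    if (response_maps && i == model$map_layer) {
      n_maps <- t$c
      maps <- array(0, c(n_maps, t$h, t$w))
      for (ch in seq_len(n_maps)) maps[ch, , ] <- batch_channel_map(t, 1L, ch)
    }
  }
  raw <- t$x[1, 1]
  structure(list(count_real = max(raw, 0), count_int = count_to_int(raw),
                 response_maps = maps),
            class = "count_prediction")
}

#' @export
print.count_prediction <- function(x, ...) {
  cat(sprintf("<count_prediction> count_real = %.3f, count_int = %d\n",
              x$count_real, x$count_int))
  invisible(x)
}

#' @export
tidy.count_model <- function(x, ...) x$loss_trace

#' @export
glance.count_model <- function(x, ...) {
  tibble(trained = x$trained,
         epochs = nrow(x$loss_trace),
         final_loss = if (nrow(x$loss_trace)) tail(x$loss_trace$loss, 1) else NA_real_,
         supervision = paste(x$supervision_log, collapse = "+"))
}

#' Save / load a fitted counting model
#'
#' Models are plain R lists; serialization round-trips to identical
#' predictions.
#'
#' @param model Any fitted model from this package.
#' @param path File path (`.rds`).
#' @return `save_count_model()` returns `path` invisibly;
#'   `load_count_model()` returns the model.
#' @export
save_count_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_count_model
#' @export
load_count_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model checkpoint not found: '%s'", path))
  readRDS(path)
}
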