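# Minimal reverse-mode neural-network engine.
#
# All models in this package (supervised count regression, presence-absence
# classifier, multi-branch counter, density-map network) are built from the
# layer primitives below. Feature maps are stored as a matrix with one row
# per (image, pixel) and one column per channel; convolution is im2col +
# BLAS matrix multiplication. Pixel order within an image is row-major
# ((row-1)*w + col), images stacked block-wise.

.bc_cache <- new.env(parent = emptyenv())

bt <- function(x, n, h, w, c) list(x = x, n = n, h = h, w = w, c = c)

# list of h x w x c arrays -> batch tensor
images_to_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  n <- length(imgs); h <- d[1]; w <- d[2]; c <- d[3]
  x <- matrix(0, n * h * w, c)
  hw <- h * w
  for (i in seq_len(n)) {
    x[((i - 1) * hw + 1):(i * hw), ] <- matrix(aperm(imgs[[i]], c(2, 1, 3)), hw, c)
  }
  bt(x, n, h, w, c)
}

# one image's channel column -> h x w matrix
batch_channel_map <- function(t, image, channel) {
  hw <- t$h * t$w
  v <- t$x[((image - 1) * hw + 1):(image * hw), channel]
  t(matrix(v, t$w, t$h))
}

# gather indices for 3x3 same-padding convolution; 0 marks a padded source
conv_idx <- function(n, h, w) {
  key <- paste0("c", n, "_", h, "_", w)
  got <- .bc_cache[[key]]
  if (!is.null(got)) return(got)
  hw <- h * w
  r <- rep(seq_len(h), each = w)
  cc <- rep.int(seq_len(w), h)
  shift <- rep((seq_len(n) - 1L) * hw, each = hw)
  out <- vector("list", 9L)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    r2 <- r + dy; c2 <- cc + dx
    base <- ifelse(r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w, (r2 - 1L) * w + c2, 0L)
    idx <- rep.int(base, n)
    pos <- idx > 0L
    idx[pos] <- idx[pos] + shift[pos]
    out[[k]] <- idx
  }
  assign(key, out, envir = .bc_cache)
  out
}

# gather indices for 2x2/stride-2 max pooling (h, w even)
pool_idx <- function(n, h, w) {
  key <- paste0("p", n, "_", h, "_", w)
  got <- .bc_cache[[key]]
  if (!is.null(got)) return(got)
  oh <- h %/% 2L; ow <- w %/% 2L
  r <- rep(seq_len(oh), each = ow)
  cc <- rep.int(seq_len(ow), oh)
  shift <- rep((seq_len(n) - 1L) * h * w, each = oh * ow)
  out <- vector("list", 4L)
  k <- 0L
  for (dy in 0:1) for (dx in 0:1) {
    k <- k + 1L
    base <- (2L * r - 2L + dy) * w + (2L * cc - 1L + dx)
    out[[k]] <- rep.int(base, n) + shift
  }
  assign(key, out, envir = .bc_cache)
  out
}

add_bias <- function(y, b) y + rep(b, each = nrow(y))

# ---- layer constructors (parameters drawn from the current RNG state) ----

ly_conv3 <- function(cin, cout) {
  sdv <- sqrt(2 / (9 * cin))
  list(type = "conv3", cin = cin, cout = cout,
       w = matrix(rnorm(9L * cin * cout, 0, sdv), 9L * cin, cout),
       b = numeric(cout))
}

ly_conv1 <- function(cin, cout, wscale = 1) {
  sdv <- wscale * sqrt(2 / cin)
  list(type = "conv1", cin = cin, cout = cout,
       w = matrix(rnorm(cin * cout, 0, sdv), cin, cout),
       b = numeric(cout))
}

ly_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = momentum, eps = eps)
}

ly_relu <- function() list(type = "relu")
ly_softplus <- function() list(type = "softplus")
ly_pool <- function() list(type = "pool")
ly_flatten <- function() list(type = "flatten")
ly_gmax <- function() list(type = "gmax")

ly_dense <- function(din, dout, wscale = 1) {
  sdv <- wscale * sqrt(2 / din)
  list(type = "dense", din = din, dout = dout,
       w = matrix(rnorm(din * dout, 0, sdv), din, dout),
       b = numeric(dout))
}

ly_resblock <- function(c) {
  list(type = "resblock",
       inner = list(ly_conv3(c, c), ly_bn(c), ly_relu(), ly_conv3(c, c), ly_bn(c)))
}

# ---- forward / backward ----

layer_fwd <- function(ly, t, training) {
  switch(ly$type,
    conv3 = {
      idx <- conv_idx(t$n, t$h, t$w)
      x0 <- rbind(0, t$x)
      xcol <- do.call(cbind, lapply(idx, function(iv) x0[iv + 1L, , drop = FALSE]))
      y <- add_bias(xcol %*% ly$w, ly$b)
      list(out = bt(y, t$n, t$h, t$w, ly$cout), cache = list(xcol = xcol, t = t), ly = ly)
    },
    conv1 = {
      y <- add_bias(t$x %*% ly$w, ly$b)
      list(out = bt(y, t$n, t$h, t$w, ly$cout), cache = list(t = t), ly = ly)
    },
    bn = {
      x <- t$x; m <- nrow(x)
      if (training && m > 1) {
        mu <- colMeans(x)
        xc <- x - rep(mu, each = m)
        v <- colSums(xc * xc) / m
        invstd <- 1 / sqrt(v + ly$eps)
        xhat <- xc * rep(invstd, each = m)
        ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * mu
        ly$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * v
      } else {
        invstd <- 1 / sqrt(ly$rvar + ly$eps)
        xhat <- (x - rep(ly$rmean, each = m)) * rep(invstd, each = m)
      }
      y <- xhat * rep(ly$gamma, each = m) + rep(ly$beta, each = m)
      out <- t; out$x <- y
      list(out = out, cache = list(xhat = xhat, invstd = invstd, m = m, training = training),
           ly = ly)
    },
    relu = {
      y <- t$x * (t$x > 0)
      out <- t; out$x <- y
      list(out = out, cache = list(pos = t$x > 0), ly = ly)
    },
    softplus = {
      x <- t$x
      y <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
      out <- t; out$x <- y
      list(out = out, cache = list(sig = 1 / (1 + exp(-pmin(pmax(x, -30), 30)))), ly = ly)
    },
    pool = {
      idx <- pool_idx(t$n, t$h, t$w)
      m <- t$x[idx[[1L]], , drop = FALSE]
      arg <- matrix(1L, nrow(m), ncol(m))
      for (k in 2:4) {
        g <- t$x[idx[[k]], , drop = FALSE]
        sel <- g > m
        m[sel] <- g[sel]
        arg[sel] <- k
      }
      list(out = bt(m, t$n, t$h %/% 2L, t$w %/% 2L, t$c),
           cache = list(arg = arg, t = t), ly = ly)
    },
    flatten = {
      hw <- t$h * t$w
      y <- matrix(aperm(array(t$x, c(hw, t$n, t$c)), c(2, 1, 3)), t$n, hw * t$c)
      list(out = list(x = y, n = t$n, h = 1L, w = 1L, c = ncol(y), flat = TRUE),
           cache = list(t = t), ly = ly)
    },
    gmax = {
      hw <- t$h * t$w
      y <- matrix(0, t$n, t$c)
      argrow <- matrix(0L, t$n, t$c)
      for (i in seq_len(t$n)) {
        rows <- ((i - 1) * hw + 1):(i * hw)
        blk <- t$x[rows, , drop = FALSE]
        am <- max.col(t(blk), ties.method = "first")
        argrow[i, ] <- rows[am]
        y[i, ] <- blk[cbind(am, seq_len(t$c))]
      }
      list(out = list(x = y, n = t$n, h = 1L, w = 1L, c = t$c, flat = TRUE),
           cache = list(argrow = argrow, t = t), ly = ly)
    },
    dense = {
      y <- add_bias(t$x %*% ly$w, ly$b)
      list(out = list(x = y, n = t$n, h = 1L, w = 1L, c = ly$dout, flat = TRUE),
           cache = list(t = t), ly = ly)
    },
    resblock = {
      res <- seq_fwd(ly$inner, t, training)
      ly$inner <- res$layers
      pre <- t$x + res$out$x
      out <- t; out$x <- pre * (pre > 0)
      list(out = out, cache = list(inner = res$caches, pos = pre > 0, t = t), ly = ly)
    },
    abort(paste("unknown layer type:", ly$type))
  )
}

layer_bwd <- function(ly, cache, gy) {
  switch(ly$type,
    conv3 = {
      t <- cache$t
      gw <- crossprod(cache$xcol, gy)
      gb <- colSums(gy)
      gcol <- gy %*% t(ly$w)
      gx <- matrix(0, nrow(t$x), t$c)
      idx <- conv_idx(t$n, t$h, t$w)
      cin <- t$c
      for (k in 1:9) {
        cols <- ((k - 1L) * cin + 1L):(k * cin)
        iv <- idx[[k]]
        pos <- iv > 0L
        tgt <- iv[pos]
        gx[tgt, ] <- gx[tgt, , drop = FALSE] + gcol[pos, cols, drop = FALSE]
      }
      list(gx = gx, grads = list(w = gw, b = gb))
    },
    conv1 = {
      list(gx = gy %*% t(ly$w),
           grads = list(w = crossprod(cache$t$x, gy), b = colSums(gy)))
    },
    bn = {
      m <- cache$m
      xhat <- cache$xhat
      ggamma <- colSums(gy * xhat)
      gbeta <- colSums(gy)
      gxhat <- gy * rep(ly$gamma, each = m)
      if (cache$training && m > 1) {
        s1 <- colSums(gxhat)
        s2 <- ly$gamma * ggamma  # = colSums(gxhat * xhat)
        gx <- (gxhat - rep(s1 / m, each = m) - xhat * rep(s2 / m, each = m)) *
          rep(cache$invstd, each = m)
      } else {
        gx <- gxhat * rep(cache$invstd, each = m)
      }
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    relu = list(gx = gy * cache$pos, grads = NULL),
    softplus = list(gx = gy * cache$sig, grads = NULL),
    pool = {
      t <- cache$t
      gx <- matrix(0, nrow(t$x), t$c)
      idx <- pool_idx(t$n, t$h, t$w)
      for (k in 1:4) {
        sel <- cache$arg == k
        if (!any(sel)) next
        tmp <- gy * sel
        gx[idx[[k]], ] <- gx[idx[[k]], , drop = FALSE] + tmp
      }
      list(gx = gx, grads = NULL)
    },
    flatten = {
      t <- cache$t
      hw <- t$h * t$w
      gx <- matrix(aperm(array(gy, c(t$n, hw, t$c)), c(2, 1, 3)), hw * t$n, t$c)
      list(gx = gx, grads = NULL)
    },
    gmax = {
      t <- cache$t
      gx <- matrix(0, nrow(t$x), t$c)
      for (ch in seq_len(t$c)) {
        gx[cbind(cache$argrow[, ch], ch)] <- gy[, ch]
      }
      list(gx = gx, grads = NULL)
    },
    dense = {
      list(gx = gy %*% t(ly$w),
           grads = list(w = crossprod(cache$t$x, gy), b = colSums(gy)))
    },
    resblock = {
      gpre <- gy * cache$pos
      inner <- seq_bwd(ly$inner, cache$inner, gpre)
      list(gx = gpre + inner$gx, grads = list(inner = inner$grads))
    },
    abort(paste("unknown layer type:", ly$type))
  )
}

seq_fwd <- function(layers, t, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], t, training)
    layers[[i]] <- r$ly
    caches[[i]] <- r$cache
    t <- r$out
  }
  list(out = t, caches = caches, layers = layers)
}

seq_bwd <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], caches[[i]], gy)
    grads[i] <- list(r$grads)  # keep NULL slots (parameter-free layers)
    gy <- r$gx
  }
  list(gx = gy, grads = grads)
}

# ---- parameter trees and optimizers ----

layer_params <- function(ly) {
  switch(ly$type,
    conv3 = , conv1 = , dense = list(w = ly$w, b = ly$b),
    bn = list(gamma = ly$gamma, beta = ly$beta),
    resblock = list(inner = lapply(ly$inner, layer_params)),
    NULL)
}

layer_set_params <- function(ly, p) {
  switch(ly$type,
    conv3 = , conv1 = , dense = { ly$w <- p$w; ly$b <- p$b },
    bn = { ly$gamma <- p$gamma; ly$beta <- p$beta },
    resblock = {
      for (i in seq_along(ly$inner)) {
        if (!is.null(p$inner[[i]])) ly$inner[[i]] <- layer_set_params(ly$inner[[i]], p$inner[[i]])
      }
    },
    NULL)
  ly
}

tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(do.call(f, trees))
  out <- a
  for (nm in seq_along(a)) {
    out[nm] <- list(do.call(tree_map, c(list(f), lapply(trees, `[[`, nm))))
  }
  out
}

opt_init <- function(layers, kind = c("adam", "sgd"), lr = 1e-3) {
  kind <- match.arg(kind)
  params <- lapply(layers, layer_params)
  zeros <- tree_map(function(p) p * 0, params)
  list(kind = kind, lr = lr, t = 0L, m = zeros, v = zeros)
}

opt_step <- function(layers, grads, state) {
  params <- lapply(layers, layer_params)
  if (state$kind == "sgd") {
    newp <- tree_map(function(p, g) p - state$lr * g, params, grads)
  } else {
    state$t <- state$t + 1L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
    state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
    c1 <- 1 / (1 - b1^state$t); c2 <- 1 / (1 - b2^state$t)
    newp <- tree_map(function(p, m, v) p - state$lr * (m * c1) / (sqrt(v * c2) + eps),
                     params, state$m, state$v)
  }
  for (i in seq_along(layers)) {
    if (!is.null(newp[[i]])) layers[[i]] <- layer_set_params(layers[[i]], newp[[i]])
  }
  list(layers = layers, state = state)
}

# minibatch index blocks for one epoch (seeded shuffling is the caller's job)
batch_blocks <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}
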