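# Minimal neural-network primitives with explicit forward/backward passes.
#
# Conventions:
#   - dense activations: N x D matrices (rows = samples)
#   - conv activations:  H x W x C x N arrays (channel-last, batch last)
#   - a layer is a list(type, params, buffers, cfg, sub); composite layers
#     (residual blocks) hold sublayers in $sub
#   - forward returns list(y, cache, layer): the layer comes back because
#     batch-norm running statistics update during training
#   - backward returns list(dx, grads) with grads mirroring the layer shape
#
# All heavy lifting is BLAS matrix multiplication via im2col; the im2col
# gather indices depend only on geometry and are memoised per shape.

.conv_memo <- new.env(parent = emptyenv())

new_layer <- function(type, params = list(), buffers = list(),
                      cfg = list(), sub = NULL) {
  list(type = type, params = params, buffers = buffers, cfg = cfg, sub = sub)
}

# ---- constructors ---------------------------------------------------------

layer_dense <- function(d_in, d_out, rng) {
  W <- matrix(rs_rnorm(rng, d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out)
  new_layer("dense", params = list(W = W, b = numeric(d_out)),
            cfg = list(d_in = d_in, d_out = d_out))
}

layer_bn1d <- function(d, eps = 1e-5, momentum = 0.1) {
  new_layer("bn1d",
            params = list(gamma = rep(1, d), beta = numeric(d)),
            buffers = list(running_mean = numeric(d), running_var = rep(1, d)),
            cfg = list(d = d, eps = eps, momentum = momentum))
}

layer_bn2d <- function(c, eps = 1e-5, momentum = 0.1) {
  l <- layer_bn1d(c, eps, momentum)
  l$type <- "bn2d"
  l
}

layer_relu <- function() new_layer("relu")

layer_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  new_layer("dropout", cfg = list(p = p))
}

layer_conv2d <- function(c_in, c_out, k, stride = 1L, pad = 0L, rng) {
  fan_in <- k * k * c_in
  W <- matrix(rs_rnorm(rng, fan_in * c_out, sd = sqrt(2 / fan_in)),
              fan_in, c_out)
  new_layer("conv2d", params = list(W = W, b = numeric(c_out)),
            cfg = list(c_in = c_in, c_out = c_out, k = as.integer(k),
                       stride = as.integer(stride), pad = as.integer(pad)))
}

layer_maxpool <- function(k, stride = k, pad = 0L) {
  new_layer("maxpool", cfg = list(k = as.integer(k),
                                  stride = as.integer(stride),
                                  pad = as.integer(pad)))
}

layer_gap <- function() new_layer("gap")

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      is.null(layers[[1]]$type)) layers <- layers[[1]]
  structure(list(layers = layers), class = "nn_sequential")
}

# ---- im2col machinery -----------------------------------------------------

conv_geometry <- function(H, W, k, stride, pad) {
  H <- unname(H); W <- unname(W)
  oh <- (H + 2L * pad - k) %/% stride + 1L
  ow <- (W + 2L * pad - k) %/% stride + 1L
  if (oh < 1L || ow < 1L) stop("convolution window larger than input")
  c(oh = oh, ow = ow)
}

# Gather matrix of linear indices into the zero-padded input, rows ordered
# (oh, ow, N), columns (k, k, C); memoised by full geometry.
im2col_index <- function(H, W, C, N, k, stride, pad) {
  key <- paste("c", H, W, C, N, k, stride, pad, sep = "_")
  hit <- .conv_memo[[key]]
  if (!is.null(hit)) return(hit)
  g <- conv_geometry(H, W, k, stride, pad)
  oh <- unname(g["oh"]); ow <- unname(g["ow"])
  Hp <- unname(H) + 2L * pad; Wp <- unname(W) + 2L * pad
  r_idx <- outer(seq(0L, by = stride, length.out = oh), seq_len(k), "+")
  c_idx <- outer(seq(0L, by = stride, length.out = ow), seq_len(k), "+")
  lin4 <- outer(r_idx, (c_idx - 1L) * Hp, "+")                  # oh,k,ow,k
  lin5 <- outer(lin4, (seq_len(C) - 1L) * (Hp * Wp), "+")       # oh,k,ow,k,C
  lin6 <- outer(lin5, (seq_len(N) - 1L) * (Hp * Wp * C), "+")   # ...,N
  perm <- aperm(lin6, c(1L, 3L, 6L, 2L, 4L, 5L))                # oh,ow,N,k,k,C
  out <- list(idx = matrix(as.integer(perm), oh * ow * N, k * k * C),
              oh = oh, ow = ow, Hp = Hp, Wp = Wp)
  .conv_memo[[key]] <- out
  out
}

pad_input <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# ---- forward dispatch -----------------------------------------------------

layer_forward <- function(layer, x, training = FALSE, rng = NULL) {
  switch(layer$type,
    dense = {
      y <- x %*% layer$params$W
      y <- y + rep(layer$params$b, each = nrow(y))
      list(y = y, cache = list(x = x), layer = layer)
    },
    relu = list(y = x * (x > 0), cache = list(mask = x > 0), layer = layer),
    dropout = {
      if (!training || layer$cfg$p == 0) {
        list(y = x, cache = list(mask = NULL), layer = layer)
      } else {
        if (is.null(rng)) stop("dropout in training mode needs an rng stream")
        keep <- 1 - layer$cfg$p
        mask <- (rs_runif(rng, length(x)) < keep) / keep
        dim(mask) <- dim(x)
        if (is.null(dim(x))) mask <- as.numeric(mask)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      }
    },
    bn1d = bn_forward(layer, x, training, reshape = FALSE),
    bn2d = bn_forward(layer, x, training, reshape = TRUE),
    conv2d = conv_forward(layer, x),
    maxpool = maxpool_forward(layer, x),
    gap = {
      d <- dim(x)
      m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
      y <- t(matrix(m, d[3], d[4]))
      list(y = y, cache = list(dims = d), layer = layer)
    },
    resblock = resblock_forward(layer, x, training, rng),
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dy, cache) {
  switch(layer$type,
    dense = list(
      dx = tcrossprod(dy, layer$params$W),
      grads = list(params = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    ),
    relu = list(dx = dy * cache$mask, grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    bn1d = bn_backward(layer, dy, cache),
    bn2d = bn_backward(layer, dy, cache),
    conv2d = conv_backward(layer, dy, cache),
    maxpool = maxpool_backward(layer, dy, cache),
    gap = {
      d <- cache$dims
      hw <- d[1] * d[2]
      dx <- array(rep(as.vector(t(dy)) / hw, each = hw), d)
      list(dx = dx, grads = NULL)
    },
    resblock = resblock_backward(layer, dy, cache),
    stop("unknown layer type: ", layer$type)
  )
}

# ---- batch norm -----------------------------------------------------------

bn_forward <- function(layer, x, training, reshape) {
  if (reshape) {
    d <- dim(x)                               # H W C N
    xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
  } else xm <- x
  n <- nrow(xm)
  eps <- layer$cfg$eps
  if (training) {
    if (n < 2L) stop("batch normalization in training mode needs batch size >= 2")
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    var_b <- colMeans(xc * xc)
    istd <- 1 / sqrt(var_b + eps)
    xhat <- xc * rep(istd, each = n)
    mom <- layer$cfg$momentum
    layer$buffers$running_mean <- (1 - mom) * layer$buffers$running_mean + mom * mu
    layer$buffers$running_var <-
      (1 - mom) * layer$buffers$running_var + mom * var_b * n / (n - 1)
  } else {
    istd <- 1 / sqrt(layer$buffers$running_var + eps)
    xhat <- (xm - rep(layer$buffers$running_mean, each = n)) *
      rep(istd, each = n)
  }
  y <- xhat * rep(layer$params$gamma, each = n) +
    rep(layer$params$beta, each = n)
  if (reshape) {
    y <- aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
    cache <- list(xhat = xhat, istd = istd, n = n, dims = d,
                  training = training)
  } else cache <- list(xhat = xhat, istd = istd, n = n, dims = NULL,
                       training = training)
  list(y = y, cache = cache, layer = layer)
}

bn_backward <- function(layer, dy, cache) {
  d <- cache$dims
  if (!is.null(d)) {
    dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
  } else dym <- dy
  n <- cache$n
  xhat <- cache$xhat
  ggamma <- colSums(dym * xhat)
  gbeta <- colSums(dym)
  if (cache$training) {
    dxhat <- dym * rep(layer$params$gamma, each = n)
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             xhat * rep(colMeans(dxhat * xhat), each = n)) *
      rep(cache$istd, each = n)
  } else {
    dx <- dym * rep(layer$params$gamma * cache$istd, each = n)
  }
  if (!is.null(d)) {
    dx <- aperm(array(dx, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
  }
  list(dx = dx, grads = list(params = list(gamma = ggamma, beta = gbeta)))
}

# ---- convolution ----------------------------------------------------------

conv_forward <- function(layer, x) {
  d <- dim(x)
  cfg <- layer$cfg
  if (d[3] != cfg$c_in)
    stop("conv2d expected ", cfg$c_in, " input channels, got ", d[3])
  ii <- im2col_index(d[1], d[2], d[3], d[4], cfg$k, cfg$stride, cfg$pad)
  xp <- pad_input(x, cfg$pad)
  M <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  y <- M %*% layer$params$W
  y <- y + rep(layer$params$b, each = nrow(y))
  out <- aperm(array(y, c(ii$oh, ii$ow, d[4], cfg$c_out)), c(1L, 2L, 4L, 3L))
  list(y = out, cache = list(M = M, in_dims = d, ii = ii), layer = layer)
}

conv_backward <- function(layer, dy, cache) {
  cfg <- layer$cfg
  d <- cache$in_dims
  ii <- cache$ii
  oh <- ii$oh; ow <- ii$ow; N <- d[4]
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), oh * ow * N, cfg$c_out)
  gW <- crossprod(cache$M, dym)
  gb <- colSums(dym)
  dM <- tcrossprod(dym, layer$params$W)
  dMarr <- array(dM, c(oh, ow, N, cfg$k, cfg$k, d[3]))
  dxp <- array(0, c(ii$Hp, ii$Wp, d[3], N))
  for (ki in seq_len(cfg$k)) {
    rows <- seq(ki, by = cfg$stride, length.out = oh)
    for (kj in seq_len(cfg$k)) {
      cols <- seq(kj, by = cfg$stride, length.out = ow)
      slab <- array(dMarr[, , , ki, kj, , drop = FALSE], c(oh, ow, N, d[3]))
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] +
        aperm(slab, c(1L, 2L, 4L, 3L))
    }
  }
  p <- cfg$pad
  dx <- if (p == 0L) dxp else
    dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, grads = list(params = list(W = gW, b = gb)))
}

# ---- max pooling ----------------------------------------------------------

maxpool_index <- function(H, W, C, N, k, stride, pad) {
  key <- paste("p", H, W, C, N, k, stride, pad, sep = "_")
  hit <- .conv_memo[[key]]
  if (!is.null(hit)) return(hit)
  g <- conv_geometry(H, W, k, stride, pad)
  oh <- unname(g["oh"]); ow <- unname(g["ow"])
  Hp <- unname(H) + 2L * pad; Wp <- unname(W) + 2L * pad
  r_idx <- outer(seq(0L, by = stride, length.out = oh), seq_len(k), "+")
  c_idx <- outer(seq(0L, by = stride, length.out = ow), seq_len(k), "+")
  lin4 <- aperm(outer(r_idx, (c_idx - 1L) * Hp, "+"), c(1L, 3L, 2L, 4L))
  base <- matrix(as.integer(lin4), oh * ow, k * k)
  offs <- as.vector(outer((seq_len(C) - 1L) * (Hp * Wp),
                          (seq_len(N) - 1L) * (Hp * Wp * C), "+"))
  idx <- base[rep(seq_len(oh * ow), length(offs)), , drop = FALSE] +
    rep(offs, each = oh * ow)
  out <- list(idx = idx, oh = oh, ow = ow, Hp = Hp, Wp = Wp)
  .conv_memo[[key]] <- out
  out
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  cfg <- layer$cfg
  ii <- maxpool_index(d[1], d[2], d[3], d[4], cfg$k, cfg$stride, cfg$pad)
  xp <- pad_input(x, cfg$pad, fill = -Inf)
  vals <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  m <- vals[, 1]
  for (j in 2:ncol(vals)) m <- pmax(m, vals[, j])
  amax <- max.col(vals, ties.method = "first")
  chosen <- ii$idx[cbind(seq_len(nrow(vals)), amax)]
  y <- array(m, c(ii$oh, ii$ow, d[3], d[4]))
  list(y = y, cache = list(chosen = chosen, in_dims = d, ii = ii),
       layer = layer)
}

maxpool_backward <- function(layer, dy, cache) {
  d <- cache$in_dims
  ii <- cache$ii
  p <- layer$cfg$pad
  dxp_vec <- numeric(ii$Hp * ii$Wp * d[3] * d[4])
  agg <- rowsum(as.vector(dy), cache$chosen)
  dxp_vec[as.integer(rownames(agg))] <- agg[, 1]
  dxp <- array(dxp_vec, c(ii$Hp, ii$Wp, d[3], d[4]))
  dx <- if (p == 0L) dxp else
    dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, grads = NULL)
}

# ---- residual bottleneck block (1x1 -> 3x3 -> 1x1, identity skip) ---------

layer_bottleneck <- function(c_in, c_mid, stride, rng) {
  c_out <- 4L * c_mid
  sub <- list(
    conv1 = layer_conv2d(c_in, c_mid, 1L, 1L, 0L, rng),
    bn1 = layer_bn2d(c_mid),
    conv2 = layer_conv2d(c_mid, c_mid, 3L, stride, 1L, rng),
    bn2 = layer_bn2d(c_mid),
    conv3 = layer_conv2d(c_mid, c_out, 1L, 1L, 0L, rng),
    bn3 = layer_bn2d(c_out)
  )
  if (stride != 1L || c_in != c_out) {
    sub$down_conv <- layer_conv2d(c_in, c_out, 1L, stride, 0L, rng)
    sub$down_bn <- layer_bn2d(c_out)
  }
  new_layer("resblock", cfg = list(c_in = c_in, c_out = c_out,
                                   stride = as.integer(stride)), sub = sub)
}

resblock_forward <- function(layer, x, training, rng) {
  sub <- layer$sub
  caches <- list()
  run <- function(name, inp) {
    r <- layer_forward(sub[[name]], inp, training, rng)
    sub[[name]] <<- r$layer
    caches[[name]] <<- r$cache
    r$y
  }
  h <- run("conv1", x); h <- run("bn1", h)
  m1 <- h > 0; h <- h * m1
  h <- run("conv2", h); h <- run("bn2", h)
  m2 <- h > 0; h <- h * m2
  h <- run("conv3", h); h <- run("bn3", h)
  idn <- if (!is.null(sub$down_conv)) {
    run("down_bn", run("down_conv", x))
  } else x
  s <- h + idn
  m3 <- s > 0
  layer$sub <- sub
  list(y = s * m3,
       cache = list(caches = caches, m1 = m1, m2 = m2, m3 = m3,
                    has_down = !is.null(sub$down_conv)),
       layer = layer)
}

resblock_backward <- function(layer, dy, cache) {
  sub <- layer$sub
  grads <- list()
  back <- function(name, d) {
    r <- layer_backward(sub[[name]], d, cache$caches[[name]])
    grads[[name]] <<- r$grads
    r$dx
  }
  ds <- dy * cache$m3
  dh <- back("bn3", ds); dh <- back("conv3", dh)
  dh <- dh * cache$m2
  dh <- back("bn2", dh); dh <- back("conv2", dh)
  dh <- dh * cache$m1
  dx_main <- back("conv1", back("bn1", dh))
  dx_id <- if (cache$has_down) back("down_conv", back("down_bn", ds)) else ds
  list(dx = dx_main + dx_id, grads = list(sub = grads))
}

# ---- container forward/backward ------------------------------------------

nn_forward <- function(net, x, training = FALSE, rng = NULL) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, training, rng)
    x <- r$y
    caches[[i]] <- r$cache
    net$layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, net = net)
}

nn_backward <- function(net, dy, caches) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], dy, caches[[i]])
    dy <- r$dx
    grads[i] <- list(r$grads)
  }
  list(dx = dy, grads = grads)
}

# ---- optimiser ------------------------------------------------------------

init_velocity_layer <- function(layer) {
  v <- list()
  if (!is.null(layer$sub))
    v$sub <- lapply(layer$sub, init_velocity_layer)
  if (length(layer$params))
    v$params <- lapply(layer$params, function(p) p * 0)
  v
}

init_velocity <- function(net) lapply(net$layers, init_velocity_layer)

sgd_layer <- function(layer, grads, vel, lr, momentum, wd) {
  if (!is.null(layer$sub)) {
    for (nm in names(layer$sub)) {
      r <- sgd_layer(layer$sub[[nm]], grads$sub[[nm]], vel$sub[[nm]],
                     lr, momentum, wd)
      layer$sub[[nm]] <- r$layer
      vel$sub[[nm]] <- r$vel
    }
  }
  if (length(layer$params)) {
    for (nm in names(layer$params)) {
      g <- grads$params[[nm]] + wd * layer$params[[nm]]
      v <- momentum * vel$params[[nm]] + g
      vel$params[[nm]] <- v
      layer$params[[nm]] <- layer$params[[nm]] - lr * v
    }
  }
  list(layer = layer, vel = vel)
}

# One SGD-with-momentum step over a whole sequential net (in functional
# style: returns the updated net and velocity).
sgd_step_net <- function(net, grads, vel, lr, momentum, wd) {
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]]) && !length(net$layers[[i]]$params) &&
        is.null(net$layers[[i]]$sub)) next
    r <- sgd_layer(net$layers[[i]], grads[[i]], vel[[i]], lr, momentum, wd)
    net$layers[[i]] <- r$layer
    vel[[i]] <- r$vel
  }
  list(net = net, vel = vel)
}

n_params_layer <- function(layer) {
  n <- sum(vapply(layer$params, length, integer(1)))
  if (!is.null(layer$sub))
    n <- n + sum(vapply(layer$sub, n_params_layer, numeric(1)))
  n
}

n_params <- function(net) sum(vapply(net$layers, n_params_layer, numeric(1)))

count_layer_types <- function(net) {
  counts <- integer(0)
  bump <- function(layer) {
    counts[layer$type] <<- (if (is.na(counts[layer$type])) 0L
                            else counts[layer$type]) + 1L
    if (!is.null(layer$sub)) for (l in layer$sub) bump(l)
  }
  for (l in net$layers) bump(l)
  counts
}
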