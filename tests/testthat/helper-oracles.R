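# Independent brute-force oracles used to pin down expected values.

# Six-term pairwise loss: normalize every vector, take the six ordered-pair
# dot products with weight 1/2, divide by 3. Written without any package
# internals.
triloss_oracle <- function(z1, z2, z3, v1, v2, v3) {
  nrm <- function(x) x / sqrt(sum(x^2))
  zs <- lapply(list(z1, z2, z3), nrm)
  vs <- lapply(list(v1, v2, v3), nrm)
  pairs <- list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  s <- sum(vapply(pairs, function(p)
    0.5 * -sum(zs[[p[1]]] * vs[[p[2]]]), numeric(1)))
  s / 3
}

# Direct 2-D Gaussian convolution with edge-repeating reflective padding,
# double loop over output pixels.
gaussian_blur_oracle <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k1 <- dnorm(-r:r, sd = sigma)
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  d <- dim(img)
  out <- array(0, d)
  for (ch in 1:d[3]) for (i in 1:d[1]) for (j in 1:d[2]) {
    ii <- refl(i + (-r:r), d[1])
    jj <- refl(j + (-r:r), d[2])
    out[i, j, ch] <- sum(k2 * img[ii, jj, ch])
  }
  out
}

# One-vs-rest confusion-matrix metrics, computed per class from first
# principles (rows = truth, cols = prediction).
metrics_oracle <- function(cm) {
  n <- sum(cm)
  k <- nrow(cm)
  per <- t(vapply(seq_len(k), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }, numeric(3)))
  list(accuracy = sum(diag(cm)) / n,
       precision = mean(per[, "precision"]),
       recall = mean(per[, "recall"]),
       f1 = mean(per[, "f1"]),
       per_class = per)
}

# Central finite differences of a scalar function of a vector.
numeric_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    up <- x; up[i] <- up[i] + h
    dn <- x; dn[i] <- dn[i] - h
    g[i] <- (f(up) - f(dn)) / (2 * h)
  }
  g
}

# Small shared fixtures -----------------------------------------------------

tiny_model_cfg <- function(seed = 2L) {
  model_config("tinycnn", feature_dim = 8L, proj_dim = 16L,
               pred_hidden_dim = 8L, seed = seed)
}

tiny_train_cfg <- function(..., seed = 5L) {
  train_config(image_size = 16L, epochs = 2L, batch_size = 4L,
               model = tiny_model_cfg(), seed = seed, ...)
}

random_images <- function(n, size = 16L, seed = 1L) {
  rng <- rng_stream(seed)
  lapply(seq_len(n), function(i)
    array(rs_runif(rng, size * size * 3L), c(size, size, 3L)))
}

tiny_synth_spec <- function(...) {
  synthetic_spec(n_classes = 4L, n_per_class = 10L, image_size = 24L,
                 seed = 7L, ...)
}

# A triview-shaped object around an untrained (randomly initialised) model,
# for pretrained-vs-random baseline comparisons.
random_init_fit <- function(model_cfg, train_cfg) {
  structure(list(model = build_model(model_cfg), config = train_cfg),
            class = "triview")
}
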