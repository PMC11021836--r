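#' Augmentation configuration
#'
#' Parameters of the stochastic view-generation pipeline. One source image
#' is turned into a view by applying, in order: random resized crop (with
#' resize to `out_size`), colour jitter, random greyscale, Gaussian blur,
#' horizontal flip and vertical flip. Defaults follow the pretraining
#' recipe: crop scale 0.08-1.0 with aspect ratio 3/4-4/3, colour jitter
#' (brightness 0.32, contrast and saturation 0.68-1.32, hue 0.02) applied
#' with probability 0.8, greyscale with probability 0.2, Gaussian blur with
#' a standard deviation drawn uniformly from 0.1-2.0 pixels, and both flips
#' with probability 0.5.
#'
#' @param crop_scale_lo,crop_scale_hi bounds on the crop area as a fraction
#'   of the source image area.
#' @param aspect_lo,aspect_hi bounds on the crop aspect ratio (width/height).
#' @param out_size output resolution in pixels (square views).
#' @param brightness brightness delta; factor drawn from
#'   `[1 - brightness, 1 + brightness]`.
#' @param contrast_lo,contrast_hi contrast factor range.
#' @param saturation_lo,saturation_hi saturation factor range.
#' @param hue hue shift bound, in fractions of a full hue revolution.
#' @param jitter_p probability that colour jitter is applied at all.
#' @param gray_p probability of greyscale conversion.
#' @param blur_sigma_lo,blur_sigma_hi Gaussian blur std bounds, in pixels.
#' @param blur_p probability of applying the blur (default 1: always).
#' @param hflip_p,vflip_p flip probabilities.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(crop_scale_lo = 0.08, crop_scale_hi = 1.0,
                           aspect_lo = 3 / 4, aspect_hi = 4 / 3,
                           out_size = 256L,
                           brightness = 0.32,
                           contrast_lo = 0.68, contrast_hi = 1.32,
                           saturation_lo = 0.68, saturation_hi = 1.32,
                           hue = 0.02,
                           jitter_p = 0.8, gray_p = 0.2,
                           blur_sigma_lo = 0.1, blur_sigma_hi = 2.0,
                           blur_p = 1.0,
                           hflip_p = 0.5, vflip_p = 0.5) {
  cfg <- list(
    crop_scale_lo = crop_scale_lo, crop_scale_hi = crop_scale_hi,
    aspect_lo = aspect_lo, aspect_hi = aspect_hi,
    out_size = as.integer(out_size),
    brightness = brightness,
    contrast_lo = contrast_lo, contrast_hi = contrast_hi,
    saturation_lo = saturation_lo, saturation_hi = saturation_hi,
    hue = hue, jitter_p = jitter_p, gray_p = gray_p,
    blur_sigma_lo = blur_sigma_lo, blur_sigma_hi = blur_sigma_hi,
    blur_p = blur_p, hflip_p = hflip_p, vflip_p = vflip_p
  )
  probs <- c(jitter_p, gray_p, blur_p, hflip_p, vflip_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!(crop_scale_lo > 0 && crop_scale_lo <= crop_scale_hi && crop_scale_hi <= 1))
    stop("need 0 < crop_scale_lo <= crop_scale_hi <= 1")
  if (aspect_lo > aspect_hi || aspect_lo <= 0)
    stop("need 0 < aspect_lo <= aspect_hi")
  if (blur_sigma_lo > blur_sigma_hi || blur_sigma_lo <= 0)
    stop("need 0 < blur_sigma_lo <= blur_sigma_hi")
  if (cfg$out_size < 1L) stop("out_size must be >= 1")
  if (brightness < 0 || brightness > 1) stop("brightness delta must be in [0, 1]")
  structure(cfg, class = "augment_config")
}

#' Random resized crop
#'
#' Samples a crop whose area is a uniform fraction of the source area in
#' `[crop_scale_lo, crop_scale_hi]` and whose aspect ratio is log-uniform in
#' `[aspect_lo, aspect_hi]`, then resizes it to `out_size` x `out_size`
#' (bilinear). After ten rejected proposals it falls back to the largest
#' centred crop with the aspect ratio clamped into range.
#'
#' @param img source image (see [as_image()]).
#' @param cfg an [augment_config()].
#' @param rng an [rng_stream()].
#' @return an `out_size` x `out_size` x 3 image. The realized crop geometry
#'   is attached as attribute `"crop"` (top, left, height, width).
#' @export
random_resized_crop <- function(img, cfg, rng) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (H < 2 || W < 2)
    stop("image too small to crop: need at least 2x2 pixels, got ",
         H, "x", W)
  area <- H * W
  crop <- NULL
  for (attempt in 1:10) {
    target <- rs_runif(rng, 1L, cfg$crop_scale_lo, cfg$crop_scale_hi) * area
    ar <- exp(rs_runif(rng, 1L, log(cfg$aspect_lo), log(cfg$aspect_hi)))
    w <- as.integer(round(sqrt(target * ar)))
    h <- as.integer(round(sqrt(target / ar)))
    if (w < 1L || h < 1L || w > W || h > H) next
    frac <- (w * h) / area
    ratio <- w / h
    if (frac < cfg$crop_scale_lo || frac > cfg$crop_scale_hi) next
    if (ratio < cfg$aspect_lo || ratio > cfg$aspect_hi) next
    top <- rs_sample_int(rng, H - h + 1L)
    left <- rs_sample_int(rng, W - w + 1L)
    crop <- c(top = top, left = left, height = h, width = w)
    break
  }
  if (is.null(crop)) {
    in_ratio <- W / H
    if (in_ratio < cfg$aspect_lo) {
      w <- W; h <- max(1L, min(H, as.integer(round(W / cfg$aspect_lo))))
    } else if (in_ratio > cfg$aspect_hi) {
      h <- H; w <- max(1L, min(W, as.integer(round(H * cfg$aspect_hi))))
    } else {
      w <- W; h <- H
    }
    crop <- c(top = (H - h) %/% 2L + 1L, left = (W - w) %/% 2L + 1L,
              height = h, width = w)
  }
  out <- resize_bilinear(
    crop_image(img, crop["top"], crop["left"], crop["height"], crop["width"]),
    cfg$out_size, cfg$out_size
  )
  attr(out, "crop") <- crop
  out
}

#' Colour jitter
#'
#' With probability `jitter_p`, applies brightness, contrast, saturation and
#' hue perturbations in a random order; each factor is drawn uniformly from
#' its configured range. Contrast and saturation blend towards the mean
#' luminance and the per-pixel luminance respectively; hue is shifted in HSV
#' space with wrap-around. Output is clipped to \[0, 1\] after each step.
#'
#' @inheritParams random_resized_crop
#' @return a jittered image of the same shape.
#' @export
color_jitter <- function(img, cfg, rng) {
  if (!rs_bernoulli(rng, cfg$jitter_p)) return(img)
  ord <- rs_sample_int(rng, 4L, 4L)
  bf <- rs_runif(rng, 1L, 1 - cfg$brightness, 1 + cfg$brightness)
  cf <- rs_runif(rng, 1L, cfg$contrast_lo, cfg$contrast_hi)
  sf <- rs_runif(rng, 1L, cfg$saturation_lo, cfg$saturation_hi)
  hd <- rs_runif(rng, 1L, -cfg$hue, cfg$hue)
  for (op in ord) {
    img <- switch(op,
      clip01(img * bf),                                    # brightness
      {                                                    # contrast
        m <- mean(luminance(img))
        clip01(img * cf + (1 - cf) * m)
      },
      {                                                    # saturation
        g <- to_grayscale(img)
        clip01(img * sf + (1 - sf) * g)
      },
      {                                                    # hue
        if (hd == 0) img else {
          hsv <- rgb_to_hsv_img(img)
          hsv[, , 1] <- (hsv[, , 1] + hd) %% 1
          clip01(hsv_to_rgb_img(hsv))
        }
      }
    )
  }
  img
}

# Isotropic Gaussian convolution, separable, reflective padding, kernel
# truncated at radius ceiling(4 * sigma) (odd total size by construction).
convolve_gaussian <- function(img, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(img)
  pass <- function(x, n_dim) {
    n <- dim(x)[n_dim]
    idx <- reflect_index((1L - r):(n + r), n)
    if (n_dim == 1L) {
      padded <- x[idx, , , drop = FALSE]
      out <- array(0, dim(x))
      for (t in seq_along(k))
        out <- out + k[t] * padded[t:(t + n - 1L), , , drop = FALSE]
    } else {
      padded <- x[, idx, , drop = FALSE]
      out <- array(0, dim(x))
      for (t in seq_along(k))
        out <- out + k[t] * padded[, t:(t + n - 1L), , drop = FALSE]
    }
    out
  }
  pass(pass(img, 1L), 2L)
}

# Reflect indices into [1, n] with the edge repeated (d c b a | a b c d |
# d c b a); this convention makes Gaussian smoothing conserve total
# intensity exactly. Handles any overshoot.
reflect_index <- function(i, n) {
  period <- 2L * n
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Gaussian blur
#'
#' Convolves each channel with an isotropic Gaussian kernel whose standard
#' deviation is drawn uniformly from `[blur_sigma_lo, blur_sigma_hi]`
#' (pixels). The kernel is truncated at radius `ceiling(4 * sigma)` and the
#' image is reflectively padded (edge repeated), so a constant image and
#' the total pixel sum are preserved exactly.
#'
#' @inheritParams random_resized_crop
#' @return the blurred image; the drawn std is attached as attribute
#'   `"sigma"`.
#' @export
gaussian_blur <- function(img, cfg, rng) {
  sigma <- rs_runif(rng, 1L, cfg$blur_sigma_lo, cfg$blur_sigma_hi)
  out <- convolve_gaussian(img, sigma)
  attr(out, "sigma") <- sigma
  out
}

#' Generate one augmented view
#'
#' Applies the full pipeline in its fixed order: random resized crop (which
#' includes the resize to `out_size`), colour jitter, random greyscale,
#' Gaussian blur (with probability `blur_p`), horizontal flip, vertical
#' flip.
#'
#' @inheritParams random_resized_crop
#' @return an `out_size` x `out_size` x 3 image in \[0, 1\].
#' @export
augment_view <- function(img, cfg, rng) {
  img <- as_image(img)
  out <- random_resized_crop(img, cfg, rng)
  attr(out, "crop") <- NULL
  out <- color_jitter(out, cfg, rng)
  if (rs_bernoulli(rng, cfg$gray_p)) out <- to_grayscale(out)
  if (rs_bernoulli(rng, cfg$blur_p)) {
    out <- gaussian_blur(out, cfg, rng)
    attr(out, "sigma") <- NULL
  }
  if (rs_bernoulli(rng, cfg$hflip_p)) out <- flip_horizontal(out)
  if (rs_bernoulli(rng, cfg$vflip_p)) out <- flip_vertical(out)
  out
}

#' Generate a view triplet
#'
#' Draws three independent augmented views of one image from three
#' decorrelated substreams of `rng`, so the triplet is reproducible from the
#' stream alone and the three views are conditionally independent given it.
#'
#' @inheritParams random_resized_crop
#' @return a list of class `view_triplet` with elements `x1`, `x2`, `x3`.
#' @export
make_triplet <- function(img, cfg, rng) {
  seeds <- rs_sample_int(rng, 2147483646L, 3L, replace = TRUE)
  views <- lapply(1:3, function(v)
    augment_view(img, cfg, rng_substream(seeds[v], v)))
  structure(list(x1 = views[[1]], x2 = views[[2]], x3 = views[[3]]),
            class = "view_triplet")
}
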