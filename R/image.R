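#' Images as numeric arrays
#'
#' Throughout the package an image is a rank-3 numeric array of shape
#' height x width x 3 with float values in \[0, 1\], channel-last, 1-based
#' pixel indexing. `as_image()` validates (and if needed expands a greyscale
#' or RGBA decode to) that convention.
#'
#' @param x numeric array; H x W (greyscale), H x W x 1, H x W x 3 or
#'   H x W x 4 (alpha dropped).
#' @return a valid H x W x 3 array in \[0, 1\].
#' @export
as_image <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("an image must be a height x width x channel array")
  d <- dim(x)
  if (d[3] == 1L) x <- array(rep(x, 3L), c(d[1], d[2], 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] != 3L)
    stop("an image must have 1, 3 or 4 channels, got ", d[3])
  if (!is.numeric(x) || anyNA(x)) stop("image pixels must be finite numerics")
  if (min(x) < 0 || max(x) > 1)
    stop("image pixel values must lie in [0, 1]")
  x
}

is_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L &&
    is.numeric(x) && !anyNA(x) && min(x) >= 0 && max(x) <= 1
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Bilinear resize
#'
#' Resizes an image with bilinear interpolation using the half-pixel-centre
#' convention (source coordinate `(i - 0.5) * scale + 0.5`), so resizing to
#' the source resolution is the exact identity.
#'
#' @param img an image array (see [as_image()]).
#' @param out_h,out_w output height and width in pixels.
#' @return the resized H x W x 3 image.
#' @export
resize_bilinear <- function(img, out_h, out_w = out_h) {
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (out_h < 1 || out_w < 1) stop("output size must be >= 1")
  sy <- H / out_h; sx <- W / out_w
  src_y <- (seq_len(out_h) - 0.5) * sy + 0.5
  src_x <- (seq_len(out_w) - 0.5) * sx + 0.5
  y0 <- floor(src_y); x0 <- floor(src_x)
  wy <- pmin(pmax(src_y - y0, 0), 1)
  wx <- pmin(pmax(src_x - x0, 0), 1)
  y0c <- pmin(pmax(y0, 1), H); y1c <- pmin(pmax(y0 + 1, 1), H)
  x0c <- pmin(pmax(x0, 1), W); x1c <- pmin(pmax(x0 + 1, 1), W)
  out <- array(0, c(out_h, out_w, C))
  w00 <- outer(1 - wy, 1 - wx); w01 <- outer(1 - wy, wx)
  w10 <- outer(wy, 1 - wx);     w11 <- outer(wy, wx)
  for (ch in seq_len(C)) {
    m <- img[, , ch]
    out[, , ch] <- w00 * m[y0c, x0c, drop = FALSE] +
      w01 * m[y0c, x1c, drop = FALSE] +
      w10 * m[y1c, x0c, drop = FALSE] +
      w11 * m[y1c, x1c, drop = FALSE]
  }
  out
}

#' Flip an image
#'
#' `flip_horizontal()` mirrors left-right, `flip_vertical()` top-bottom.
#' Both are involutions: applying the same flip twice restores the input.
#'
#' @param img an image array.
#' @return the flipped image.
#' @export
flip_horizontal <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

#' @rdname flip_horizontal
#' @export
flip_vertical <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

crop_image <- function(img, top, left, h, w) {
  d <- dim(img)
  stopifnot(top >= 1, left >= 1, top + h - 1 <= d[1], left + w - 1 <= d[2])
  img[top:(top + h - 1), left:(left + w - 1), , drop = FALSE]
}

# Luminance (ITU-R BT.601 weights), returned as an H x W matrix.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Greyscale an image
#'
#' Replaces each channel with the BT.601 luminance, so all three channels
#' are equal pixel-wise afterwards.
#'
#' @param img an image array.
#' @return an H x W x 3 image with identical channels.
#' @export
to_grayscale <- function(img) {
  g <- luminance(img)
  array(rep(g, 3L), dim(img))
}

# Vectorized RGB <-> HSV on whole images; h, s, v all in [0, 1].
rgb_to_hsv_img <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  dlt <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- dlt > 0
  rmax <- nz & (mx == r)
  gmax <- nz & (mx == g) & !rmax
  bmax <- nz & !rmax & !gmax
  h[rmax] <- ((g - b)[rmax] / dlt[rmax]) %% 6
  h[gmax] <- (b - r)[gmax] / dlt[gmax] + 2
  h[bmax] <- (r - g)[bmax] / dlt[bmax] + 4
  h <- h / 6
  s <- ifelse(mx > 0, dlt / mx, 0)
  array(c(h, s, mx), dim(img))
}

hsv_to_rgb_img <- function(hsv) {
  h <- (hsv[, , 1] %% 1) * 6
  s <- hsv[, , 2]; v <- hsv[, , 3]
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  i0 <- i == 0; i1 <- i == 1; i2 <- i == 2
  i3 <- i == 3; i4 <- i == 4; i5 <- i >= 5
  r[i1] <- q[i1]; r[i2] <- p[i2]; r[i3] <- p[i3]; r[i4] <- t[i4]
  g[i0] <- t[i0]; g[i3] <- q[i3]; g[i4] <- p[i4]; g[i5] <- p[i5]
  b[i0] <- p[i0]; b[i1] <- p[i1]; b[i2] <- t[i2]; b[i5] <- q[i5]
  array(c(r, g, b), dim(hsv))
}

# Stack a list of H x W x 3 images into an H x W x 3 x N batch array.
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}
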