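test_that("augment_config validates its invariants", {
  expect_s3_class(augment_config(), "augment_config")
  expect_error(augment_config(jitter_p = 1.2), "probabilities")
  expect_error(augment_config(crop_scale_lo = 0), "crop_scale")
  expect_error(augment_config(crop_scale_lo = 0.5, crop_scale_hi = 0.2))
  expect_error(augment_config(blur_sigma_lo = 3, blur_sigma_hi = 1))
  expect_error(augment_config(out_size = 0), "out_size")
})

test_that("an identity crop reproduces the resized source", {
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  cfg <- augment_config(crop_scale_lo = 1, crop_scale_hi = 1,
                        aspect_lo = 1, aspect_hi = 1, out_size = 12)
  out <- random_resized_crop(img, cfg, rng_stream(1))
  attr(out, "crop") <- NULL
  expect_equal(out, resize_bilinear(img, 12, 12))
})

test_that("realized crop area and aspect stay in the configured ranges", {
  cfg <- augment_config(out_size = 8)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  rng <- rng_stream(3)
  for (i in 1:500) {
    crop <- attr(random_resized_crop(img, cfg, rng), "crop")
    frac <- (crop["height"] * crop["width"]) / (64 * 64)
    expect_gte(frac, 0.08)
    expect_lte(frac, 1)
    ratio <- crop["width"] / crop["height"]
    expect_gte(ratio, 3 / 4 - 1e-12)
    expect_lte(ratio, 4 / 3 + 1e-12)
  }
})

test_that("cropping is deterministic under a fixed seed and rejects tiny images", {
  img <- array(runif(30 * 30 * 3), c(30, 30, 3))
  cfg <- augment_config(out_size = 10)
  expect_identical(random_resized_crop(img, cfg, rng_stream(5)),
                   random_resized_crop(img, cfg, rng_stream(5)))
  expect_error(random_resized_crop(array(0.5, c(1, 5, 3)), cfg, rng_stream(1)),
               "too small")
})

test_that("colour jitter honours its probability and identity settings", {
  img <- array(runif(8 * 8 * 3, 0.2, 0.8), c(8, 8, 3))
  cfg0 <- augment_config(jitter_p = 0)
  expect_identical(color_jitter(img, cfg0, rng_stream(1)), img)

  cfg_id <- augment_config(jitter_p = 1, brightness = 0,
                           contrast_lo = 1, contrast_hi = 1,
                           saturation_lo = 1, saturation_hi = 1, hue = 0)
  expect_equal(color_jitter(img, cfg_id, rng_stream(2)), img,
               tolerance = 1e-12)

  # application rate ~ 0.8 within 3 binomial standard errors
  cfg <- augment_config()
  rng <- rng_stream(11)
  n <- 400
  changed <- 0L
  small <- array(runif(4 * 4 * 3, 0.3, 0.7), c(4, 4, 3))
  for (i in seq_len(n))
    if (!identical(color_jitter(small, cfg, rng), small)) changed <- changed + 1L
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(changed / n - 0.8), 3 * se)
})

test_that("jittered output stays inside [0, 1]", {
  rng <- rng_stream(4)
  cfg <- augment_config()
  for (i in 1:25) {
    img <- array(rs_runif(rng, 6 * 6 * 3), c(6, 6, 3))
    out <- color_jitter(img, cfg, rng)
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
})

test_that("gaussian blur matches the brute-force oracle and conserves mass", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  for (sigma in c(0.4, 1.1, 2.0)) {
    ours <- triview:::convolve_gaussian(img, sigma)
    expect_equal(ours, gaussian_blur_oracle(img, sigma), tolerance = 1e-10)
    expect_lt(abs(sum(ours) - sum(img)) / sum(img), 1e-4)
  }
  const <- array(0.37, c(8, 8, 3))
  expect_equal(triview:::convolve_gaussian(const, 1.7), const,
               tolerance = 1e-12)
})

test_that("blur sigmas are drawn from the configured interval", {
  cfg <- augment_config()
  rng <- rng_stream(8)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  sigmas <- replicate(300, attr(gaussian_blur(img, cfg, rng), "sigma"))
  expect_gte(min(sigmas), 0.1)
  expect_lte(max(sigmas), 2.0)
  # draws actually spread over the interval
  expect_gt(diff(range(sigmas)), 1.5)
})

test_that("a fully degenerate config makes augment_view the resize map", {
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  cfg <- augment_config(crop_scale_lo = 1, crop_scale_hi = 1,
                        aspect_lo = 1, aspect_hi = 1, out_size = 10,
                        jitter_p = 0, gray_p = 0, blur_p = 0,
                        hflip_p = 0, vflip_p = 0)
  expect_equal(augment_view(img, cfg, rng_stream(3)),
               resize_bilinear(img, 10, 10))
})

test_that("the grayscale branch yields three equal channels at its configured rate", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  cfg1 <- augment_config(out_size = 8, gray_p = 1, jitter_p = 0, blur_p = 0)
  v <- augment_view(img, cfg1, rng_stream(2))
  expect_equal(v[, , 1], v[, , 2])
  expect_equal(v[, , 2], v[, , 3])

  is_gray <- function(x) isTRUE(all.equal(x[, , 1], x[, , 2])) &&
    isTRUE(all.equal(x[, , 2], x[, , 3]))
  count_gray <- function(p, n, seed) {
    cfg <- augment_config(out_size = 6, gray_p = p, jitter_p = 0, blur_p = 0)
    rng <- rng_stream(seed)
    sum(vapply(seq_len(n), function(i)
      is_gray(augment_view(img, cfg, rng)), logical(1)))
  }
  n <- 300
  expect_equal(count_gray(1, 60, 5), 60)
  rate <- count_gray(0.2, n, 6) / n
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("flip probabilities are calibrated", {
  img <- array(runif(10 * 10 * 3), c(10, 10, 3))
  cfg <- augment_config(crop_scale_lo = 1, crop_scale_hi = 1,
                        aspect_lo = 1, aspect_hi = 1, out_size = 10,
                        jitter_p = 0, gray_p = 0, blur_p = 0,
                        hflip_p = 0.5, vflip_p = 0)
  rng <- rng_stream(9)
  n <- 400
  flipped <- sum(vapply(seq_len(n), function(i)
    identical(augment_view(img, cfg, rng), flip_horizontal(img)),
    logical(1)))
  expect_lt(abs(flipped / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("triplets are reproducible, valid and generally distinct views", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  cfg <- augment_config(out_size = 16)
  t1 <- make_triplet(img, cfg, rng_stream(13))
  t2 <- make_triplet(img, cfg, rng_stream(13))
  expect_identical(t1, t2)
  for (v in t1) {
    expect_equal(dim(v), c(16, 16, 3))
    expect_gte(min(v), 0)
    expect_lte(max(v), 1)
  }
  # under the default stochastic config the three views differ pairwise
  rng <- rng_stream(21)
  distinct <- vapply(1:30, function(i) {
    tr <- make_triplet(img, cfg, rng)
    !identical(tr$x1, tr$x2) && !identical(tr$x1, tr$x3) &&
      !identical(tr$x2, tr$x3)
  }, logical(1))
  expect_gte(mean(distinct), 0.95)

  cfg_id <- augment_config(crop_scale_lo = 1, crop_scale_hi = 1,
                           aspect_lo = 1, aspect_hi = 1, out_size = 16,
                           jitter_p = 0, gray_p = 0, blur_p = 0,
                           hflip_p = 0, vflip_p = 0)
  tr <- make_triplet(img, cfg_id, rng_stream(1))
  resized <- resize_bilinear(img, 16, 16)
  expect_equal(tr$x1, resized)
  expect_equal(tr$x2, resized)
  expect_equal(tr$x3, resized)
})
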