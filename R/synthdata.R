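#' Synthetic dataset specification
#'
#' Describes a deterministic multi-class RGB image generator that emulates
#' a class-per-subdirectory medical-image dataset at desk scale. Class
#' identity is encoded redundantly in three factors — base hue, sinusoidal
#' texture frequency and elliptical blob count — so that features
#' surviving crops, flips and moderate colour jitter exist, which is what
#' makes contrastive pretraining on these images meaningful. Default base
#' hues are evenly spaced (at least 0.2 apart for up to 5 classes) so
#' colour jitter at the default strength cannot swap class identities.
#'
#' @param n_classes number of classes (>= 2), default 4.
#' @param n_per_class images per class.
#' @param image_size square image side in pixels.
#' @param base_hue per-class base hue in \[0, 1); default evenly spaced.
#' @param texture_freq per-class sinusoidal texture frequency in
#'   cycles/image; default `2 * (class index)`.
#' @param blob_count_range per-class integer pair (list of length
#'   `n_classes`); default class `c` gets `c(2c - 1, 2c + 1)`.
#' @param noise_sigma Gaussian pixel noise std, default 0.05.
#' @param seed master seed; the full dataset is a pure function of the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 4L, n_per_class = 50L,
                           image_size = 64L,
                           base_hue = NULL, texture_freq = NULL,
                           blob_count_range = NULL,
                           noise_sigma = 0.05, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least 2 classes")
  if (n_per_class < 1L) stop("need at least 1 image per class")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(base_hue)) base_hue <- (seq_len(n_classes) - 1L) / n_classes
  if (is.null(texture_freq)) texture_freq <- 2 * seq_len(n_classes)
  if (is.null(blob_count_range))
    blob_count_range <- lapply(seq_len(n_classes),
                               function(c) c(2L * c - 1L, 2L * c + 1L))
  if (length(base_hue) != n_classes || length(texture_freq) != n_classes ||
      length(blob_count_range) != n_classes)
    stop("per-class parameters must have length n_classes")
  if (any(base_hue < 0 | base_hue >= 1)) stop("base hues must lie in [0, 1)")
  sig <- paste(base_hue, texture_freq,
               vapply(blob_count_range, paste, character(1), collapse = ","))
  if (anyDuplicated(sig))
    stop("per-class (hue, texture, blob) signatures must be pairwise distinct")
  structure(list(n_classes = n_classes, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), base_hue = base_hue,
                 texture_freq = texture_freq,
                 blob_count_range = blob_count_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Render one synthetic image
#'
#' A class-`k` image is a background of the class base hue modulated by a
#' sinusoidal texture at the class frequency (random orientation and
#' phase), scattered with a class-dependent number of brighter elliptical
#' blobs, plus Gaussian pixel noise, clipped to \[0, 1\].
#'
#' @param class_index class, 1-based (1 .. `n_classes`).
#' @param spec a [synthetic_spec()].
#' @param rng an [rng_stream()].
#' @return an `image_size` x `image_size` x 3 image.
#' @export
render_image <- function(class_index, spec, rng) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- as.integer(class_index)
  if (k < 1L || k > spec$n_classes)
    stop("class_index out of range: ", class_index)
  n <- spec$image_size
  xs <- matrix((seq_len(n) - 0.5) / n, n, n, byrow = TRUE)
  ys <- matrix((seq_len(n) - 0.5) / n, n, n)
  theta <- rs_runif(rng, 1L, 0, pi)
  phase <- rs_runif(rng, 1L, 0, 2 * pi)
  f <- spec$texture_freq[k]
  value <- 0.55 + 0.15 * sin(2 * pi * f * (cos(theta) * xs + sin(theta) * ys)
                             + phase)
  sat <- matrix(0.55, n, n)
  hue <- matrix((spec$base_hue[k] + rs_runif(rng, 1L, -0.02, 0.02)) %% 1, n, n)
  rg <- spec$blob_count_range[[k]]
  n_blobs <- if (rg[2] > rg[1])
    rg[1] + rs_sample_int(rng, rg[2] - rg[1] + 1L) - 1L else rg[1]
  if (n_blobs > 0) for (b in seq_len(n_blobs)) {
    cx <- rs_runif(rng, 1L); cy <- rs_runif(rng, 1L)
    ax <- rs_runif(rng, 1L, 0.04, 0.12); ay <- rs_runif(rng, 1L, 0.04, 0.12)
    rot <- rs_runif(rng, 1L, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- cos(rot) * dx + sin(rot) * dy
    w <- -sin(rot) * dx + cos(rot) * dy
    inside <- (u / ax)^2 + (w / ay)^2 <= 1
    value[inside] <- pmin(1, value[inside] + 0.3)
    sat[inside] <- pmax(0, sat[inside] - 0.25)
  }
  img <- hsv_to_rgb_img(array(c(hue, sat, clip01(value)), c(n, n, 3L)))
  if (spec$noise_sigma > 0)
    img <- img + rs_rnorm(rng, length(img), sd = spec$noise_sigma)
  clip01(img)
}

#' Generate a labelled synthetic dataset
#'
#' Produces exactly `n_per_class` images per class, fully deterministic
#' given the spec's seed (each image has its own substream keyed by class
#' and index, so the dataset does not depend on generation order).
#'
#' @param spec a [synthetic_spec()].
#' @return a `labelled_image_set`: list with `images` (list of arrays),
#'   `labels` (1-based integer classes) and `class_names`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  images <- vector("list", spec$n_classes * spec$n_per_class)
  labels <- integer(length(images))
  i <- 0L
  for (k in seq_len(spec$n_classes)) {
    for (j in seq_len(spec$n_per_class)) {
      i <- i + 1L
      images[[i]] <- render_image(k, spec, rng_substream(spec$seed, k, j))
      labels[i] <- k
    }
  }
  labelled_image_set(images, labels,
                     sprintf("class_%02d", seq_len(spec$n_classes)))
}

#' Construct a labelled image set
#'
#' @param images list of H x W x 3 images (see [as_image()]).
#' @param labels integer class labels, 1-based.
#' @param class_names character vector of class names.
#' @return an object of class `labelled_image_set`.
#' @export
labelled_image_set <- function(images, labels, class_names) {
  labels <- as.integer(labels)
  if (length(images) != length(labels))
    stop("images and labels must have equal length")
  if (length(labels) && (min(labels) < 1L || max(labels) > length(class_names)))
    stop("labels must index into class_names")
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names)),
            class = "labelled_image_set")
}

#' @export
print.labelled_image_set <- function(x, ...) {
  cat("<labelled_image_set> ", length(x$images), " images, ",
      length(x$class_names), " classes\n", sep = "")
  print(table(factor(x$class_names[x$labels], levels = x$class_names)))
  invisible(x)
}

subset_image_set <- function(ds, idx) {
  labelled_image_set(ds$images[idx], ds$labels[idx], ds$class_names)
}

#' Write / read a class-per-subdirectory PNG image folder
#'
#' The standard layout: one subdirectory per class (named by class), PNG
#' files inside. PNG is lossless at 8 bits, so a write/read round-trip
#' preserves labels exactly and pixels to within 1/255 per channel.
#' Non-PNG files found when reading are skipped with a warning.
#'
#' @param ds a `labelled_image_set`.
#' @param path folder to write to / read from.
#' @return `read_image_folder()` returns a `labelled_image_set`;
#'   `write_image_folder()` returns `path` invisibly.
#' @export
write_image_folder <- function(ds, path) {
  stopifnot(inherits(ds, "labelled_image_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  counter <- integer(length(ds$class_names))
  for (i in seq_along(ds$images)) {
    k <- ds$labels[i]
    cls_dir <- file.path(path, ds$class_names[k])
    if (!dir.exists(cls_dir)) dir.create(cls_dir)
    counter[k] <- counter[k] + 1L
    png::writePNG(ds$images[[i]],
                  file.path(cls_dir, sprintf("img_%05d.png", counter[k])))
  }
  invisible(path)
}

#' @rdname write_image_folder
#' @export
read_image_folder <- function(path) {
  if (!dir.exists(path)) stop("no such folder: ", path)
  class_dirs <- sort(list.dirs(path, recursive = FALSE))
  if (!length(class_dirs)) stop("no class subdirectories under ", path)
  class_names <- basename(class_dirs)
  images <- list(); labels <- integer(0)
  for (k in seq_along(class_dirs)) {
    files <- sort(list.files(class_dirs[k], full.names = TRUE))
    kept <- 0L
    for (f in files) {
      if (!grepl("\\.png$", f, ignore.case = TRUE)) {
        warning("skipping non-PNG file: ", f)
        next
      }
      img <- tryCatch(as_image(png::readPNG(f)), error = function(e) {
        warning("skipping unreadable image: ", f)
        NULL
      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k)
      kept <- kept + 1L
    }
    if (kept == 0L)
      stop("class directory '", class_names[k], "' contains no readable images")
  }
  labelled_image_set(images, labels, class_names)
}
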