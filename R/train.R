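#' Pretraining configuration
#'
#' Hyperparameters of the self-supervised pretraining stage. Defaults are
#' the reference recipe: 256 x 256 inputs, 200 epochs, batch size 256,
#' SGD at base learning rate 0.05 with cosine decay, weight decay 5e-4 and
#' momentum 0.9. The three ablation switches correspond to the components
#' studied in the ablation protocol: the augmentation module, the
#' projection MLP and the prediction MLP.
#'
#' @param image_size square input resolution fed to the encoder; also sets
#'   the augmentation output size.
#' @param epochs number of passes over the dataset (>= 1).
#' @param batch_size images per SGD step (>= 2; batch normalization needs
#'   more than one sample in training mode).
#' @param base_lr base learning rate (> 0).
#' @param weight_decay l2 weight decay, applied to all parameters.
#' @param momentum SGD momentum.
#' @param seed master seed for shuffling, augmentation and weight init.
#' @param lr_linear_scaling scale the learning rate by `batch_size / 256`?
#'   Off by default (the base rate is used literally at any batch size).
#' @param augment an [augment_config()]; its `out_size` is forced to
#'   `image_size`.
#' @param model a [model_config()].
#' @param use_augmentation,use_projection,use_prediction ablation switches
#'   (all on by default).
#' @return an object of class `train_config`.
#' @export
train_config <- function(image_size = 256L, epochs = 200L, batch_size = 256L,
                         base_lr = 0.05, weight_decay = 5e-4,
                         momentum = 0.9, seed = 1L,
                         lr_linear_scaling = FALSE,
                         augment = NULL, model = model_config(),
                         use_augmentation = TRUE, use_projection = TRUE,
                         use_prediction = TRUE) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 2L) stop("batch_size must be >= 2 (batch-norm contract)")
  if (base_lr <= 0) stop("base_lr must be > 0")
  if (is.null(augment)) augment <- augment_config(out_size = image_size)
  augment$out_size <- as.integer(image_size)
  structure(list(image_size = as.integer(image_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr, weight_decay = weight_decay,
                 momentum = momentum, seed = as.integer(seed),
                 lr_linear_scaling = isTRUE(lr_linear_scaling),
                 augment = augment, model = model,
                 use_augmentation = isTRUE(use_augmentation),
                 use_projection = isTRUE(use_projection),
                 use_prediction = isTRUE(use_prediction)),
            class = "train_config")
}

#' Cosine-decayed learning rate
#'
#' `base_lr * (1 + cos(pi * step / total_steps)) / 2`: starts at `base_lr`,
#' halves at mid-schedule, reaches 0 at `total_steps`. Monotonically
#' non-increasing in `step`.
#'
#' @param step current step, `0 <= step <= total_steps`.
#' @param total_steps schedule length (>= 1).
#' @param base_lr initial learning rate.
#' @return the learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, base_lr = 0.05) {
  if (total_steps < 1) stop("total_steps must be >= 1")
  if (any(step < 0) || any(step > total_steps))
    stop("step must lie in [0, total_steps]")
  base_lr * 0.5 * (1 + cos(pi * step / total_steps))
}

#' Representation-collapse diagnostic
#'
#' l2-normalizes each row of a batch of projection vectors and returns the
#' per-dimension standard deviation across the batch, averaged over
#' dimensions. The metric is 0 iff all normalized vectors are identical
#' (total collapse) and approaches `1/sqrt(d)` for isotropically spread
#' vectors in `d` dimensions; it is invariant to positive rescaling of
#' individual vectors.
#'
#' @param projections an `n x d` matrix of projection vectors, `n >= 2`.
#' @return a non-negative scalar.
#' @export
collapse_metric <- function(projections) {
  v <- as_batch_matrix(projections)
  if (nrow(v) < 2L) stop("collapse metric needs a batch of at least 2 vectors")
  vn <- l2_normalize_rows(v)
  n <- nrow(vn)
  m <- colMeans(vn)
  s2 <- (colSums(vn * vn) - n * m^2) / (n - 1)
  mean(sqrt(pmax(s2, 0)))
}

# Recursively add two gradient trees (lists with $params / $sub leaves).
add_grad_trees <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in union(names(a), names(b)))
    out[[nm]] <- add_grad_trees(a[[nm]], b[[nm]])
  out
}

add_grad_lists <- function(a, b) {
  if (is.null(a)) return(b)
  Map(add_grad_trees, a, b)
}

new_opt_state <- function(model) {
  list(encoder = init_velocity(model$encoder),
       projection = if (!is.null(model$projection))
         init_velocity(model$projection),
       prediction = if (!is.null(model$prediction))
         init_velocity(model$prediction))
}

# Build the three view batches for a list of images under the ablation
# switches; each image gets its own augmentation substream.
make_view_batches <- function(images, cfg, rng) {
  n <- length(images)
  seeds <- rs_sample_int(rng, 2147483646L, n, replace = TRUE)
  views <- vector("list", 3L)
  if (cfg$use_augmentation) {
    trips <- lapply(seq_len(n), function(i)
      make_triplet(images[[i]], cfg$augment, rng_substream(seeds[i], 7L)))
    for (v in 1:3) views[[v]] <- stack_images(lapply(trips, `[[`, v))
  } else {
    resized <- lapply(images, function(im) {
      im <- as_image(im)
      if (!all(dim(im)[1:2] == cfg$image_size))
        resize_bilinear(im, cfg$image_size, cfg$image_size)
      else im
    })
    batch <- stack_images(resized)
    for (v in 1:3) views[[v]] <- batch
  }
  views
}

#' One pretraining SGD step
#'
#' Builds a view triplet per image (or three identical resized copies when
#' augmentation is ablated), forwards all three views through the shared
#' weights in training mode, evaluates the triple-view loss with
#' stop-gradient on the projection targets, backpropagates the prediction
#' side, and applies one SGD update with the supplied learning rate,
#' momentum and weight decay.
#'
#' @param model a [build_model()] result.
#' @param images list of images forming the batch (length >= 2).
#' @param cfg a [train_config()].
#' @param lr learning rate for this step.
#' @param opt_state optimizer momentum state (create with `NULL` on the
#'   first call).
#' @param rng an [rng_stream()] for this step's augmentation draws.
#' @return list with `model`, `opt_state`, `loss` (batch loss value) and
#'   `collapse` (collapse metric of the three projection batches).
#' @export
pretrain_step <- function(model, images, cfg, lr, opt_state = NULL, rng) {
  if (length(images) < 2L)
    stop("pretraining batch must contain at least 2 images (batch-norm contract)")
  if (is.null(opt_state)) opt_state <- new_opt_state(model)
  views <- make_view_batches(images, cfg, rng)
  # With augmentation ablated the three views coincide, so one forward pass
  # serves all branches, and because backpropagation is linear in the output
  # gradient (for fixed caches) the three branch gradients collapse into a
  # single backward pass over the summed z-gradient.
  identical_views <- !cfg$use_augmentation
  if (identical_views) {
    b1 <- forward_branch(model, views[[1]], training = TRUE, rng = rng)
    model <- b1$model
    br <- list(b1, b1, b1)
  } else {
    fw <- forward_triplet(model, views, training = TRUE, rng = rng)
    model <- fw$model
    br <- list(fw$b1, fw$b2, fw$b3)
  }
  zs <- lapply(br, `[[`, "z")
  vs <- lapply(br, `[[`, "v")
  loss <- triloss(zs[[1]], zs[[2]], zs[[3]], vs[[1]], vs[[2]], vs[[3]])
  g <- triloss_gradient(zs[[1]], zs[[2]], zs[[3]], vs[[1]], vs[[2]], vs[[3]],
                        stop_targets = TRUE)
  genc <- gproj <- gpred <- NULL
  branch_set <- if (identical_views) 1L else 1:3
  for (i in branch_set) {
    d <- if (identical_views) g$z[[1]] + g$z[[2]] + g$z[[3]] else g$z[[i]]
    if (!is.null(model$prediction)) {
      bh <- nn_backward(model$prediction, d, br[[i]]$caches$prediction)
      gpred <- add_grad_lists(gpred, bh$grads)
      d <- bh$dx
    }
    if (!is.null(model$projection)) {
      bp <- nn_backward(model$projection, d, br[[i]]$caches$projection)
      gproj <- add_grad_lists(gproj, bp$grads)
      d <- bp$dx
    }
    be <- nn_backward(model$encoder, d, br[[i]]$caches$encoder)
    genc <- add_grad_lists(genc, be$grads)
  }
  upd <- sgd_step_net(model$encoder, genc, opt_state$encoder, lr,
                      cfg$momentum, cfg$weight_decay)
  model$encoder <- upd$net; opt_state$encoder <- upd$vel
  if (!is.null(model$projection)) {
    upd <- sgd_step_net(model$projection, gproj, opt_state$projection, lr,
                        cfg$momentum, cfg$weight_decay)
    model$projection <- upd$net; opt_state$projection <- upd$vel
  }
  if (!is.null(model$prediction)) {
    upd <- sgd_step_net(model$prediction, gpred, opt_state$prediction, lr,
                        cfg$momentum, cfg$weight_decay)
    model$prediction <- upd$net; opt_state$prediction <- upd$vel
  }
  list(model = model, opt_state = opt_state, loss = as.numeric(loss),
       collapse = collapse_metric(rbind(vs[[1]], vs[[2]], vs[[3]])))
}

#' Self-supervised triple-view pretraining
#'
#' The main fitting function. Trains the shared-weight triple-branch
#' network (encoder, projection MLP, prediction MLP) on unlabelled images:
#' every SGD step draws three stochastic augmented views per image,
#' minimizes the six-term negative cosine similarity loss with
#' stop-gradient on the projection targets, and follows a per-step cosine
#' learning-rate schedule. Labels, if present in `x`, are ignored at this
#' stage. Returns a fitted object whose encoder is then reused for
#' downstream evaluation ([linear_probe()], [fine_tune()]).
#'
#' @param x training images: a `labelled_image_set`, a list of images, or
#'   the path to a class-per-subdirectory image folder.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress to stderr?
#' @return an object of class `triview`: list with the trained `model`,
#'   the `config`, a per-step `log` (data.frame: step, epoch, lr, loss,
#'   collapse), a per-epoch summary `epoch_log`, and the optimizer state.
#' @seealso [predict.triview()], [plot.triview()], [save_checkpoint()]
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_per_class = 8, image_size = 32))
#' cfg <- train_config(image_size = 32, epochs = 1, batch_size = 8,
#'                     model = model_config("tinycnn", feature_dim = 8,
#'                                          proj_dim = 16,
#'                                          pred_hidden_dim = 8))
#' fit <- triview(ds, cfg)
#' dim(predict(fit, ds$images[1:2], type = "features"))
triview <- function(x, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  images <- extract_images(x)
  n <- length(images)
  if (n == 0L) stop("empty dataset: nothing to pretrain on")
  model <- build_model(config$model,
                       use_projection = config$use_projection,
                       use_prediction = config$use_prediction)
  opt_state <- new_opt_state(model)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  lr_scale <- if (config$lr_linear_scaling) config$batch_size / 256 else 1
  log_rows <- vector("list", total_steps)
  warned_partial <- FALSE
  gstep <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (epoch in seq_len(config$epochs)) {
    ord <- rs_eval(rng_substream(config$seed, 11L, epoch), sample.int(n))
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1L) * config$batch_size + 1L):min(s * config$batch_size, n)]
      if (length(idx) < 2L) {
        if (!warned_partial) {
          warning("dropping a partial batch of size 1 (batch-norm contract)")
          warned_partial <- TRUE
        }
        gstep <- gstep + 1L
        next
      }
      lr <- lr_scale * cosine_lr(gstep, total_steps, config$base_lr)
      step_rng <- rng_substream(config$seed, 13L, epoch, s)
      res <- pretrain_step(model, images[idx], config, lr, opt_state, step_rng)
      model <- res$model
      opt_state <- res$opt_state
      gstep <- gstep + 1L
      log_rows[[gstep]] <- data.frame(step = gstep, epoch = epoch, lr = lr,
                                      loss = res$loss,
                                      collapse = res$collapse)
    }
    if (verbose) {
      ep <- do.call(rbind, log_rows[(gstep - steps_per_epoch + 1L):gstep])
      message(sprintf("epoch %d/%d  loss %.4f  collapse %.4f",
                      epoch, config$epochs, mean(ep$loss), mean(ep$collapse)))
    }
  }
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  epoch_log <- do.call(rbind, lapply(split(log, log$epoch), function(d)
    data.frame(epoch = d$epoch[1], mean_loss = mean(d$loss),
               mean_collapse = mean(d$collapse))))
  rownames(epoch_log) <- NULL
  structure(list(model = model, config = config, log = log,
                 epoch_log = epoch_log, opt_state = opt_state,
                 n_images = n,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "triview")
}

extract_images <- function(x) {
  if (inherits(x, "labelled_image_set")) return(x$images)
  if (is.character(x) && length(x) == 1L)
    return(read_image_folder(x)$images)
  if (is.list(x)) return(lapply(x, as_image))
  if (is.array(x) && length(dim(x)) == 3L) return(list(as_image(x)))
  stop("cannot interpret 'x' as images (expected a labelled_image_set, ",
       "a list of images, or a folder path)")
}

#' @export
print.triview <- function(x, ...) {
  cfg <- x$config
  cat("Triple-view self-supervised pretraining fit\n")
  cat(sprintf("  backbone: %s (feature %d, proj %s, pred hidden %s)\n",
              cfg$model$backbone, cfg$model$feature_dim,
              if (x$config$use_projection) cfg$model$proj_dim else "off",
              if (x$config$use_prediction) cfg$model$pred_hidden_dim else "off"))
  cat(sprintf("  %d images, %d epochs, batch %d, base lr %.3g\n",
              x$n_images, cfg$epochs, cfg$batch_size, cfg$base_lr))
  ne <- nrow(x$epoch_log)
  cat(sprintf("  loss: %.4f (first epoch) -> %.4f (final epoch)\n",
              x$epoch_log$mean_loss[1], x$epoch_log$mean_loss[ne]))
  cat(sprintf("  collapse metric (final epoch): %.4f\n",
              x$epoch_log$mean_collapse[ne]))
  invisible(x)
}

#' @export
summary.triview <- function(object, ...) {
  ne <- nrow(object$epoch_log)
  out <- list(
    backbone = object$config$model$backbone,
    n_parameters = model_n_params(object$model),
    n_images = object$n_images,
    epochs = object$config$epochs,
    first_epoch_loss = object$epoch_log$mean_loss[1],
    final_epoch_loss = object$epoch_log$mean_loss[ne],
    final_collapse = object$epoch_log$mean_collapse[ne],
    collapse_floor = min(object$log$collapse),
    elapsed_sec = object$elapsed
  )
  class(out) <- "summary.triview"
  out
}

#' @export
print.summary.triview <- function(x, ...) {
  cat("Triple-view pretraining summary\n")
  cat(sprintf("  backbone %s, %s parameters\n", x$backbone,
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  %d images x %d epochs (%.1f s)\n", x$n_images, x$epochs,
              x$elapsed_sec))
  cat(sprintf("  mean loss: first epoch %.4f, final epoch %.4f\n",
              x$first_epoch_loss, x$final_epoch_loss))
  cat(sprintf("  collapse metric: final %.4f, minimum over run %.4f\n",
              x$final_collapse, x$collapse_floor))
  invisible(x)
}

#' Plot pretraining diagnostics
#'
#' Two panels: the per-step loss (with the per-epoch mean overlaid) and
#' the collapse metric over steps. A collapse metric falling to zero
#' signals total representational collapse.
#'
#' @param x a fitted [triview()] object.
#' @param ... unused.
#' @export
plot.triview <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$log$step, x$log$loss, type = "l", col = "grey60",
                 xlab = "step", ylab = "loss", main = "triple-view loss")
  spe <- nrow(x$log) / nrow(x$epoch_log)
  graphics::lines(x$epoch_log$epoch * spe, x$epoch_log$mean_loss,
                  col = "firebrick", lwd = 2)
  graphics::plot(x$log$step, x$log$collapse, type = "l", col = "steelblue",
                 xlab = "step", ylab = "collapse metric",
                 main = "collapse diagnostic")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Extract representations from a fitted model
#'
#' Forwards images through the trained network in evaluation mode
#' (batch-norm running statistics, no augmentation beyond a resize to the
#' training resolution) and returns the requested stage: encoder
#' `"features"`, `"projection"` outputs, or `"prediction"` outputs.
#'
#' @param object a fitted [triview()] object.
#' @param newdata images: `labelled_image_set`, list of images, one image,
#'   or a folder path.
#' @param type which representation to return.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return an `n x d` numeric matrix.
#' @export
predict.triview <- function(object, newdata,
                            type = c("features", "projection", "prediction"),
                            batch_size = 64L, ...) {
  type <- match.arg(type)
  model <- object$model
  if (type == "projection" && is.null(model$projection))
    stop("this fit was trained without a projection MLP")
  if (type == "prediction" && is.null(model$prediction))
    stop("this fit was trained without a prediction MLP")
  images <- extract_images(newdata)
  size <- object$config$image_size
  images <- lapply(images, function(im) {
    im <- as_image(im)
    if (!all(dim(im)[1:2] == size)) resize_bilinear(im, size, size) else im
  })
  out <- NULL
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    x <- stack_images(images[idx])
    b <- forward_branch(model, x, training = FALSE)
    piece <- switch(type, features = b$e, projection = b$v, prediction = b$z)
    out <- rbind(out, piece)
  }
  out
}
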