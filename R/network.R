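#' Model configuration
#'
#' Architecture of the shared-weight triple-branch network: an encoder
#' backbone producing a `feature_dim`-vector, a three-layer projection MLP
#' of width `proj_dim` (8192 by default), and a two-layer bottleneck
#' prediction MLP with hidden width `pred_hidden_dim` (2048 by default).
#' The default backbone is ResNet-50 (feature length 2048, global average
#' pooled); `"tinycnn"` is a small three-stage convolutional backbone for
#' CPU-scale experiments and tests.
#'
#' @param backbone `"resnet50"` or `"tinycnn"`.
#' @param feature_dim encoder output width; fixed at 2048 for ResNet-50,
#'   configurable (default 64) for tinycnn.
#' @param proj_dim projection MLP width (all three layers), also the
#'   prediction MLP output width.
#' @param pred_hidden_dim prediction MLP bottleneck width.
#' @param pretrained_backbone load externally supplied backbone weights?
#'   Default `FALSE` (random initialisation); when `TRUE`, a weights file
#'   must be passed to [build_encoder()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `model_config`.
#' @export
model_config <- function(backbone = c("resnet50", "tinycnn"),
                         feature_dim = NULL,
                         proj_dim = 8192L,
                         pred_hidden_dim = 2048L,
                         pretrained_backbone = FALSE,
                         seed = 1L) {
  backbone <- match.arg(backbone)
  feature_dim <- if (backbone == "resnet50") {
    if (!is.null(feature_dim) && feature_dim != 2048L)
      stop("resnet50 has a fixed feature_dim of 2048")
    2048L
  } else {
    as.integer(if (is.null(feature_dim)) 64L else feature_dim)
  }
  cfg <- list(backbone = backbone, feature_dim = feature_dim,
              proj_dim = as.integer(proj_dim),
              pred_hidden_dim = as.integer(pred_hidden_dim),
              pretrained_backbone = isTRUE(pretrained_backbone),
              seed = as.integer(seed))
  if (any(c(cfg$feature_dim, cfg$proj_dim, cfg$pred_hidden_dim) < 1L))
    stop("all dimensions must be >= 1")
  structure(cfg, class = "model_config")
}

build_tinycnn <- function(feature_dim, rng) {
  widths <- c(16L, 32L, feature_dim)
  layers <- list()
  c_in <- 3L
  for (w in widths) {
    layers <- c(layers, list(
      layer_conv2d(c_in, w, 3L, stride = 2L, pad = 1L, rng),
      layer_bn2d(w),
      layer_relu()
    ))
    c_in <- w
  }
  nn_sequential(c(layers, list(layer_gap())))
}

build_resnet50_net <- function(rng) {
  layers <- list(
    layer_conv2d(3L, 64L, 7L, stride = 2L, pad = 3L, rng),
    layer_bn2d(64L),
    layer_relu(),
    layer_maxpool(3L, 2L, 1L)
  )
  stage_blocks <- c(3L, 4L, 6L, 3L)
  stage_mid <- c(64L, 128L, 256L, 512L)
  c_in <- 64L
  for (s in 1:4) {
    stride <- if (s == 1L) 1L else 2L
    for (b in seq_len(stage_blocks[s])) {
      layers <- c(layers, list(
        layer_bottleneck(c_in, stage_mid[s], if (b == 1L) stride else 1L, rng)
      ))
      c_in <- 4L * stage_mid[s]
    }
  }
  nn_sequential(c(layers, list(layer_gap())))
}

#' Build an encoder
#'
#' Returns the encoder network for the configured backbone: ResNet-50 with
#' the classification head removed and global average pooling (feature
#' length 2048), or the tinycnn test backbone (three conv-BN-ReLU stages
#' with stride-2 downsampling and global average pooling).
#'
#' @param cfg a [model_config()].
#' @param weights optional path to an RDS file holding encoder weights (a
#'   previously saved encoder network); required when
#'   `cfg$pretrained_backbone` is `TRUE`.
#' @return an encoder network (class `nn_sequential`).
#' @export
build_encoder <- function(cfg, weights = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  rng <- rng_substream(cfg$seed, 101L)
  net <- switch(cfg$backbone,
    resnet50 = build_resnet50_net(rng),
    tinycnn = build_tinycnn(cfg$feature_dim, rng),
    stop("unknown backbone '", cfg$backbone,
         "'; valid options: resnet50, tinycnn")
  )
  if (cfg$pretrained_backbone) {
    if (is.null(weights))
      stop("pretrained_backbone = TRUE requires a 'weights' file ",
           "(an RDS of a saved encoder network)")
    net <- readRDS(weights)
  }
  net
}

#' Build the projection MLP
#'
#' Three dense layers of width `proj_dim`; the first two are followed by
#' batch normalization and ReLU, the last by batch normalization only.
#'
#' @param cfg a [model_config()].
#' @return an `nn_sequential` network mapping `feature_dim` to `proj_dim`.
#' @export
build_projection_mlp <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  rng <- rng_substream(cfg$seed, 102L)
  nn_sequential(list(
    layer_dense(cfg$feature_dim, cfg$proj_dim, rng),
    layer_bn1d(cfg$proj_dim),
    layer_relu(),
    layer_dense(cfg$proj_dim, cfg$proj_dim, rng),
    layer_bn1d(cfg$proj_dim),
    layer_relu(),
    layer_dense(cfg$proj_dim, cfg$proj_dim, rng),
    layer_bn1d(cfg$proj_dim)
  ))
}

#' Build the prediction MLP
#'
#' A bottleneck: dense to `pred_hidden_dim` with batch normalization and
#' ReLU, then dense back to the input width with no normalization or
#' activation.
#'
#' @param cfg a [model_config()].
#' @param d_in input (and output) width; defaults to `cfg$proj_dim`. The
#'   pretraining loop passes `feature_dim` here when the projection MLP is
#'   ablated away.
#' @return an `nn_sequential` network.
#' @export
build_prediction_mlp <- function(cfg, d_in = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (is.null(d_in)) d_in <- cfg$proj_dim
  rng <- rng_substream(cfg$seed, 103L)
  nn_sequential(list(
    layer_dense(d_in, cfg$pred_hidden_dim, rng),
    layer_bn1d(cfg$pred_hidden_dim),
    layer_relu(),
    layer_dense(cfg$pred_hidden_dim, d_in, rng)
  ))
}

#' Build the full triple-branch model
#'
#' Assembles encoder, projection MLP and prediction MLP under one parameter
#' set; the three branches of the network share these weights, so the model
#' holds exactly one copy. `use_projection`/`use_prediction` ablate the
#' respective head (the prediction MLP is then sized to operate directly on
#' encoder features).
#'
#' @param cfg a [model_config()].
#' @param use_projection,use_prediction include the respective MLP?
#' @return a list of class `triview_model` with elements `encoder`,
#'   `projection` (or `NULL`), `prediction` (or `NULL`) and `cfg`.
#' @export
build_model <- function(cfg, use_projection = TRUE, use_prediction = TRUE) {
  enc <- build_encoder(cfg)
  proj <- if (use_projection) build_projection_mlp(cfg) else NULL
  embed_dim <- if (use_projection) cfg$proj_dim else cfg$feature_dim
  pred <- if (use_prediction) build_prediction_mlp(cfg, d_in = embed_dim)
          else NULL
  structure(list(encoder = enc, projection = proj, prediction = pred,
                 cfg = cfg), class = "triview_model")
}

model_n_params <- function(model) {
  n <- n_params(model$encoder)
  if (!is.null(model$projection)) n <- n + n_params(model$projection)
  if (!is.null(model$prediction)) n <- n + n_params(model$prediction)
  n
}

# Forward one view batch through encoder -> projection -> prediction.
# Returns e, v, z plus per-net caches (training mode) and updated model.
forward_branch <- function(model, x, training = FALSE, rng = NULL) {
  fe <- nn_forward(model$encoder, x, training, rng)
  model$encoder <- fe$net
  e <- fe$y
  if (!is.null(model$projection)) {
    fp <- nn_forward(model$projection, e, training, rng)
    model$projection <- fp$net
    v <- fp$y
  } else {
    fp <- NULL
    v <- e
  }
  if (!is.null(model$prediction)) {
    fh <- nn_forward(model$prediction, v, training, rng)
    model$prediction <- fh$net
    z <- fh$y
  } else {
    fh <- NULL
    z <- v
  }
  list(e = e, v = v, z = z,
       caches = list(encoder = fe$caches,
                     projection = if (!is.null(fp)) fp$caches,
                     prediction = if (!is.null(fh)) fh$caches),
       model = model)
}

#' Forward a view triplet through the shared-weight branches
#'
#' Runs the three view batches through the single parameter set (encoder,
#' projection MLP, prediction MLP) and returns per-branch outputs: encoder
#' features `e`, projections `v` and predictions `z`.
#'
#' @param model a [build_model()] result.
#' @param views list of three image batches (`H x W x 3 x N` arrays), or a
#'   `view_triplet` of single images.
#' @param training forward in training mode (batch-norm batch statistics)?
#' @param rng an [rng_stream()]; only needed when training layers draw
#'   randomness (dropout).
#' @return a list with elements `b1`, `b2`, `b3` (each with `e`, `v`, `z`
#'   matrices, rows = samples) and `model` (updated running statistics).
#' @export
forward_triplet <- function(model, views, training = FALSE, rng = NULL) {
  stopifnot(inherits(model, "triview_model"))
  if (inherits(views, "view_triplet"))
    views <- lapply(views, function(v) stack_images(list(v)))
  if (length(views) != 3L) stop("'views' must hold exactly three batches")
  out <- vector("list", 3L)
  for (i in 1:3) {
    b <- forward_branch(model, views[[i]], training, rng)
    model <- b$model
    out[[i]] <- b
  }
  list(b1 = out[[1]], b2 = out[[2]], b3 = out[[3]], model = model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned container (RDS) holding the model
#' configuration, all weights and batch-norm running statistics, the epoch
#' counter, the optimizer velocity state and the training log, so training
#' can be resumed and evaluation-mode forward passes reproduce exactly.
#'
#' @param object a fitted [triview()] object or a `triview_model`.
#' @param path file path to write to / read from.
#' @return `load_checkpoint()` returns the saved object; `save_checkpoint()`
#'   returns `path` invisibly.
#' @export
save_checkpoint <- function(object, path) {
  ck <- list(format = "triview-checkpoint", version = 1L, object = object)
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "triview-checkpoint"))
    stop("not a triview checkpoint: ", path)
  if (ck$version > 1L)
    stop("checkpoint version ", ck$version, " is newer than this package")
  ck$object
}
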