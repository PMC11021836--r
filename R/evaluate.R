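#' Dataset split specification
#'
#' Controls the evaluation protocol's splits: an 80:20 train/test split by
#' default, with the training portion further divided into a labelled
#' subset (fraction `labelled_ratio`, e.g. 0.01, 0.1, 0.25, 0.5, 1.0) and
#' an unlabelled remainder. Splits are stratified by class by default and
#' fully determined by the seed.
#'
#' @param test_fraction fraction of the data held out for testing.
#' @param labelled_ratio fraction of the training split whose labels are
#'   available to the proxy task.
#' @param seed split seed.
#' @param stratified stratify both splits by class?
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, labelled_ratio = 1.0,
                       seed = 1L, stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (labelled_ratio <= 0 || labelled_ratio > 1)
    stop("labelled_ratio must lie in (0, 1]")
  structure(list(test_fraction = test_fraction,
                 labelled_ratio = labelled_ratio,
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Allocate `total` picks across classes proportionally to class sizes,
# by largest remainder; returns per-class counts.
largest_remainder <- function(class_sizes, total) {
  quota <- class_sizes * total / sum(class_sizes)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  pmin(base, class_sizes)
}

#' Split a dataset for evaluation
#'
#' Deterministically (given the spec's seed) partitions a dataset into
#' three disjoint parts whose union is the input: a stratified test set of
#' `floor(test_fraction * n)` items, a labelled training subset of
#' `round(labelled_ratio * n_train)` items, and the unlabelled remainder
#' of the training split.
#'
#' @param ds a `labelled_image_set`.
#' @param spec a [split_spec()].
#' @return a list with `labelled`, `unlabelled` and `test`
#'   (`labelled_image_set`s); each carries its source indices in attribute
#'   `"idx"`.
#' @export
split_dataset <- function(ds, spec) {
  stopifnot(inherits(ds, "labelled_image_set"), inherits(spec, "split_spec"))
  n <- length(ds$images)
  classes <- seq_along(ds$class_names)
  sizes <- vapply(classes, function(k) sum(ds$labels == k), numeric(1))
  if (any(sizes < 1))
    stop("class '", ds$class_names[which(sizes < 1)[1]], "' has no items")
  n_test <- floor(spec$test_fraction * n)
  test_quota <- if (spec$stratified) largest_remainder(sizes, n_test)
                else NULL
  rng <- rng_substream(spec$seed, 31L)
  test_idx <- integer(0)
  if (spec$stratified) {
    for (k in classes) {
      pool <- which(ds$labels == k)
      pick <- pool[rs_sample_int(rng, length(pool), test_quota[k])]
      test_idx <- c(test_idx, pick)
    }
  } else {
    test_idx <- rs_sample_int(rng, n, n_test)
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  n_lab <- round(spec$labelled_ratio * length(train_idx))
  if (n_lab < 1) stop("labelled_ratio leaves no labelled training items")
  lab_idx <- integer(0)
  if (spec$stratified) {
    tr_sizes <- vapply(classes, function(k)
      sum(ds$labels[train_idx] == k), numeric(1))
    lab_quota <- largest_remainder(tr_sizes, n_lab)
    short <- which(lab_quota < 1)
    if (length(short))
      stop("class '", ds$class_names[short[1]],
           "' has too few training items for a stratified labelled split ",
           "at labelled_ratio ", spec$labelled_ratio)
    for (k in classes) {
      pool <- train_idx[ds$labels[train_idx] == k]
      pick <- pool[rs_sample_int(rng, length(pool), lab_quota[k])]
      lab_idx <- c(lab_idx, pick)
    }
  } else {
    lab_idx <- train_idx[rs_sample_int(rng, length(train_idx), n_lab)]
  }
  unlab_idx <- setdiff(train_idx, lab_idx)
  wrap <- function(idx) {
    out <- subset_image_set(ds, idx)
    attr(out, "idx") <- idx
    out
  }
  list(labelled = wrap(lab_idx), unlabelled = wrap(unlab_idx),
       test = wrap(sort(test_idx)))
}

#' Classifier head configuration
#'
#' The downstream classifier is the pre-trained encoder followed by a
#' dropout layer (probability 0.2) and a dense layer with softmax over the
#' classes; the projection and prediction MLPs are discarded. With
#' `freeze_encoder` the encoder weights are held fixed (linear
#' evaluation); otherwise the whole network trains end to end
#' (fine-tuning).
#'
#' @param n_classes number of output classes.
#' @param dropout_p dropout probability before the dense layer.
#' @param freeze_encoder freeze the encoder weights?
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes, dropout_p = 0.2,
                              freeze_encoder = TRUE) {
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must lie in [0, 1)")
  structure(list(n_classes = as.integer(n_classes), dropout_p = dropout_p,
                 freeze_encoder = isTRUE(freeze_encoder)),
            class = "classifier_config")
}

#' Build a downstream classifier from a pretrained fit
#'
#' @param object a fitted [triview()] object, a `triview_model`, or a
#'   checkpoint path.
#' @param cfg a [classifier_config()].
#' @param seed head initialisation seed.
#' @return a list of class `triview_classifier` with the encoder, the
#'   dropout+dense head, and the configuration.
#' @export
build_classifier <- function(object, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "classifier_config"))
  if (is.character(object)) object <- load_checkpoint(object)
  model <- if (inherits(object, "triview")) object$model else object
  stopifnot(inherits(model, "triview_model"))
  rng <- rng_substream(seed, 104L)
  head <- nn_sequential(list(
    layer_dropout(cfg$dropout_p),
    layer_dense(model$cfg$feature_dim, cfg$n_classes, rng)
  ))
  structure(list(encoder = model$encoder, head = head, cfg = cfg,
                 feature_dim = model$cfg$feature_dim),
            class = "triview_classifier")
}

# Softmax over rows.
softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Class probabilities from a classifier
#'
#' @param object a `triview_classifier`.
#' @param images list of images (already at the encoder's input size) or a
#'   feature matrix when `from_features = TRUE`.
#' @param from_features treat `images` as precomputed encoder features?
#' @param ... unused.
#' @return an `n x n_classes` matrix of softmax probabilities (rows sum
#'   to 1).
#' @export
predict.triview_classifier <- function(object, images,
                                       from_features = FALSE, ...) {
  feats <- if (from_features) images else {
    x <- stack_images(lapply(images, as_image))
    nn_forward(object$encoder, x, training = FALSE)$y
  }
  logits <- nn_forward(object$head, feats, training = FALSE)$y
  softmax_rows(logits)
}

# Cross-entropy loss and gradient for integer labels (1-based).
cross_entropy <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), labels)] + eps))
  g <- p
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  list(loss = loss, grad = g / n)
}

#' Confusion-matrix based classification metrics
#'
#' From a confusion matrix (rows = true class, columns = predicted class)
#' computes accuracy (trace over total) and per-class one-vs-rest
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)`. Aggregate
#' precision/recall/F1 are macro-averages (unweighted means of the
#' per-class values) by default; micro-averaging is available. Classes
#' with a zero denominator contribute 0 with a warning.
#'
#' @param confusion a square matrix of non-negative integer counts.
#' @param average `"macro"` (default) or `"micro"`.
#' @return a list of class `eval_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, `per_class` (data.frame), `confusion`, `n_test`.
#' @export
compute_metrics <- function(confusion, average = c("macro", "micro")) {
  average <- match.arg(average)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion matrix counts must be non-negative")
  total <- sum(confusion)
  if (total <= 0) stop("confusion matrix must contain at least one count")
  k <- nrow(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    zero <- den == 0
    if (any(zero))
      warning("zero denominator for ", what, " in class(es) ",
              paste(which(zero), collapse = ", "), "; reporting 0")
    out[!zero] <- num[!zero] / den[!zero]
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  acc <- sum(tp) / total
  agg <- if (average == "macro") {
    c(precision = mean(precision), recall = mean(recall), f1 = mean(f1))
  } else {
    mp <- sum(tp) / sum(tp + fp)
    mr <- sum(tp) / sum(tp + fn)
    c(precision = mp, recall = mr,
      f1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0)
  }
  cls <- if (!is.null(rownames(confusion))) rownames(confusion)
         else paste0("class_", seq_len(k))
  structure(list(accuracy = acc,
                 precision = unname(agg["precision"]),
                 recall = unname(agg["recall"]),
                 f1 = unname(agg["f1"]),
                 per_class = data.frame(class = cls, tp = tp, fp = fp,
                                        fn = fn,
                                        tn = total - tp - fp - fn,
                                        precision = precision,
                                        recall = recall, f1 = f1,
                                        row.names = NULL),
                 confusion = confusion, n_test = total, average = average),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation report (n = %d, %s-averaged)\n", x$n_test, x$average))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

confusion_from_predictions <- function(truth, pred, class_names) {
  k <- length(class_names)
  m <- matrix(0L, k, k, dimnames = list(class_names, class_names))
  for (i in seq_along(truth)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  m
}

# Shared head/end-to-end classifier training loop. When the encoder is
# frozen, features are computed once and only the head trains; otherwise
# every step forwards and backpropagates through the encoder too.
train_classifier <- function(clf, ds_train, ds_test, image_size,
                             epochs = 30L, batch_size = 32L, lr = 0.1,
                             momentum = 0.9, weight_decay = 0,
                             seed = 1L) {
  prep <- function(ds) lapply(ds$images, function(im) {
    im <- as_image(im)
    if (!all(dim(im)[1:2] == image_size))
      resize_bilinear(im, image_size, image_size) else im
  })
  imgs_train <- prep(ds_train)
  n <- length(imgs_train)
  if (n == 0L) stop("empty labelled training set")
  frozen <- clf$cfg$freeze_encoder
  feats_train <- if (frozen) {
    nn_forward(clf$encoder, stack_images(imgs_train), training = FALSE)$y
  } else NULL
  vel_head <- init_velocity(clf$head)
  vel_enc <- if (!frozen) init_velocity(clf$encoder) else NULL
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- max(1L, epochs * steps_per_epoch)
  gstep <- 0L
  losses <- numeric(0)
  for (epoch in seq_len(epochs)) {
    ord <- rs_eval(rng_substream(seed, 41L, epoch), sample.int(n))
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1L) * batch_size + 1L):min(s * batch_size, n)]
      if (!frozen && length(idx) < 2L) { gstep <- gstep + 1L; next }
      step_lr <- cosine_lr(gstep, total_steps, lr)
      rng <- rng_substream(seed, 43L, epoch, s)
      if (frozen) {
        f <- feats_train[idx, , drop = FALSE]
      } else {
        fe <- nn_forward(clf$encoder, stack_images(imgs_train[idx]),
                         training = TRUE, rng = rng)
        clf$encoder <- fe$net
        f <- fe$y
      }
      fh <- nn_forward(clf$head, f, training = TRUE, rng = rng)
      clf$head <- fh$net
      ce <- cross_entropy(fh$y, ds_train$labels[idx])
      losses[length(losses) + 1L] <- ce$loss
      bh <- nn_backward(clf$head, ce$grad, fh$caches)
      upd <- sgd_step_net(clf$head, bh$grads, vel_head, step_lr, momentum,
                          weight_decay)
      clf$head <- upd$net; vel_head <- upd$vel
      if (!frozen) {
        be <- nn_backward(clf$encoder, bh$dx, fe$caches)
        upd <- sgd_step_net(clf$encoder, be$grads, vel_enc, step_lr,
                            momentum, weight_decay)
        clf$encoder <- upd$net; vel_enc <- upd$vel
      }
      gstep <- gstep + 1L
    }
  }
  imgs_test <- prep(ds_test)
  feats_test <- nn_forward(clf$encoder, stack_images(imgs_test),
                           training = FALSE)$y
  probs <- predict(clf, feats_test, from_features = TRUE)
  pred <- max.col(probs, ties.method = "first")
  report <- compute_metrics(
    confusion_from_predictions(ds_test$labels, pred, ds_test$class_names))
  list(classifier = clf, report = report, train_loss = losses)
}

#' Linear evaluation of a pretrained encoder
#'
#' The standard linear-probe protocol: the dataset is split (80:20 by
#' default), the encoder from the pretrained fit is frozen, and only a
#' dropout + dense + softmax head is trained with cross-entropy on the
#' labelled fraction of the training split; metrics are computed on the
#' held-out test set.
#'
#' @param object a fitted [triview()] object (or checkpoint path).
#' @param ds a `labelled_image_set`.
#' @param split a [split_spec()].
#' @param epochs,batch_size,lr head-training hyperparameters (SGD with
#'   momentum 0.9 and cosine decay).
#' @param dropout_p dropout probability before the dense layer.
#' @param seed head init / shuffling seed.
#' @return an `eval_report` (see [compute_metrics()]) with the trained
#'   classifier attached as attribute `"classifier"`.
#' @export
linear_probe <- function(object, ds, split = split_spec(), epochs = 30L,
                         batch_size = 32L, lr = 0.1, dropout_p = 0.2,
                         seed = 1L) {
  evaluate_downstream(object, ds, split, freeze_encoder = TRUE,
                      epochs = epochs, batch_size = batch_size, lr = lr,
                      dropout_p = dropout_p, seed = seed)
}

#' Fine-tune a pretrained encoder with partial labels
#'
#' Like [linear_probe()] but the encoder weights train together with the
#' classification head (end-to-end), matching the semi-supervised
#' protocol of reusing the pretrained encoder under varying labelled
#' ratios.
#'
#' @inheritParams linear_probe
#' @return an `eval_report`.
#' @export
fine_tune <- function(object, ds, split = split_spec(), epochs = 30L,
                      batch_size = 32L, lr = 0.1, dropout_p = 0.2,
                      seed = 1L) {
  evaluate_downstream(object, ds, split, freeze_encoder = FALSE,
                      epochs = epochs, batch_size = batch_size, lr = lr,
                      dropout_p = dropout_p, seed = seed)
}

evaluate_downstream <- function(object, ds, split, freeze_encoder, epochs,
                                batch_size, lr, dropout_p, seed) {
  if (is.character(object)) object <- load_checkpoint(object)
  stopifnot(inherits(object, "triview"), inherits(ds, "labelled_image_set"))
  parts <- split_dataset(ds, split)
  ccfg <- classifier_config(length(ds$class_names), dropout_p,
                            freeze_encoder = freeze_encoder)
  clf <- build_classifier(object, ccfg, seed = seed)
  res <- train_classifier(clf, parts$labelled, parts$test,
                          image_size = object$config$image_size,
                          epochs = epochs, batch_size = batch_size, lr = lr,
                          seed = seed)
  rep <- res$report
  rep$labelled_ratio <- split$labelled_ratio
  rep$n_labelled <- length(parts$labelled$images)
  attr(rep, "classifier") <- res$classifier
  rep
}

#' Predictor-gap diagnostic
#'
#' Measures how well the prediction MLP approximates the cross-view
#' expectation of the projections: the mean over the three cyclic branch
#' pairs (1,2), (2,3), (3,1) and over the batch of
#' `||H(v_i) - v_j||^2`. The raw gap scales with the squared norm of the
#' projections, which typically grows during pretraining; for before/after
#' comparisons use `relative = TRUE`, which divides by the mean squared
#' target norm. A well-trained predictor closes the relative gap compared
#' with a randomly initialised one.
#'
#' @param model a `triview_model` (with a prediction MLP) or a fitted
#'   [triview()] object.
#' @param views list of three view batches (`H x W x 3 x N` arrays,
#'   `N >= 2`), e.g. stacked [make_triplet()] draws.
#' @param relative divide by the mean squared projection norm?
#' @return a non-negative scalar.
#' @export
predictor_gap <- function(model, views, relative = FALSE) {
  if (inherits(model, "triview")) model <- model$model
  stopifnot(inherits(model, "triview_model"))
  if (is.null(model$prediction))
    stop("predictor_gap needs a model with a prediction MLP")
  fw <- forward_triplet(model, views, training = FALSE)
  vs <- list(fw$b1$v, fw$b2$v, fw$b3$v)
  zs <- list(fw$b1$z, fw$b2$z, fw$b3$z)
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  gap <- mean(vapply(pairs, function(p) {
    d <- zs[[p[1]]] - vs[[p[2]]]
    mean(rowSums(d * d))
  }, numeric(1)))
  if (relative) {
    msq <- mean(vapply(vs, function(v) mean(rowSums(v * v)), numeric(1)))
    gap <- gap / msq
  }
  gap
}

#' Component ablation study
#'
#' Pretrains and linearly evaluates five configurations that mirror the
#' component ablation protocol: a baseline with the augmentation module,
#' projection MLP and prediction MLP all removed; each component added
#' alone; and the full method. All runs share one seed and budget.
#'
#' @param ds a `labelled_image_set`.
#' @param base_config a [train_config()] used for every run (the ablation
#'   switches are overridden per configuration).
#' @param split a [split_spec()] for the linear evaluation.
#' @param probe_epochs head-training epochs for the probe.
#' @param seed shared seed for pretraining and probing.
#' @param verbose print progress?
#' @return a data.frame with one row per configuration: configuration
#'   label, accuracy, precision, recall, f1, labelled_ratio, seed.
#' @export
run_ablation <- function(ds, base_config, split = split_spec(labelled_ratio = 0.1),
                         probe_epochs = 30L, seed = 1L, verbose = FALSE) {
  configs <- list(
    baseline = c(FALSE, FALSE, FALSE),
    `+augmentation` = c(TRUE, FALSE, FALSE),
    `+projection` = c(FALSE, TRUE, FALSE),
    `+prediction` = c(FALSE, FALSE, TRUE),
    full = c(TRUE, TRUE, TRUE)
  )
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    flags <- configs[[i]]
    cfg <- base_config
    cfg$use_augmentation <- flags[1]
    cfg$use_projection <- flags[2]
    cfg$use_prediction <- flags[3]
    cfg$seed <- as.integer(seed)
    cfg$model$seed <- as.integer(seed)
    if (verbose)
      message("ablation configuration: ", names(configs)[i])
    fit <- triview(ds, cfg)
    rep <- linear_probe(fit, ds, split, epochs = probe_epochs, seed = seed)
    rows[[i]] <- data.frame(configuration = names(configs)[i],
                            accuracy = rep$accuracy,
                            precision = rep$precision,
                            recall = rep$recall, f1 = rep$f1,
                            labelled_ratio = split$labelled_ratio,
                            seed = seed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize an evaluation report
#'
#' Writes the full report as JSON and, optionally, appends a flat CSV row
#' (configuration, labelled_ratio, seed, accuracy, precision, recall, f1).
#'
#' @param report an `eval_report`.
#' @param json_path path for the JSON report (`NULL` to skip).
#' @param csv_path path for the CSV row (`NULL` to skip; appends when the
#'   file exists).
#' @param configuration,seed provenance fields for the CSV row.
#' @return the report, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL,
                              configuration = "full", seed = NA) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(json_path)) {
    payload <- list(accuracy = report$accuracy, precision = report$precision,
                    recall = report$recall, f1 = report$f1,
                    n_test = report$n_test, average = report$average,
                    labelled_ratio = report$labelled_ratio,
                    per_class = report$per_class,
                    confusion = as.data.frame(as.table(report$confusion)))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    row <- data.frame(configuration = configuration,
                      labelled_ratio = if (is.null(report$labelled_ratio))
                        NA else report$labelled_ratio,
                      seed = seed, accuracy = report$accuracy,
                      precision = report$precision, recall = report$recall,
                      f1 = report$f1)
    utils::write.table(row, csv_path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(csv_path), append =
                         file.exists(csv_path))
  }
  invisible(report)
}
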