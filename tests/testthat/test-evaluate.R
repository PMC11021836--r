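make_balanced_ds <- function(n_per_class = 25, n_classes = 4, size = 8,
                             seed = 3) {
  rng <- rng_stream(seed)
  imgs <- lapply(seq_len(n_per_class * n_classes), function(i)
    array(rs_runif(rng, size * size * 3), c(size, size, 3)))
  labelled_image_set(imgs, rep(seq_len(n_classes), each = n_per_class),
                     paste0("c", seq_len(n_classes)))
}

test_that("splits follow the 80:20 protocol and the labelled-ratio rounding", {
  ds <- make_balanced_ds(25, 4)        # n = 100
  parts <- split_dataset(ds, split_spec(labelled_ratio = 0.1, seed = 5))
  expect_length(parts$test$images, 20)
  expect_length(parts$labelled$images, 8)   # round(0.1 * 80)
  expect_length(parts$unlabelled$images, 72)
  idx <- c(attr(parts$labelled, "idx"), attr(parts$unlabelled, "idx"),
           attr(parts$test, "idx"))
  expect_equal(sort(idx), 1:100)            # disjoint, union = all
  # stratification: balanced classes stay balanced
  expect_equal(as.numeric(table(parts$test$labels)), rep(5, 4))
  expect_equal(as.numeric(table(parts$labelled$labels)), rep(2, 4))
})

test_that("splits are deterministic and full supervision empties the pool", {
  ds <- make_balanced_ds(10, 3)
  s <- split_spec(labelled_ratio = 1.0, seed = 9)
  p1 <- split_dataset(ds, s)
  p2 <- split_dataset(ds, s)
  expect_identical(attr(p1$labelled, "idx"), attr(p2$labelled, "idx"))
  expect_length(p1$unlabelled$images, 0)
})

test_that("a class too small for the stratified labelled split is named", {
  imgs <- random_images(42, size = 8, seed = 1)
  ds <- labelled_image_set(imgs, c(rep(1, 40), rep(2, 2)), c("big", "rare"))
  expect_error(split_dataset(ds, split_spec(labelled_ratio = 0.05, seed = 2)),
               "rare")
})

test_that("split_spec rejects out-of-range fractions", {
  expect_error(split_spec(test_fraction = 0), "test_fraction")
  expect_error(split_spec(labelled_ratio = 0), "labelled_ratio")
  expect_error(split_spec(labelled_ratio = 1.5), "labelled_ratio")
})

test_that("metrics reproduce hand arithmetic on the binary fixture", {
  cm <- rbind(c(50, 5), c(10, 35))  # TP 50, FN 5, FP 10, TN 35 for class 1
  rep <- compute_metrics(cm)
  expect_equal(rep$accuracy, 0.85)
  expect_equal(rep$per_class$precision[1], 0.8333, tolerance = 1e-4)
  expect_equal(rep$per_class$recall[1], 0.9091, tolerance = 1e-4)
  expect_equal(rep$per_class$f1[1], 0.8696, tolerance = 1e-4)
  expect_equal(rep$per_class$tn[1], 35)
  expect_equal(rep$n_test, 100)
})

test_that("metrics match the one-vs-rest oracle on random confusion matrices", {
  rng <- rng_stream(55)
  for (i in 1:20) {
    k <- 2 + (i %% 4)
    cm <- matrix(rs_sample_int(rng, 30, k * k, replace = TRUE) - 1, k, k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- suppressWarnings(compute_metrics(cm))
    want <- metrics_oracle(cm)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
    expect_equal(got$per_class$precision, unname(want$per_class[, "precision"]))
  }
})

test_that("metric edge cases: perfect diagonal, zero denominators, errors", {
  perfect <- diag(c(7, 9, 4))
  rep <- compute_metrics(perfect)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)
  # a never-predicted class has precision 0 with a warning
  cm <- rbind(c(0, 3), c(0, 5))
  w <- capture_warnings(rep0 <- compute_metrics(cm))  # precision and F1 warn
  expect_true(all(grepl("zero denominator", w)))
  expect_length(w, 2)
  expect_equal(rep0$per_class$precision[1], 0)
  expect_error(compute_metrics(rbind(c(-1, 0), c(0, 2))), "non-negative")
  expect_error(compute_metrics(matrix(0, 2, 3)), "square")
  # micro averaging: precision = recall = accuracy for a complete matrix
  cmr <- rbind(c(8, 2, 0), c(1, 5, 1), c(0, 3, 9))
  micro <- compute_metrics(cmr, average = "micro")
  expect_equal(micro$precision, micro$accuracy)
  expect_equal(micro$recall, micro$accuracy)
})

test_that("accuracy is invariant under consistent class relabelling", {
  rng <- rng_stream(66)
  cm <- matrix(rs_sample_int(rng, 20, 16, replace = TRUE), 4, 4)
  p <- rs_sample_int(rng, 4, 4)
  got <- suppressWarnings(compute_metrics(cm))
  perm <- suppressWarnings(compute_metrics(cm[p, p]))
  expect_equal(perm$accuracy, got$accuracy)
  expect_equal(perm$f1, got$f1)  # macro average is permutation-invariant too
})

test_that("classifier probabilities are normalized and the frozen encoder stays put", {
  ds <- generate_dataset(tiny_synth_spec())
  fit <- triview(ds, train_config(image_size = 24, epochs = 1,
                                  batch_size = 8,
                                  model = model_config("tinycnn",
                                                       feature_dim = 12,
                                                       proj_dim = 24,
                                                       pred_hidden_dim = 8),
                                  seed = 2))
  clf <- build_classifier(fit, classifier_config(4))
  probs <- predict(clf, ds$images[1:5])
  expect_equal(dim(probs), c(5, 4))
  expect_equal(rowSums(probs), rep(1, 5))
  rep <- suppressWarnings(   # tiny probe: zero-denominator classes expected
    linear_probe(fit, ds, split_spec(labelled_ratio = 0.5, seed = 4),
                 epochs = 5))
  trained <- attr(rep, "classifier")
  expect_identical(trained$encoder, fit$model$encoder)  # bit-identical weights
  # dropout disabled in evaluation: repeated predictions identical
  expect_identical(predict(trained, ds$images[1:3]),
                   predict(trained, ds$images[1:3]))
})

test_that("a linear probe on trivially separable classes is perfect", {
  spec <- synthetic_spec(n_classes = 4, n_per_class = 12, image_size = 16,
                         texture_freq = rep(0, 4),
                         blob_count_range = rep(list(c(0, 0)), 4),
                         noise_sigma = 0, seed = 3)
  ds <- generate_dataset(spec)
  fit <- triview(ds, train_config(image_size = 16, epochs = 2,
                                  batch_size = 12,
                                  model = tiny_model_cfg(), seed = 6))
  rep <- linear_probe(fit, ds, split_spec(labelled_ratio = 1.0, seed = 8))
  expect_equal(rep$accuracy, 1.0)
  expect_equal(sum(rep$confusion), rep$n_test)
})

test_that("fine-tuning with lr = 0 leaves every parameter unchanged", {
  ds <- generate_dataset(tiny_synth_spec())
  fit <- triview(ds, train_config(image_size = 24, epochs = 1,
                                  batch_size = 8, model = tiny_model_cfg(),
                                  seed = 2))
  rep <- suppressWarnings(   # an untrained head predicts degenerately
    fine_tune(fit, ds, split_spec(labelled_ratio = 0.5, seed = 4),
              epochs = 2, lr = 0))
  tuned <- attr(rep, "classifier")
  flat <- function(net) unlist(lapply(net$layers, function(l) l$params))
  expect_identical(flat(tuned$encoder), flat(fit$model$encoder))
  expect_equal(sum(rep$confusion), rep$n_test)
  expect_equal(rep$n_test, length(split_dataset(
    ds, split_spec(labelled_ratio = 0.5, seed = 4))$test$images))
})

test_that("fine-tuning can separate what a frozen random encoder can", {
  spec <- synthetic_spec(n_classes = 3, n_per_class = 8, image_size = 16,
                         texture_freq = rep(0, 3),
                         blob_count_range = rep(list(c(0, 0)), 3),
                         noise_sigma = 0, seed = 5)
  ds <- generate_dataset(spec)
  fit <- random_init_fit(tiny_model_cfg(),
                         train_config(image_size = 16, epochs = 1,
                                      batch_size = 8,
                                      model = tiny_model_cfg()))
  rep <- fine_tune(fit, ds, split_spec(labelled_ratio = 1.0, seed = 2),
                   epochs = 10, batch_size = 6)
  expect_gt(rep$accuracy, 1 / 3)
})

test_that("predictor gap is zero for an identity predictor on shared views", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  # replace H by the exact identity map
  ident <- triview:::layer_dense(cfg$proj_dim, cfg$proj_dim, rng_stream(1))
  ident$params$W <- diag(cfg$proj_dim)
  ident$params$b <- numeric(cfg$proj_dim)
  m$prediction <- triview:::nn_sequential(list(ident))
  x <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  expect_equal(predictor_gap(m, list(x, x, x)), 0, tolerance = 1e-20)
})

test_that("predictor gap equals a direct per-pair computation", {
  m <- build_model(tiny_model_cfg())
  rng <- rng_stream(31)
  views <- lapply(1:3, function(v)
    array(rs_runif(rng, 16 * 16 * 3 * 4), c(16, 16, 3, 4)))
  got <- predictor_gap(m, views)
  fw <- forward_triplet(m, views, training = FALSE)
  vs <- list(fw$b1$v, fw$b2$v, fw$b3$v)
  zs <- list(fw$b1$z, fw$b2$z, fw$b3$z)
  want <- mean(c(mean(rowSums((zs[[1]] - vs[[2]])^2)),
                 mean(rowSums((zs[[2]] - vs[[3]])^2)),
                 mean(rowSums((zs[[3]] - vs[[1]])^2))))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(predictor_gap(build_model(tiny_model_cfg(),
                                         use_prediction = FALSE), views),
               "prediction MLP")
})

test_that("the ablation runner emits the five labelled configurations", {
  ds <- generate_dataset(synthetic_spec(n_classes = 3, n_per_class = 8,
                                        image_size = 16, seed = 9))
  # feature width 12: wide enough that ReLU + pooling cannot zero out an
  # entire feature vector (a zero vector is a domain error for the loss)
  base <- train_config(image_size = 16, epochs = 1, batch_size = 8,
                       model = model_config("tinycnn", feature_dim = 12,
                                            proj_dim = 24,
                                            pred_hidden_dim = 12),
                       seed = 3)
  tab <- suppressWarnings(   # short probes may leave classes unpredicted
    run_ablation(ds, base, split = split_spec(labelled_ratio = 0.5),
                 probe_epochs = 5, seed = 3))
  expect_equal(nrow(tab), 5)
  expect_equal(tab$configuration,
               c("baseline", "+augmentation", "+projection", "+prediction",
                 "full"))
  for (col in c("accuracy", "precision", "recall", "f1")) {
    expect_true(all(tab[[col]] >= 0 & tab[[col]] <= 1))
  }
})

test_that("evaluation reports serialize to JSON and CSV", {
  cm <- rbind(c(9, 1), c(2, 8))
  rep <- compute_metrics(cm)
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_eval_report(rep, jp, cp, configuration = "full", seed = 1)
  j <- jsonlite::read_json(jp)
  expect_equal(j$accuracy, rep$accuracy)
  write_eval_report(rep, NULL, cp, configuration = "full", seed = 2)
  tab <- utils::read.csv(cp)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$accuracy, rep(rep$accuracy, 2))
})

test_that("pretraining closes the relative predictor gap", {
  ds <- generate_dataset(synthetic_spec(seed = 7))
  mc <- model_config("tinycnn", feature_dim = 32, proj_dim = 64,
                     pred_hidden_dim = 16, seed = 7)
  tc <- train_config(image_size = 64, epochs = 3, batch_size = 32,
                     model = mc, seed = 7)
  fit <- triview(ds, tc)
  rngb <- rng_stream(99)
  views <- lapply(1:3, function(v) triview:::stack_images(
    lapply(ds$images[1:16], function(im)
      augment_view(im, tc$augment, rngb))))
  gap_rand <- predictor_gap(build_model(mc), views, relative = TRUE)
  gap_fit <- predictor_gap(fit, views, relative = TRUE)
  expect_lte(gap_fit, gap_rand)
})
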