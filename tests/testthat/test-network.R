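test_that("model_config validates and propagates dimensions", {
  cfg <- model_config("tinycnn", feature_dim = 32, proj_dim = 64,
                      pred_hidden_dim = 16)
  expect_equal(cfg$feature_dim, 32L)
  expect_error(model_config("vgg16"), "resnet50")
  expect_error(model_config("resnet50", feature_dim = 512), "2048")
  expect_equal(model_config("resnet50")$feature_dim, 2048L)
})

test_that("the tinycnn encoder maps batches to ordered feature vectors", {
  cfg <- tiny_model_cfg()
  enc <- build_encoder(cfg)
  x <- array(runif(16 * 16 * 3 * 5), c(16, 16, 3, 5))
  f <- triview:::nn_forward(enc, x, training = FALSE)$y
  expect_equal(dim(f), c(5, 8))
  expect_true(all(is.finite(f)))
  # order-preserving: single-sample forward matches the batch rows
  for (i in c(1, 3, 5)) {
    fi <- triview:::nn_forward(enc, x[, , , i, drop = FALSE],
                               training = FALSE)$y
    expect_equal(as.numeric(fi), f[i, ], tolerance = 1e-12)
  }
})

test_that("the projection MLP has the documented structure", {
  cfg <- tiny_model_cfg()
  proj <- build_projection_mlp(cfg)
  types <- vapply(proj$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "dense"), 3L)
  expect_equal(sum(types == "relu"), 2L)
  expect_equal(sum(types == "bn1d"), 3L)
  # last two layers: dense then batch norm, no trailing relu
  expect_equal(types[length(types)], "bn1d")
  expect_equal(types[length(types) - 1L], "dense")
  e <- matrix(rnorm(2 * cfg$feature_dim), 2)
  v <- triview:::nn_forward(proj, e, training = FALSE)$y
  expect_equal(dim(v), c(2L, cfg$proj_dim))
})

test_that("the prediction MLP is a bottleneck with one BN and one ReLU", {
  cfg <- tiny_model_cfg()
  pred <- build_prediction_mlp(cfg)
  types <- vapply(pred$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "dense"), 2L)
  expect_equal(sum(types == "relu"), 1L)
  expect_equal(sum(types == "bn1d"), 1L)
  expect_equal(pred$layers[[1]]$cfg$d_out, cfg$pred_hidden_dim)
  expect_equal(pred$layers[[length(types)]]$cfg$d_out, cfg$proj_dim)
  expect_equal(types[length(types)], "dense")  # no BN/ReLU after the output
})

test_that("identical views produce identical branch outputs (weight sharing)", {
  m <- build_model(tiny_model_cfg())
  x <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  fw <- forward_triplet(m, list(x, x, x), training = FALSE)
  expect_identical(fw$b1$e, fw$b2$e)
  expect_identical(fw$b2$v, fw$b3$v)
  expect_identical(fw$b1$z, fw$b3$z)
  expect_true(all(is.finite(fw$b1$z)))
})

test_that("a single weight perturbation shifts all three branches identically", {
  m <- build_model(tiny_model_cfg())
  x1 <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  base <- forward_triplet(m, list(x1, x1, x1), training = FALSE)
  m2 <- m
  m2$encoder$layers[[1]]$params$W[1] <-
    m2$encoder$layers[[1]]$params$W[1] + 0.5
  pert <- forward_triplet(m2, list(x1, x1, x1), training = FALSE)
  d1 <- pert$b1$z - base$b1$z
  d2 <- pert$b2$z - base$b2$z
  d3 <- pert$b3$z - base$b3$z
  expect_false(isTRUE(all.equal(max(abs(d1)), 0)))
  expect_identical(d1, d2)
  expect_identical(d2, d3)
})

test_that("the triple-branch model holds a single parameter set", {
  m <- build_model(tiny_model_cfg())
  single <- triview:::n_params(m$encoder) +
    triview:::n_params(m$projection) + triview:::n_params(m$prediction)
  expect_equal(triview:::model_n_params(m), single)
})

test_that("evaluation-mode forward passes are deterministic", {
  m <- build_model(tiny_model_cfg())
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  f1 <- forward_triplet(m, list(x, x, x), training = FALSE)
  f2 <- forward_triplet(m, list(x, x, x), training = FALSE)
  expect_identical(f1$b1$z, f2$b1$z)
})

test_that("network gradients agree with finite differences (stop-grad loss)", {
  mc <- model_config("tinycnn", feature_dim = 6, proj_dim = 10,
                     pred_hidden_dim = 4, seed = 3)
  tc <- train_config(image_size = 8, epochs = 1, batch_size = 3, model = mc,
                     seed = 5)
  m <- build_model(mc)
  imgs <- random_images(3, size = 8, seed = 20)
  views <- triview:::make_view_batches(imgs, tc, rng_stream(4))
  fw0 <- forward_triplet(m, views, training = TRUE)
  v_fix <- list(fw0$b1$v, fw0$b2$v, fw0$b3$v)
  loss_sg <- function(model) {
    fw <- forward_triplet(model, views, training = TRUE)
    as.numeric(triloss(fw$b1$z, fw$b2$z, fw$b3$z,
                       v_fix[[1]], v_fix[[2]], v_fix[[3]]))
  }
  grads <- local({
    fw <- forward_triplet(m, views, training = TRUE)
    br <- list(fw$b1, fw$b2, fw$b3)
    g <- triloss_gradient(fw$b1$z, fw$b2$z, fw$b3$z,
                          fw$b1$v, fw$b2$v, fw$b3$v)
    acc <- list(encoder = NULL, projection = NULL, prediction = NULL)
    for (i in 1:3) {
      d <- g$z[[i]]
      bh <- triview:::nn_backward(fw$model$prediction, d,
                                  br[[i]]$caches$prediction)
      acc$prediction <- triview:::add_grad_lists(acc$prediction, bh$grads)
      bp <- triview:::nn_backward(fw$model$projection, bh$dx,
                                  br[[i]]$caches$projection)
      acc$projection <- triview:::add_grad_lists(acc$projection, bp$grads)
      be <- triview:::nn_backward(fw$model$encoder, bp$dx,
                                  br[[i]]$caches$encoder)
      acc$encoder <- triview:::add_grad_lists(acc$encoder, be$grads)
    }
    acc
  })
  h <- 1e-5
  probes <- list(
    list("encoder", 1L, "W", 5L), list("encoder", 2L, "gamma", 3L),
    list("encoder", 4L, "W", 17L), list("encoder", 7L, "W", 3L),
    list("projection", 1L, "W", 11L), list("projection", 8L, "gamma", 6L),
    list("prediction", 1L, "W", 9L), list("prediction", 4L, "W", 13L)
  )
  for (p in probes) {
    up <- m; dn <- m
    up[[p[[1]]]]$layers[[p[[2]]]]$params[[p[[3]]]][p[[4]]] <-
      up[[p[[1]]]]$layers[[p[[2]]]]$params[[p[[3]]]][p[[4]]] + h
    dn[[p[[1]]]]$layers[[p[[2]]]]$params[[p[[3]]]][p[[4]]] <-
      dn[[p[[1]]]]$layers[[p[[2]]]]$params[[p[[3]]]][p[[4]]] - h
    fd <- (loss_sg(up) - loss_sg(dn)) / (2 * h)
    an <- grads[[p[[1]]]][[p[[2]]]]$params[[p[[3]]]][p[[4]]]
    expect_equal(an, fd, tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip bit-identical evaluation outputs", {
  m <- build_model(tiny_model_cfg())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  expect_identical(forward_triplet(m, list(x, x, x))$b1$z,
                   forward_triplet(m2, list(x, x, x))$b1$z)
  saveRDS(list(foo = 1), path)
  expect_error(load_checkpoint(path), "not a triview checkpoint")
})
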