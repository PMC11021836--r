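#' Negative cosine similarity
#'
#' The alignment term between a prediction vector `z` and a projection
#' target `v`: minus the dot product of the l2-normalized vectors,
#' `-(z/||z||) . (v/||v||)`, with values in \[-1, 1\] and minimum -1 at
#' positively collinear inputs. For matrices (rows = samples) the per-row
#' values are averaged.
#'
#' @param v,z numeric vectors, or matrices with one sample per row.
#' @return a scalar.
#' @export
negative_cosine <- function(v, z) {
  v <- as_batch_matrix(v)
  z <- as_batch_matrix(z)
  if (!identical(dim(v), dim(z)))
    stop("'v' and 'z' must have the same dimensions")
  mean(rowSums(l2_normalize_rows(z) * -l2_normalize_rows(v)))
}

as_batch_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Row-wise l2 normalization; norms below 1e-8 are a domain error (the
# direction of a near-zero vector is undefined), an epsilon of 1e-12 under
# the square root guards the well-conditioned case.
l2_normalize_rows <- function(x) {
  ss <- rowSums(x * x)
  if (any(sqrt(ss) < 1e-8))
    stop("zero vector: cosine similarity is undefined for vectors with ",
         "norm below 1e-8")
  x / sqrt(ss + 1e-12)
}

check_triloss_inputs <- function(z1, z2, z3, v1, v2, v3) {
  mats <- list(z1 = z1, z2 = z2, z3 = z3, v1 = v1, v2 = v2, v3 = v3)
  mats <- lapply(mats, as_batch_matrix)
  d <- dim(mats[[1]])
  for (nm in names(mats)) {
    if (!identical(dim(mats[[nm]]), d))
      stop("shape mismatch: all six inputs must share dimensions; '", nm,
           "' differs")
    if (anyNA(mats[[nm]]) || any(!is.finite(mats[[nm]])))
      stop("non-finite values in '", nm, "'")
  }
  mats
}

#' Triple-view loss
#'
#' The six-term pairwise loss over three views: each branch's prediction is
#' aligned with the other two branches' projections,
#' \deqn{L = \frac{1}{3}\left[\tfrac12 N(z_1,v_2) + \tfrac12 N(z_2,v_1) +
#'   \tfrac12 N(z_1,v_3) + \tfrac12 N(z_3,v_1) + \tfrac12 N(z_2,v_3) +
#'   \tfrac12 N(z_3,v_2)\right],}
#' where `N` is [negative_cosine()]. The half-weighted six-term sum is
#' divided by 3 (the number of unordered view pairs) so the minimum is -1,
#' attained when all six vectors are pairwise positively collinear; the raw
#' undivided sum is attached as attribute `"raw"`. For batches the loss is
#' the mean of per-image losses. The stop-gradient on the projection
#' targets affects differentiation only, never the value; see
#' [triloss_gradient()].
#'
#' @param z1,z2,z3 prediction vectors (or batch matrices, rows = samples).
#' @param v1,v2,v3 projection vectors (or batch matrices).
#' @return a scalar in \[-1, 1\] with attribute `"raw"` (the sum before
#'   division by 3, in \[-3, 3\]).
#' @export
triloss <- function(z1, z2, z3, v1, v2, v3) {
  m <- check_triloss_inputs(z1, z2, z3, v1, v2, v3)
  zn <- lapply(m[1:3], l2_normalize_rows)
  vn <- lapply(m[4:6], l2_normalize_rows)
  pair <- function(i, j) mean(rowSums(zn[[i]] * -vn[[j]]))
  raw <- 0.5 * (pair(1, 2) + pair(2, 1) + pair(1, 3) +
                pair(3, 1) + pair(2, 3) + pair(3, 2))
  structure(raw / 3, raw = raw)
}

# Gradient of mean_rows(-zhat . vhat) with respect to the first argument,
# holding the second fixed: for each row,
#   d/dz [-(z.v)/(||z|| ||v||)] = -(vhat - (zhat.vhat) zhat) / ||z||.
neg_cos_grad_first <- function(z, v) {
  n <- nrow(z)
  znrm <- sqrt(rowSums(z * z) + 1e-12)
  zh <- z / znrm
  vh <- l2_normalize_rows(v)
  cosv <- rowSums(zh * vh)
  -(vh - zh * cosv) / znrm / n
}

#' Gradient of the triple-view loss
#'
#' Analytic gradients of [triloss()] with respect to its six inputs. With
#' `stop_targets = TRUE` (the training configuration) each projection
#' target `v` is treated as a constant under differentiation, so all
#' v-side gradients are exactly zero and only the prediction side carries
#' gradient; with `stop_targets = FALSE` the v-side gradients are the true
#' partial derivatives. Gradients are of the normalized (divided by 3),
#' batch-averaged loss.
#'
#' @inheritParams triloss
#' @param stop_targets stop gradients on the projection targets?
#' @return a list with elements `z` and `v`, each a list of three gradient
#'   matrices shaped like the inputs.
#' @export
triloss_gradient <- function(z1, z2, z3, v1, v2, v3, stop_targets = TRUE) {
  m <- check_triloss_inputs(z1, z2, z3, v1, v2, v3)
  zs <- m[1:3]
  vs <- m[4:6]
  # per-branch partner indices: z_i pairs with v_j for j != i
  gz <- lapply(1:3, function(i) {
    partners <- setdiff(1:3, i)
    g <- 0
    for (j in partners) g <- g + neg_cos_grad_first(zs[[i]], vs[[j]])
    g / 6  # each term enters with weight 1/2, and the sum is divided by 3
  })
  gv <- if (stop_targets) {
    lapply(zs, function(z) z * 0)
  } else {
    lapply(1:3, function(j) {
      partners <- setdiff(1:3, j)
      g <- 0
      for (i in partners) g <- g + neg_cos_grad_first(vs[[j]], zs[[i]])
      g / 6
    })
  }
  list(z = gz, v = gv)
}

#' Check the stop-gradient contract numerically
#'
#' Compares the analytic [triloss_gradient()] against central finite
#' differences of [triloss()] and reports the maximum absolute v-side
#' gradient together with the largest relative error on the z-side (and,
#' when `stop_targets = FALSE`, the v-side).
#'
#' @inheritParams triloss_gradient
#' @param h finite-difference step.
#' @return a list: `max_v_grad`, `max_rel_err_z`, `max_rel_err_v` (`NA`
#'   when targets are stopped), and the analytic `gradient`.
#' @export
triloss_gradient_check <- function(z1, z2, z3, v1, v2, v3,
                                   stop_targets = TRUE, h = 1e-4) {
  g <- triloss_gradient(z1, z2, z3, v1, v2, v3, stop_targets = stop_targets)
  args <- list(z1 = z1, z2 = z2, z3 = z3, v1 = v1, v2 = v2, v3 = v3)
  fd_one <- function(which) {
    x <- as_batch_matrix(args[[which]])
    gfd <- x * 0
    for (k in seq_along(x)) {
      up <- args; dn <- args
      xu <- x; xu[k] <- xu[k] + h
      xd <- x; xd[k] <- xd[k] - h
      up[[which]] <- xu; dn[[which]] <- xd
      gfd[k] <- (as.numeric(do.call(triloss, up)) -
                 as.numeric(do.call(triloss, dn))) / (2 * h)
    }
    gfd
  }
  rel_err <- function(ga, gn) {
    denom <- pmax(abs(gn), 1e-6)
    max(abs(ga - gn) / denom)
  }
  errz <- max(vapply(1:3, function(i)
    rel_err(g$z[[i]], fd_one(paste0("z", i))), numeric(1)))
  errv <- if (stop_targets) NA_real_ else
    max(vapply(1:3, function(j)
      rel_err(g$v[[j]], fd_one(paste0("v", j))), numeric(1)))
  list(max_v_grad = max(vapply(g$v, function(m) max(abs(m)), numeric(1))),
       max_rel_err_z = errz, max_rel_err_v = errv, gradient = g)
}
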