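#' Column-wise scaling of a block
#'
#' Centers every column and optionally divides by the column standard
#' deviation (`"uv"`, unit variance) or its square root (`"pareto"`).
#' Zero-variance columns are centered only and flagged.
#'
#' @param X numeric matrix (>= 2 rows) or [feature_block()].
#' @param method `"uv"`, `"pareto"` or `"center"`.
#' @return list with `X` (scaled matrix), `center`, `scale`, `constant`
#'   (logical flags), `method`.
#' @export
scale_block <- function(X, method = c("uv", "pareto", "center")) {
  method <- match.arg(method)
  X <- block_matrix(X)
  abort_if(nrow(X) < 2, "scaling needs >= 2 samples")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  constant <- sds == 0
  scl <- switch(method,
                uv = ifelse(constant, 1, sds),
                pareto = ifelse(constant, 1, sqrt(sds)),
                center = rep(1, ncol(X)))
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl, constant = constant, method = method)
}

apply_scaling <- function(X, scaling) {
  X <- block_matrix(X)
  sweep(sweep(X, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

# Kernel OPLS for a single centered response: one predictive component plus
# n_ortho response-orthogonal components, expressed entirely through the
# linear kernel K = X X'. Equivalent to primal OPLS on the (implicit)
# weighted concatenated matrix.
kopls_fit <- function(K, yc, n_ortho) {
  Kd <- K
  comps <- list()
  for (i in seq_len(n_ortho)) {
    s <- sqrt(drop(crossprod(yc, Kd %*% yc)))
    if (s < 1e-12) break
    t <- drop(Kd %*% yc) / s
    tt <- sum(t^2)
    Kt <- drop(Kd %*% t)
    wp <- drop(crossprod(yc, Kt)) / (s * tt)   # w'p
    pp <- drop(crossprod(t, Kt)) / tt^2        # p'p
    wo2 <- pp - wp^2
    if (wo2 < 1e-12) break                     # no orthogonal variation left
    to <- (Kt / tt - wp * t) / sqrt(wo2)
    toto <- sum(to^2)
    v <- drop(Kd %*% to) / toto
    # deflate: Kd <- (I - to to'/toto) Kd (I - to to'/toto)
    Kd <- Kd - outer(to, v) - outer(v, to) + (sum(to * v) / toto) * outer(to, to)
    comps[[i]] <- list(s = s, t = t, tt = tt, wp = wp, wo_norm = sqrt(wo2),
                       to = to, toto = toto, v = v)
  }
  s_final <- sqrt(drop(crossprod(yc, Kd %*% yc)))
  t_pred <- if (s_final > 1e-12) drop(Kd %*% yc) / s_final else rep(0, length(yc))
  T_ortho <- if (length(comps))
    do.call(cbind, lapply(comps, `[[`, "to")) else
      matrix(0, length(yc), 0)
  list(t_pred = t_pred, T_ortho = T_ortho, comps = comps, s_final = s_final)
}

# Project a cross-kernel K_te (m x n_train) through a fitted kernel OPLS.
kopls_project <- function(fit, K_te, yc) {
  To_te <- matrix(0, nrow(K_te), length(fit$comps))
  for (i in seq_along(fit$comps)) {
    cp <- fit$comps[[i]]
    t_te <- drop(K_te %*% yc) / cp$s
    to_te <- (drop(K_te %*% cp$t) / cp$tt - cp$wp * t_te) / cp$wo_norm
    To_te[, i] <- to_te
    A <- K_te - outer(to_te, cp$v)
    K_te <- A - outer(drop(A %*% cp$to), cp$to) / cp$toto
  }
  t_pred <- if (fit$s_final > 1e-12) drop(K_te %*% yc) / fit$s_final else
    rep(0, nrow(K_te))
  list(t_pred = t_pred, T_ortho = To_te)
}

consensus_kernels <- function(blocks, scale_method, scalings = NULL) {
  fresh <- is.null(scalings)
  if (fresh) scalings <- vector("list", length(blocks))
  Xs <- vector("list", length(blocks))
  kn <- numeric(length(blocks))
  Ks <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    if (fresh) {
      sc <- scale_block(blocks[[b]], scale_method)
      Xs[[b]] <- sc$X
      scalings[[b]] <- sc[c("center", "scale", "constant", "method")]
    } else {
      Xs[[b]] <- apply_scaling(blocks[[b]], scalings[[b]])
    }
    K <- tcrossprod(Xs[[b]])
    kn[b] <- sqrt(sum(K^2))
    abort_if(kn[b] < 1e-12, "a block has no variance after scaling")
    Ks[[b]] <- K / kn[b]
  }
  list(K_blocks = Ks, kernel_norms = kn, scalings = scalings, Xs = Xs)
}

#' Fit a consensus (multiblock) OPLS model
#'
#' Relates two or more row-aligned predictor blocks to one response through a
#' weighted consensus of per-block linear kernels. Each block kernel
#' `K_b = X_b X_b'` is Frobenius-normalized; the consensus kernel
#' `K = sum(w_b K_b)` is decomposed by kernel OPLS into one
#' response-predictive component and `n_ortho` orthogonal components; block
#' weights are then updated proportionally to the squared congruence between
#' `K_b` and the predictive-score outer product and the fit is repeated until
#' the weights stabilize. The predictive score is oriented so that it
#' correlates positively with the response.
#'
#' @param blocks named list of matrices or [feature_block()]s with aligned
#'   rows (samples).
#' @param y numeric response (e.g. percent inhibition), one value per sample.
#' @param n_ortho number of orthogonal components (default 1).
#' @param scale column scaling applied within each block ([scale_block()]).
#' @param max_iter,tol block-weight iteration controls.
#' @return object of class `mbopls`: block weights, predictive score
#'   `t_pred`, orthogonal scores `T_ortho`, `r2y`, per-component explained
#'   X-variance, scaling parameters, and the kernel internals needed to
#'   project new samples with [predict.mbopls()].
#' @export
fit_consensus_opls <- function(blocks, y, n_ortho = 1,
                               scale = c("uv", "pareto", "center"),
                               max_iter = 100, tol = 1e-6) {
  scale <- match.arg(scale)
  abort_if(!is.list(blocks) || length(blocks) < 1, "blocks must be a list")
  mats <- lapply(blocks, block_matrix)
  n <- nrow(mats[[1]])
  abort_if(!all(vapply(mats, nrow, 0L) == n),
           "blocks are not row-aligned (sample counts differ)")
  rn <- lapply(mats, rownames)
  if (!is.null(rn[[1]])) {
    abort_if(!all(vapply(rn, identical, TRUE, y = rn[[1]])),
             "blocks are not row-aligned (sample ids differ)")
  }
  abort_if(n < 3, "need >= 3 samples")
  abort_if(length(y) != n, "y must have one value per sample")
  abort_if(stats::sd(y) == 0, "y has zero variance")
  abort_if(n_ortho < 0, "n_ortho must be >= 0")

  ck <- consensus_kernels(mats, scale)
  B <- length(mats)
  y_mean <- mean(y)
  yc <- y - y_mean
  w <- rep(1 / B, B)
  converged <- FALSE
  n_iter <- 0L
  kfit <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    K <- Reduce(`+`, Map(`*`, ck$K_blocks, w))
    kfit <- kopls_fit(K, yc, n_ortho)
    t <- kfit$t_pred
    tt <- sum(t^2)
    g <- vapply(ck$K_blocks, function(Kb)
      (drop(crossprod(t, Kb %*% t)) / tt)^2, 0)
    if (sum(g) < 1e-300) break
    w_new <- g / sum(g)
    if (max(abs(w_new - w)) < tol) { w <- w_new; converged <- TRUE; break }
    w <- w_new
  }
  K <- Reduce(`+`, Map(`*`, ck$K_blocks, w))
  kfit <- kopls_fit(K, yc, n_ortho)

  flip <- stats::cov(kfit$t_pred, yc) < 0
  t_pred <- if (flip) -kfit$t_pred else kfit$t_pred
  q <- sum(t_pred * yc) / sum(t_pred^2)
  yhat <- t_pred * q
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)

  scores <- cbind(predictive = t_pred, kfit$T_ortho)
  if (ncol(kfit$T_ortho) > 0)
    colnames(scores)[-1] <- paste0("ortho_", seq_len(ncol(kfit$T_ortho)))
  trK <- sum(diag(K))
  ev <- apply(scores, 2, function(t0)
    drop(crossprod(t0, K %*% t0)) / sum(t0^2) / trK)

  if (is.null(names(w)))
    names(w) <- if (!is.null(names(blocks))) names(blocks) else
      paste0("block_", seq_len(B))

  structure(list(
    block_weights = w, t_pred = t_pred, T_ortho = kfit$T_ortho, q = q,
    y = y, y_mean = y_mean, r2y = r2y, q2 = NA_real_,
    explained_variance = ev, n_ortho = ncol(kfit$T_ortho),
    n_ortho_requested = n_ortho, converged = converged, n_iter = n_iter,
    scale_method = scale, scalings = ck$scalings, Xs_train = ck$Xs,
    kernel_norms = ck$kernel_norms, kopls = kfit, flip = flip,
    block_names = names(w),
    ion_ids = lapply(mats, colnames)), class = "mbopls")
}

#' @export
print.mbopls <- function(x, ...) {
  cat(sprintf(
    "<mbopls> %d samples, %d block(s); 1 predictive + %d orthogonal component(s)\n",
    length(x$t_pred), length(x$block_weights), x$n_ortho))
  cat(sprintf("  R2Y = %.3f%s; block weights: %s\n", x$r2y,
              if (is.na(x$q2)) "" else sprintf(", Q2 = %.3f", x$q2),
              paste(sprintf("%s=%.3f", names(x$block_weights),
                            x$block_weights), collapse = ", ")))
  cat(sprintf("  explained X variance: %s\n",
              paste(sprintf("%s=%.1f%%", names(x$explained_variance),
                            100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}

#' Project new samples through a fitted consensus OPLS
#'
#' @param object a fitted `mbopls` model.
#' @param newblocks list of blocks (same order and ion sets as at fit time).
#' @param ... unused.
#' @return list with `t_pred`, `T_ortho` and `yhat` for the new samples.
#' @export
predict.mbopls <- function(object, newblocks, ...) {
  mats <- lapply(newblocks, block_matrix)
  abort_if(length(mats) != length(object$block_weights),
           "wrong number of blocks")
  K_te <- 0
  for (b in seq_along(mats)) {
    Xte <- apply_scaling(mats[[b]], object$scalings[[b]])
    K_te <- K_te + object$block_weights[b] *
      tcrossprod(Xte, object$Xs_train[[b]]) / object$kernel_norms[b]
  }
  pr <- kopls_project(object$kopls, K_te, object$y - object$y_mean)
  t_pred <- if (object$flip) -pr$t_pred else pr$t_pred
  list(t_pred = t_pred, T_ortho = pr$T_ortho,
       yhat = t_pred * object$q + object$y_mean)
}

#' Cross-validated Q2 of the consensus OPLS
#'
#' K-fold cross-validation with fold assignment optionally stratified (e.g.
#' by organ x site cell). Every fold refits the full iterative consensus
#' model — including block scaling and block-weight estimation — on the
#' training samples only, projects the held-out samples with the training
#' scaling, and accumulates PRESS. `Q2 = 1 - PRESS / SS_tot`.
#'
#' @inheritParams fit_consensus_opls
#' @param k_folds number of folds, between 2 and the sample count.
#' @param seed seed for the fold assignment.
#' @param strata optional factor used to stratify the folds.
#' @return Q2 (a single number, possibly negative).
#' @export
cross_validated_q2 <- function(blocks, y, n_ortho = 1, k_folds = 7, seed = 1,
                               strata = NULL,
                               scale = c("uv", "pareto", "center")) {
  scale <- match.arg(scale)
  mats <- lapply(blocks, block_matrix)
  n <- nrow(mats[[1]])
  abort_if(k_folds < 2 || k_folds > n, "k_folds must be between 2 and n")
  folds <- make_folds(n, k_folds, seed, strata)
  press <- 0
  for (f in seq_len(k_folds)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    fit <- fit_consensus_opls(lapply(mats, function(m) m[tr, , drop = FALSE]),
                              y[tr], n_ortho = n_ortho, scale = scale)
    pr <- predict(fit, lapply(mats, function(m) m[te, , drop = FALSE]))
    press <- press + sum((y[te] - pr$yhat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

make_folds <- function(n, k, seed, strata = NULL) {
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    folds <- integer(n)
    if (is.null(strata)) strata <- rep(1L, n)
    offset <- 0L
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
    folds
  })
}

#' Permutation test of the cross-validated Q2
#'
#' Recomputes Q2 under random permutations of the response. The p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @inheritParams cross_validated_q2
#' @param n_permutations number of response permutations (>= 19).
#' @return list of class `permutation_result`: `observed_q2`, `null_q2`,
#'   `p_value`.
#' @export
permutation_test <- function(blocks, y, n_ortho = 1, n_permutations = 99,
                             k_folds = 7, seed = 1, strata = NULL,
                             scale = c("uv", "pareto", "center")) {
  scale <- match.arg(scale)
  abort_if(n_permutations < 19, "use at least 19 permutations")
  obs <- cross_validated_q2(blocks, y, n_ortho, k_folds, seed, strata, scale)
  null_q2 <- vapply(seq_len(n_permutations), function(b) {
    y_perm <- withr::with_seed(stage_seed(seed, 100L + b), sample(y))
    cross_validated_q2(blocks, y_perm, n_ortho, k_folds,
                       stage_seed(seed, 500L + b), strata, scale)
  }, 0)
  structure(list(observed_q2 = obs, null_q2 = null_q2,
                 p_value = (1 + sum(null_q2 >= obs)) / (1 + n_permutations)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed Q2 = %.3f, p = %.4g (%d permutations)\n",
              x$observed_q2, x$p_value, length(x$null_q2)))
  invisible(x)
}

#' Back-project per-ion loadings from a fitted model
#'
#' The predictive coordinate of ion j in block b is the inner product of its
#' scaled intensity profile with the unit-norm predictive score,
#' `x_j' t_pred / ||t_pred||` — i.e. the covariance of the ion with the
#' predictive score on the scaled-data scale. With unit-variance scaling the
#' largest attainable coordinate is `sqrt(n - 1)`, so coordinates are
#' directly comparable across blocks and to a fixed selection threshold.
#' Orthogonal coordinates are computed the same way against each orthogonal
#' score.
#'
#' @param model a fitted `mbopls`.
#' @param blocks the blocks the model was fitted on (same order).
#' @return data.frame with `ion_id`, `block`, `predictive` and one
#'   `ortho_<i>` column per orthogonal component.
#' @export
back_project_loadings <- function(model, blocks) {
  abort_if(!inherits(model, "mbopls"), "model must be a fitted mbopls object")
  mats <- lapply(blocks, block_matrix)
  abort_if(length(mats) != length(model$block_weights),
           "wrong number of blocks")
  t_hat <- model$t_pred / sqrt(sum(model$t_pred^2))
  To <- model$T_ortho
  out <- lapply(seq_along(mats), function(b) {
    Xs <- apply_scaling(mats[[b]], model$scalings[[b]])
    ids <- colnames(Xs)
    if (is.null(ids)) ids <- sprintf("%s_%04d", model$block_names[b],
                                     seq_len(ncol(Xs)))
    df <- data.frame(ion_id = ids, block = model$block_names[b],
                     predictive = drop(crossprod(Xs, t_hat)),
                     stringsAsFactors = FALSE)
    for (i in seq_len(ncol(To))) {
      to_hat <- To[, i] / sqrt(sum(To[, i]^2))
      df[[paste0("ortho_", i)]] <- drop(crossprod(Xs, to_hat))
    }
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
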