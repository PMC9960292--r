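test_that("block scaling matches its definitions", {
  set.seed(3)
  X <- matrix(rnorm(30, 10, 4), 6, 5)
  uv <- scale_block(X, "uv")
  expect_equal(colMeans(uv$X), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(uv$X, 2, sd), rep(1, 5), tolerance = 1e-12)
  ctr <- scale_block(X, "center")
  expect_equal(scale_block(ctr$X, "center")$X, ctr$X, tolerance = 1e-12)
  # 3x3 hand case: pareto divides by sqrt(sd)
  H <- matrix(c(1, 2, 3, 0, 0, 0, 2, 4, 6), 3, 3)
  par <- scale_block(H, "pareto")
  expect_equal(par$X[, 1], (H[, 1] - 2) / sqrt(1), tolerance = 1e-12)
  expect_equal(par$X[, 3], (H[, 3] - 4) / sqrt(2), tolerance = 1e-12)
  expect_true(par$constant[2])
  expect_equal(par$X[, 2], rep(0, 3))
})

test_that("predictive and orthogonal scores are uncorrelated on every fit", {
  for (s in 1:5) {
    st <- small_study(s)
    y <- study_activity(st)
    m <- fit_consensus_opls(list(st$neg, st$pos), y, n_ortho = 2)
    for (i in seq_len(m$n_ortho)) {
      expect_lt(abs(cor(m$t_pred, m$T_ortho[, i])), 1e-6)
    }
    expect_lte(abs(mean(m$t_pred)), 1e-8)   # scores are centered
  }
})

test_that("with one block and no orthogonal component the fit reduces to PLS1", {
  st <- small_study(12)
  y <- study_activity(st)
  Xs <- scale_block(st$neg, "uv")$X
  m <- fit_consensus_opls(list(Xs), y, n_ortho = 0, scale = "center")
  oracle <- nipals_pls1(Xs, y)
  yhat <- m$t_pred * m$q + m$y_mean
  expect_equal(yhat, oracle$yhat, tolerance = 1e-8)
  # scores proportional (kernel normalization changes the scale only)
  expect_equal(abs(cor(m$t_pred, oracle$t)), 1, tolerance = 1e-10)
})

test_that("duplicating a block gives equal weights and unchanged scores", {
  st <- small_study(13)
  y <- study_activity(st)
  single <- fit_consensus_opls(list(st$neg), y, n_ortho = 1)
  dup <- fit_consensus_opls(list(a = st$neg, b = st$neg), y, n_ortho = 1)
  expect_equal(unname(dup$block_weights), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(dup$t_pred, single$t_pred, tolerance = 1e-8)
  expect_equal(dup$r2y, single$r2y, tolerance = 1e-8)
})

test_that("rotating a block's variable axes leaves the model invariant", {
  st <- small_study(14)
  y <- study_activity(st)
  Xc <- scale_block(st$neg, "center")$X
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(ncol(Xc)^2), ncol(Xc))))
  m1 <- fit_consensus_opls(list(Xc, st$pos$intensities), y,
                           n_ortho = 1, scale = "center")
  m2 <- fit_consensus_opls(list(Xc %*% Q, st$pos$intensities), y,
                           n_ortho = 1, scale = "center")
  expect_equal(m1$t_pred, m2$t_pred, tolerance = 1e-8)
  expect_equal(m1$r2y, m2$r2y, tolerance = 1e-8)
  expect_equal(m1$block_weights, m2$block_weights, tolerance = 1e-8)
})

test_that("the predictive axis orders organs by inhibition and R2Y is high", {
  st <- small_study(15)
  y <- study_activity(st)
  m <- fit_consensus_opls(list(st$neg, st$pos), y, n_ortho = 1)
  expect_gte(m$r2y, 0.7)
  mt <- tapply(m$t_pred, st$design$organ, mean)
  expect_true(mt[["stem_bark"]] > mt[["leaf"]] && mt[["leaf"]] > mt[["fruit"]])
})

test_that("without planted orthogonal structure the orthogonal variance is tiny", {
  # mild slope keeps the exponentiated intensities near-linear in activity,
  # so essentially no response-orthogonal structure exists in X
  st <- simulate_study(generator_config(
    seed = 21, n_ions_neg = 5, n_ions_pos = 5, n_active = 10,
    n_clone_pairs = c(neg = 0, pos = 0), n_subthreshold = c(neg = 0, pos = 0),
    organ_effect_sd = 0, noise_sd_log_intensity = 0.05, effect_size = 1))
  y <- study_activity(st)
  m <- fit_consensus_opls(list(st$neg, st$pos), y, n_ortho = 1)
  expect_lt(unname(m$explained_variance["ortho_1"]), 0.02)
})

test_that("cross-validated Q2 tracks signal strength and respects bounds", {
  st <- small_study(16, noise_sd_log_intensity = 0.05)
  y <- study_activity(st)
  q2 <- cross_validated_q2(list(st$neg, st$pos), y, 1, 7, seed = 2,
                           strata = study_strata(st))
  expect_gt(q2, 0.9)
  # leave-one-out runs and returns a finite value
  loo <- cross_validated_q2(list(st$neg, st$pos), y, 1, k_folds = length(y),
                            seed = 2)
  expect_true(is.finite(loo))
  expect_error(cross_validated_q2(list(st$neg, st$pos), y, 1, k_folds = 1),
               "k_folds")
  expect_error(fit_consensus_opls(list(st$neg), rep(1, 54)), "variance")
})

test_that("permutation null is reproducible and p hits its floor on strong signal", {
  st <- small_study(17)
  y <- study_activity(st)
  p1 <- permutation_test(list(st$neg, st$pos), y, 1, n_permutations = 19,
                         k_folds = 5, seed = 4, strata = study_strata(st))
  p2 <- permutation_test(list(st$neg, st$pos), y, 1, n_permutations = 19,
                         k_folds = 5, seed = 4, strata = study_strata(st))
  expect_identical(p1$null_q2, p2$null_q2)
  expect_equal(p1$p_value, (1 + sum(p1$null_q2 >= p1$observed_q2)) / 20)
  expect_equal(p1$p_value, 1 / 20)   # planted signal beats every permutation
  expect_error(permutation_test(list(st$neg), y, n_permutations = 5), "19")
})

test_that("back-projected loadings behave at their extremes", {
  st <- small_study(18)
  y <- study_activity(st)
  m <- fit_consensus_opls(list(neg = st$neg, pos = st$pos), y, n_ortho = 1)
  ld <- back_project_loadings(m, list(neg = st$neg, pos = st$pos))
  # with unit-variance scaling, coordinate_j = sqrt(n - 1) * cor(x_j, t_pred):
  # an independent identity pinning both the convention and its maximum
  n <- length(y)
  expect_equal(ld$predictive,
               sqrt(n - 1) * as.numeric(cor(cbind(st$neg$intensities,
                                                  st$pos$intensities), m$t_pred)),
               tolerance = 1e-10)
  expect_lte(max(abs(ld$predictive)), sqrt(n - 1) + 1e-10)
  # a column made exactly orthogonal to the fitted score projects to zero;
  # scaling is affine and scores are centered, so the stored per-column
  # scaling constants cannot leak into the inner product
  set.seed(8)
  v <- residuals(lm(rnorm(n) ~ m$t_pred))
  Xmod <- st$neg$intensities
  Xmod[, 1] <- v + 100
  ld2 <- back_project_loadings(m, list(neg = Xmod, pos = st$pos))
  expect_lt(abs(ld2$predictive[1]), 1e-10)
  expect_error(back_project_loadings(list(), list(st$neg)), "mbopls")
})
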