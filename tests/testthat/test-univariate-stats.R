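test_that("Kruskal-Wallis handles complete ties and rejects single groups", {
  r <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Kruskal-Wallis H matches the exact permutation reference on n = 9", {
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  r <- kruskal_wallis(vals, grp)
  # ranks are 1..9 by construction: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  expect_equal(r$statistic, 12 / (9 * 10) * 3 * ((2 - 5)^2 + 0 + (8 - 5)^2))
  # exact permutation p of H (all 1680 equal-size assignments) brackets the
  # chi-square approximation
  perms <- combn(9, 3)
  h_of <- function(assign1, assign2) {
    rk <- rank(vals)
    g <- integer(9); g[assign1] <- 1L; g[assign2] <- 2L; g[g == 0L] <- 3L
    12 / (9 * 10) * sum(tapply(rk, g, function(r0) length(r0) * (mean(r0) - 5)^2))
  }
  hs <- c()
  for (i in seq_len(ncol(perms))) {
    rest <- setdiff(1:9, perms[, i])
    sub <- combn(rest, 3)
    for (j in seq_len(ncol(sub))) hs <- c(hs, h_of(perms[, i], sub[, j]))
  }
  p_exact <- mean(hs >= r$statistic - 1e-12)
  expect_lt(abs(r$p_value - p_exact), 0.03)
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum direction", {
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12) + 1
  kw <- kruskal_wallis(c(x, y), rep(c("a", "b"), each = 12))
  wc <- wilcox.test(x, y, correct = FALSE, exact = FALSE)
  expect_equal(kw$p_value, wc$p.value, tolerance = 1e-10)
})

test_that("pairwise post-hoc applies Bonferroni arithmetic", {
  set.seed(4)
  vals <- c(rnorm(6), rnorm(6) + 3, rnorm(6) + 6)
  grp <- rep(c("a", "b", "c"), each = 6)
  raw <- pairwise_posthoc(vals, grp, adjust = "none")
  adj <- pairwise_posthoc(vals, grp, adjust = "bonferroni")
  expect_equal(adj[upper.tri(adj)], pmin(raw[upper.tri(raw)] * 3, 1))
  expect_true(isSymmetric(adj))
  expect_true(all(is.na(diag(adj))))
})

test_that("Dunn's many-to-one matches hand arithmetic and is label-invariant", {
  vals <- c(0, 0, 0, 100, 100, 100)
  grp <- c("g", "g", "g", "ctrl", "ctrl", "ctrl")
  d <- dunn_many_to_one(vals, grp, "ctrl")
  # mid-ranks 2,2,2 vs 5,5,5; tie correction C = 48/60; z = -3/sqrt(1.8)
  expect_equal(d$z, -3 / sqrt(1.8))
  expect_equal(d$p_adjusted, 2 * pnorm(-3 / sqrt(1.8)))
  # this allocation attains the largest |z| over all 3-vs-3 splits
  zs <- apply(combn(6, 3), 2, function(ix) {
    g <- rep("g", 6); g[ix] <- "ctrl"
    abs(dunn_many_to_one(vals, g, "ctrl")$z)
  })
  expect_equal(max(zs), abs(d$z))
  # control identical to the group: p capped at 1
  d2 <- dunn_many_to_one(c(1, 2, 3, 1, 2, 3), rep(c("ctrl", "g"), each = 3), "ctrl")
  expect_equal(d2$p_adjusted, 1)
  # relabeling non-control groups permutes but does not change p values
  set.seed(9)
  vals3 <- rnorm(12)
  g3 <- rep(c("ctrl", "x", "y", "z"), each = 3)
  g3b <- c("ctrl", "z", "y", "x")[match(g3, c("ctrl", "x", "y", "z"))]
  d3 <- dunn_many_to_one(vals3, g3, "ctrl")
  d3b <- dunn_many_to_one(vals3, g3b, "ctrl")
  expect_equal(sort(d3$p_adjusted), sort(d3b$p_adjusted))
  expect_error(dunn_many_to_one(vals3, g3, "nope"), "not present")
})

test_that("letter display covers the canonical patterns", {
  mk <- function(p, groups) {
    m <- matrix(1, length(groups), length(groups), dimnames = list(groups, groups))
    for (r in seq_len(nrow(p))) m[p[r, 1], p[r, 2]] <- m[p[r, 2], p[r, 1]] <- 0.001
    m
  }
  g3 <- c("A", "B", "C")
  all_sig <- mk(cbind(c("A", "A", "B"), c("B", "C", "C")), g3)
  expect_equal(unname(compact_letter_display(all_sig, 0.05)), c("a", "b", "c"))
  none_sig <- mk(matrix(character(), 0, 2), g3)
  expect_equal(unname(compact_letter_display(none_sig, 0.05)), c("a", "a", "a"))
  # chain A~B, B~C, A!=C -> a, ab, b
  chain <- mk(cbind("A", "C"), g3)
  expect_equal(unname(compact_letter_display(chain, 0.05)), c("a", "ab", "b"))
  # medians reorder lettering
  med <- c(A = 1, B = 2, C = 3)
  lett <- compact_letter_display(chain, 0.05, med)
  expect_equal(names(lett), c("C", "B", "A"))
  expect_error(compact_letter_display(matrix(c(1, 0.2, 0.6, 1), 2, 2,
                                             dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("letter display is consistent with its p table for every pattern", {
  for (k in 3:5) {
    n_pairs <- k * (k - 1) / 2
    groups <- LETTERS[1:k]
    pair_idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    for (pattern in 0:(2^n_pairs - 1)) {
      sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
      bits <- bitwAnd(pattern, 2^(seq_len(n_pairs) - 1)) > 0
      for (e in seq_len(n_pairs)) {
        sig[pair_idx[e, 1], pair_idx[e, 2]] <- bits[e]
        sig[pair_idx[e, 2], pair_idx[e, 1]] <- bits[e]
      }
      pm <- ifelse(sig, 0.01, 0.5)
      dimnames(pm) <- dimnames(sig)
      lett <- compact_letter_display(pm, 0.05)
      share <- letter_sharing(lett[groups])
      # consistency: share a letter iff not significantly different
      expect_identical(unname(share[upper.tri(share)]),
                       unname(!sig[upper.tri(sig)]))
      expect_true(all(nchar(lett) >= 1))
    }
  }
})

test_that("shrinking alpha never separates groups that were merged... and vice versa", {
  # monotonicity: smaller alpha means fewer significant pairs, so groups can
  # only merge, never split
  set.seed(5)
  vals <- c(rnorm(9), rnorm(9) + 1, rnorm(9) + 2, rnorm(9) + 4)
  grp <- rep(c("a", "b", "c", "d"), each = 9)
  pm <- pairwise_posthoc(vals, grp)
  for (alphas in list(c(0.05, 0.01), c(0.2, 0.05))) {
    l_hi <- compact_letter_display(pm, alphas[1])
    l_lo <- compact_letter_display(pm, alphas[2])
    sh_hi <- letter_sharing(l_hi)
    sh_lo <- letter_sharing(l_lo)
    expect_true(all(sh_lo[sh_hi]))   # pairs sharing at high alpha still share
  }
})
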