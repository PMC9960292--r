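make_block <- function(intens, rt, ids = sprintf("neg_%04d", seq_along(rt)),
                       mode = "neg") {
  feature_block(intens,
                data.frame(ion_id = ids, mode = rep(mode, length(rt)),
                           mz = seq_along(rt) + 100,
                           rt = rt, stringsAsFactors = FALSE),
                sample_ids = rownames(intens) %||% paste0("s", seq_len(nrow(intens))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("retention-time window is closed on both ends", {
  X <- matrix(1, 3, 4)
  b <- make_block(X, rt = c(0.4, 0.5, 5.0, 5.1))
  kept <- restrict_rt(b, filter_config())
  expect_equal(kept$ions$rt, c(0.5, 5.0))
  # identity when everything is inside; empty in, empty out
  b2 <- make_block(matrix(1, 3, 2), rt = c(1, 2))
  expect_identical(restrict_rt(b2)$ions, b2$ions)
  b0 <- make_block(matrix(1, 3, 0), rt = numeric())
  expect_equal(ncol(restrict_rt(b0)$intensities), 0)
})

test_that("intensity filter keeps ions above 2000 in at least one organ, strictly", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     organ = rep(c("leaf", "stem_bark", "fruit"), each = 2),
                     site = rep(c("littoral", "mountain"), 3))
  X <- cbind(ion_a = c(2500, 2500, 50, 50, 50, 50),     # leaf mean 2500 -> kept
             ion_b = rep(1999, 6),                      # all means 1999 -> dropped
             ion_c = rep(2000, 6),                      # boundary: strict > -> dropped
             ion_d = c(10, 10, 10, 10, 3000, 1500))     # fruit mean 2250 -> kept
  b <- make_block(X, rt = rep(1, 4), ids = colnames(X))
  kept <- filter_by_intensity(b, meta, filter_config())
  expect_equal(kept$ions$ion_id, c("ion_a", "ion_d"))
  meta_bad <- meta; meta_bad$organ[1] <- "root"
  expect_error(filter_by_intensity(b, meta_bad, filter_config()), "root")
})

test_that("intensity filter agrees with hand-computed means on a toy table", {
  meta <- data.frame(sample_id = paste0("s", 1:3),
                     organ = c("leaf", "stem_bark", "fruit"),
                     site = c("littoral", "littoral", "littoral"))
  X <- cbind(a = c(6001, 0, 0), b = c(2000, 2000, 2000), c = c(0, 0, 2001))
  b <- make_block(X, rt = rep(1, 3), ids = colnames(X))
  kept <- filter_by_intensity(b, meta, filter_config())$ions$ion_id
  expect_equal(kept, c("a", "c"))
})

test_that("correlation pruning honors the r and RT boundaries", {
  set.seed(1)
  base <- rnorm(20)
  # construct a pair with r exactly 0.80 at the same RT
  noise <- rnorm(20)
  noise <- residuals(lm(noise ~ base))
  x1 <- base / sd(base)
  x2 <- 0.8 * x1 + sqrt(1 - 0.8^2) * noise / sd(noise)
  X <- cbind(a = 100 + 10 * x1, b = 120 + 10 * x2)
  rr <- cor(X[, 1], X[, 2])
  expect_equal(rr, 0.8, tolerance = 1e-9)
  b1 <- make_block(X, rt = c(1, 1), ids = colnames(X))
  # threshold equal to the observed r: >= is inclusive, one ion removed
  pr <- prune_correlated(b1, filter_config(r_threshold = rr))
  expect_equal(nrow(pr$removal_log), 1)
  # threshold infinitesimally above r: both kept
  pr_above <- prune_correlated(b1, filter_config(r_threshold = rr + 1e-9))
  expect_equal(nrow(pr_above$removal_log), 0)
  # same correlation, retention times further apart than the tolerance
  b2 <- make_block(X, rt = c(1, 1.05), ids = colnames(X))
  pr2 <- prune_correlated(b2, filter_config())
  expect_equal(nrow(pr2$removal_log), 0)
  # constant ion: correlation treated as 0, noted, not an error
  X3 <- cbind(X, c = rep(5, 20))
  b3 <- make_block(X3, rt = c(1, 1, 1), ids = colnames(X3))
  pr3 <- prune_correlated(b3, filter_config())
  expect_match(pr3$notes, "constant")
  expect_false("c" %in% pr3$removal_log$removed)
})

test_that("pruning matches the brute-force oracle on random small instances", {
  for (s in 1:12) {
    set.seed(s)
    n_ion <- sample(10:50, 1)
    n_s <- 12
    base <- matrix(rnorm(n_s * 4), n_s, 4)
    mix <- matrix(runif(4 * n_ion), 4, n_ion)
    X <- pmax(base %*% mix + 0.3 * matrix(rnorm(n_s * n_ion), n_s, n_ion), 0) * 100
    rt <- round(runif(n_ion, 0.5, 1.0), 2)   # coarse grid forces co-elution
    b <- make_block(X, rt = rt)
    cfg <- filter_config(rt_tolerance = 0.011)
    got <- prune_correlated(b, cfg)$block$ions$ion_id
    expect_identical(got, intersect(b$ions$ion_id, brute_force_prune(b, cfg)))
  }
})

test_that("planted clone pairs lose exactly the clone, keeping the parent", {
  st <- small_study(6)
  for (mode in c("neg", "pos")) {
    blk <- restrict_rt(st[[mode]], filter_config())
    pr <- prune_correlated(blk, filter_config())
    pairs <- st$ground_truth$redundant_pairs
    pairs <- pairs[pairs$mode == mode & pairs$clone %in% blk$ions$ion_id, ]
    expect_true(all(pairs$clone %in% pr$removal_log$removed))
    expect_true(all(pairs$parent %in% pr$block$ions$ion_id))
  }
})

test_that("the full chain is idempotent and stage counts are recorded", {
  st <- small_study(2)
  f1 <- assemble_blocks(st$neg, st$pos, st$design)
  f2 <- assemble_blocks(f1$neg, f1$pos, st$design)
  expect_identical(f1$neg$ions, f2$neg$ions)
  expect_identical(f1$pos$intensities, f2$pos$intensities)
  expect_equal(f1$counts$stage, c("initial", "rt_window", "intensity", "correlation"))
  expect_true(all(diff(f1$counts$neg) <= 0))
  # misaligned sample order is an alignment error
  neg_bad <- st$neg
  neg_bad$sample_ids <- rev(neg_bad$sample_ids)
  expect_error(assemble_blocks(neg_bad, st$pos, st$design), "order")
})

test_that("raising the intensity threshold never keeps more ions", {
  st <- small_study(9)
  counts <- vapply(c(500, 2000, 8000, 32000), function(thr) {
    cfg <- filter_config(intensity_threshold = thr)
    ncol(filter_by_intensity(st$neg, st$design, cfg)$intensities)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("swapping intensity-filter and pruning order is audited", {
  st <- small_study(10)
  cfg <- filter_config()
  b <- restrict_rt(st$neg, cfg)
  std <- prune_correlated(filter_by_intensity(b, st$design, cfg), cfg)$block
  swapped <- filter_by_intensity(prune_correlated(b, cfg)$block, st$design, cfg)
  audit <- list(only_standard = setdiff(std$ions$ion_id, swapped$ions$ion_id),
                only_swapped = setdiff(swapped$ions$ion_id, std$ions$ion_id))
  # both orders must produce subsets of the RT-restricted ions; the audit
  # reports any divergence rather than hiding it
  expect_true(all(std$ions$ion_id %in% b$ions$ion_id))
  expect_true(all(swapped$ions$ion_id %in% b$ions$ion_id))
  expect_type(audit$only_standard, "character")
  expect_type(audit$only_swapped, "character")
})
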