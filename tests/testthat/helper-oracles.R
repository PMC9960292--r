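# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by a different route than the package implementation.

# Textbook single-component NIPALS PLS1 on an already-scaled matrix.
nipals_pls1 <- function(Xs, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xs %*% w)
  q <- sum(t * yc) / sum(t^2)
  list(t = t, q = q, yhat = t * q + mean(y))
}

# Brute-force correlation pruning: transitive closures computed by boolean
# matrix fixed point rather than graph traversal.
brute_force_prune <- function(block, config) {
  p <- ncol(block$intensities)
  if (p < 2) return(block$ions$ion_id)
  closure <- function(adj) {
    repeat {
      nxt <- adj | ((adj %*% adj) > 0)
      if (identical(nxt, adj)) return(adj)
      adj <- nxt
    }
  }
  rt <- block$ions$rt
  rt_adj <- abs(outer(rt, rt, "-")) <= config$rt_tolerance
  rt_adj <- closure(rt_adj)
  X <- if (config$cor_on_log) log1p(block$intensities) else block$intensities
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  r_eff <- if (config$use_abs_r) abs(cm) else cm
  adj <- (r_eff >= config$r_threshold) & rt_adj
  diag(adj) <- TRUE
  adj <- closure(adj)
  keep <- rep(TRUE, p)
  med <- apply(block$intensities, 2, stats::median)
  ids <- block$ions$ion_id
  seen <- rep(FALSE, p)
  for (i in seq_len(p)) {
    if (seen[i]) next
    members <- which(adj[i, ])
    seen[members] <- TRUE
    if (length(members) < 2) next
    rep_ion <- members[order(-med[members], ids[members])][1]
    keep[setdiff(members, rep_ion)] <- FALSE
  }
  ids[keep]
}

# Brute-force compact-letter-display oracle for <= 5 groups: enumerates all
# cliques of the compatibility graph and finds a minimum edge-and-vertex
# clique cover by exhaustive search.
brute_force_cld <- function(sig, k) {
  verts <- seq_len(k)
  subsets <- lapply(seq_len(2^k - 1), function(m) verts[bitwAnd(m, 2^(verts - 1)) > 0])
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    all(!sig[t(utils::combn(s, 2))])
  }, TRUE)
  cliques <- subsets[is_clique]
  need_edges <- which(upper.tri(sig) & !sig, arr.ind = TRUE)
  covers_all <- function(sel) {
    cl <- cliques[sel]
    if (!all(verts %in% unlist(cl))) return(FALSE)
    if (nrow(need_edges) == 0) return(TRUE)
    all(apply(need_edges, 1, function(e)
      any(vapply(cl, function(s) all(e %in% s), TRUE))))
  }
  for (m in seq_len(length(cliques))) {
    combos <- utils::combn(length(cliques), m)
    for (cc in seq_len(ncol(combos))) {
      if (covers_all(combos[, cc])) return(list(size = m, cliques = cliques[combos[, cc]]))
    }
  }
  stop("no cover found")
}

# Sharing relation implied by a letter assignment.
letter_sharing <- function(letters_vec) {
  k <- length(letters_vec)
  out <- matrix(FALSE, k, k, dimnames = list(names(letters_vec), names(letters_vec)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    li <- strsplit(letters_vec[i], "")[[1]]
    lj <- strsplit(letters_vec[j], "")[[1]]
    out[i, j] <- length(intersect(li, lj)) > 0
  }
  out
}

# A small, fast synthetic scenario used by several module tests.
small_study <- function(seed = 1, ...) {
  simulate_study(generator_config(
    seed = seed, n_ions_neg = 40, n_ions_pos = 30,
    n_clone_pairs = c(neg = 3, pos = 2), n_subthreshold = c(neg = 4, pos = 3),
    ...))
}

study_activity <- function(study, ref = 10) {
  act <- summarize_activity(study$plate, ref)
  act$inhibition_percent[match(study$design$sample_id, act$sample_id)]
}

study_strata <- function(study) paste(study$design$organ, study$design$site)
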