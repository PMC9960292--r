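#' Configuration of the feature-table filters
#'
#' Holds the constants of the three-stage filter chain applied to each
#' ionization-mode block: retention-time window (0.5-5 min), organ-wise mean
#' peak-area threshold (> 2000 in at least one organ), and pruning of
#' co-eluting ions correlated at r >= 0.80.
#'
#' @param rt_min,rt_max closed retention-time window, minutes.
#' @param intensity_threshold peak-area threshold (strict `>`).
#' @param r_threshold Pearson correlation threshold (inclusive `>=`).
#' @param rt_tolerance maximum retention-time difference (minutes) for two
#'   ions to count as co-eluting; groups are formed by transitive closure.
#' @param condition grouping used by the intensity filter: `"organ"` pools
#'   the two sites within each organ (default reading), `"organ_site"` uses
#'   the six cells.
#' @param intensity_stat group statistic compared to the threshold.
#' @param cor_on_log compute pruning correlations on log1p intensities
#'   instead of raw peak areas.
#' @param use_abs_r prune on `|r|` rather than the signed coefficient.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(rt_min = 0.5, rt_max = 5, intensity_threshold = 2000,
                          r_threshold = 0.80, rt_tolerance = 0.02,
                          condition = c("organ", "organ_site"),
                          intensity_stat = c("mean", "max"),
                          cor_on_log = FALSE, use_abs_r = FALSE) {
  condition <- match.arg(condition)
  intensity_stat <- match.arg(intensity_stat)
  abort_if(rt_min >= rt_max, "rt_min must be < rt_max")
  abort_if(r_threshold <= 0 || r_threshold > 1, "r_threshold must be in (0, 1]")
  abort_if(intensity_threshold < 0, "intensity_threshold must be >= 0")
  abort_if(rt_tolerance < 0, "rt_tolerance must be >= 0")
  structure(list(rt_min = rt_min, rt_max = rt_max,
                 intensity_threshold = intensity_threshold,
                 r_threshold = r_threshold, rt_tolerance = rt_tolerance,
                 condition = condition, intensity_stat = intensity_stat,
                 cor_on_log = cor_on_log, use_abs_r = use_abs_r),
            class = "filter_config")
}

#' Keep ions inside the retention-time window
#'
#' @param block a [feature_block()].
#' @param config a [filter_config()]; the window is closed on both ends.
#' @return The filtered block, ion order preserved.
#' @export
restrict_rt <- function(block, config = filter_config()) {
  keep <- block$ions$rt >= config$rt_min & block$ions$rt <= config$rt_max
  subset_ions(block, keep)
}

#' Keep ions exceeding the intensity threshold in at least one condition
#'
#' An ion is retained iff its group-wise mean (or max) peak area is strictly
#' greater than the threshold in at least one condition group — by default
#' the three organs, pooling sites.
#'
#' @param block a [feature_block()].
#' @param metadata design table aligned row-for-row with the block.
#' @param config a [filter_config()].
#' @return The filtered block.
#' @export
filter_by_intensity <- function(block, metadata, config = filter_config()) {
  abort_if(nrow(metadata) != nrow(block$intensities),
           "metadata and block disagree on sample count")
  abort_if(!all(metadata$organ %in% ORGANS),
           paste("unknown organ label(s):",
                 paste(setdiff(unique(metadata$organ), ORGANS), collapse = ", ")))
  grp <- switch(config$condition,
                organ = metadata$organ,
                organ_site = organ_site_key(metadata$organ, metadata$site))
  stat <- switch(config$intensity_stat, mean = mean, max = max)
  gstat <- rowsum(block$intensities, grp)   # sums per group
  if (config$intensity_stat == "mean") {
    gstat <- gstat / as.vector(table(grp)[rownames(gstat)])
  } else {
    gstat <- apply(block$intensities, 2, function(col) tapply(col, grp, max))
  }
  keep <- apply(gstat, 2, max) > config$intensity_threshold
  subset_ions(block, keep)
}

# Transitive-closure retention-time groups: sort by RT and chain ions whose
# adjacent gaps are <= tolerance.
rt_groups <- function(rt, tol) {
  ord <- order(rt)
  g <- integer(length(rt))
  gid <- 1L
  g[ord[1]] <- gid
  if (length(rt) > 1) {
    for (k in 2:length(ord)) {
      if (rt[ord[k]] - rt[ord[k - 1]] > tol) gid <- gid + 1L
      g[ord[k]] <- gid
    }
  }
  g
}

#' Prune correlated co-eluting ions
#'
#' Within each group of ions at the same retention time (pairwise differences
#' within `rt_tolerance`, closed transitively), ions connected by Pearson
#' `r >= r_threshold` form redundancy clusters; each cluster keeps exactly
#' one representative — the ion with the highest median peak area (ties
#' broken by lexicographically smallest ion id) — and the rest are removed.
#' Constant-intensity ions get correlation 0 by convention (noted, not an
#' error).
#'
#' @param block a [feature_block()] with at least 2 samples.
#' @param config a [filter_config()].
#' @return list with `block` (pruned), `removal_log` (data.frame `removed`,
#'   `representative`, `r`), `notes` (character, e.g. constant ions).
#' @export
prune_correlated <- function(block, config = filter_config()) {
  n_s <- nrow(block$intensities)
  abort_if(n_s < 2, "correlation pruning needs >= 2 samples")
  p <- ncol(block$intensities)
  removal_log <- data.frame(removed = character(), representative = character(),
                            r = numeric(), stringsAsFactors = FALSE)
  notes <- character()
  if (p < 2) return(list(block = block, removal_log = removal_log, notes = notes))

  X <- block$intensities
  if (config$cor_on_log) X <- log1p(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    notes <- c(notes, sprintf(
      "constant-intensity ion(s) treated as uncorrelated: %s",
      paste(block$ions$ion_id[sds == 0], collapse = ", ")))
  }
  groups <- rt_groups(block$ions$rt, config$rt_tolerance)
  drop <- logical(p)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    cm <- suppressWarnings(stats::cor(X[, idx, drop = FALSE]))
    cm[!is.finite(cm)] <- 0            # constant ions -> r = 0
    r_eff <- if (config$use_abs_r) abs(cm) else cm
    adj <- r_eff >= config$r_threshold
    diag(adj) <- FALSE
    # connected components of the redundancy graph
    comp <- rep(NA_integer_, length(idx))
    cid <- 0L
    for (s in seq_along(idx)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & is.na(comp))
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    for (cc in unique(comp)) {
      members <- idx[comp == cc]
      if (length(members) < 2) next
      med <- apply(block$intensities[, members, drop = FALSE], 2, stats::median)
      ids <- block$ions$ion_id[members]
      rep_local <- members[order(-med, ids)][1]
      losers <- setdiff(members, rep_local)
      drop[losers] <- TRUE
      li <- match(losers, idx); ri <- match(rep_local, idx)
      removal_log <- rbind(removal_log, data.frame(
        removed = block$ions$ion_id[losers],
        representative = block$ions$ion_id[rep_local],
        r = cm[cbind(li, rep(ri, length(li)))], stringsAsFactors = FALSE))
    }
  }
  list(block = subset_ions(block, !drop), removal_log = removal_log,
       notes = notes)
}

#' Run the full filter chain on both ionization-mode blocks
#'
#' Applies retention-time restriction, the intensity threshold, and
#' correlation pruning — in that order — to the negative- and positive-mode
#' blocks independently, recording ion counts after each stage.
#'
#' @param neg,pos [feature_block()]s sharing the metadata's sample order.
#' @param metadata design table (`sample_id`, `organ`, `site`, ...).
#' @param config a [filter_config()].
#' @return list with filtered `neg` and `pos`, a `counts` data.frame
#'   (stage x block), and the per-block `removal_logs`.
#' @export
assemble_blocks <- function(neg, pos, metadata, config = filter_config()) {
  for (b in list(neg, pos)) {
    abort_if(!identical(b$sample_ids, as.character(metadata$sample_id)),
             "block sample order does not match the metadata")
  }
  chain <- function(block) {
    counts <- c(initial = ncol(block$intensities))
    block <- restrict_rt(block, config)
    counts["rt_window"] <- ncol(block$intensities)
    block <- filter_by_intensity(block, metadata, config)
    counts["intensity"] <- ncol(block$intensities)
    pr <- prune_correlated(block, config)
    counts["correlation"] <- ncol(pr$block$intensities)
    list(block = pr$block, counts = counts, removal_log = pr$removal_log)
  }
  rn <- chain(neg)
  rp <- chain(pos)
  abort_if(ncol(rn$block$intensities) == 0 || ncol(rp$block$intensities) == 0,
           "a block has no ions left after filtering")
  counts <- data.frame(stage = names(rn$counts), neg = unname(rn$counts),
                       pos = unname(rp$counts), stringsAsFactors = FALSE)
  list(neg = rn$block, pos = rp$block, counts = counts,
       removal_logs = list(neg = rn$removal_log, pos = rp$removal_log))
}
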