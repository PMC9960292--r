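#' Select bioactivity-associated ions from predictive loadings
#'
#' One-sided selection of ions whose predictive coordinate exceeds the
#' threshold. Because the predictive score is oriented to correlate
#' positively with inhibition at fit time, large positive coordinates always
#' mean "more inhibitory", so the selection is stable under sign flips of
#' the response. Ranks are dense, descending in coordinate, ties broken by
#' ion id.
#'
#' @param loadings per-ion loading table from [back_project_loadings()].
#' @param threshold selection cut on the predictive coordinate (strict `>`).
#'   The historical default of 5 assumes unit-variance scaling, where the
#'   maximum attainable coordinate is `sqrt(n - 1)`.
#' @return list of class `selection_result`: `table` (with `rank` and
#'   `selected` columns), `threshold`, `selected_ids` (ordered by rank).
#' @export
select_active_ions <- function(loadings, threshold = 5) {
  abort_if(!is.data.frame(loadings) || nrow(loadings) == 0,
           "loading table must be non-empty")
  abort_if(!all(c("ion_id", "predictive") %in% names(loadings)),
           "loading table needs `ion_id` and `predictive` columns")
  ord <- order(-loadings$predictive, loadings$ion_id)
  tab <- loadings[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$selected <- tab$predictive > threshold
  rownames(tab) <- NULL
  structure(list(table = tab, threshold = threshold,
                 selected_ids = tab$ion_id[tab$selected]),
            class = "selection_result")
}

#' Percentile-based selection threshold
#'
#' Alternative to the fixed cut: the coordinate value at a high percentile
#' of the predictive-loading distribution (default: top 2%).
#'
#' @param loadings per-ion loading table.
#' @param prob percentile (default 0.98).
#' @return threshold value usable with [select_active_ions()].
#' @export
threshold_percentile <- function(loadings, prob = 0.98) {
  unname(stats::quantile(loadings$predictive, prob, type = 7))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d ions above coordinate %g\n",
              length(x$selected_ids), nrow(x$table), x$threshold))
  if (length(x$selected_ids))
    cat("  ", paste(utils::head(x$selected_ids, 12), collapse = ", "),
        if (length(x$selected_ids) > 12) "..." else "", "\n")
  invisible(x)
}

#' Group-wise mean intensities of selected ions
#'
#' Reports the mean peak area of each selected ion in every organ x site
#' cell (or organ group) together with the cell where it is most intense —
#' the descriptive counterpart of "which extracts concentrate the candidate
#' inhibitors".
#'
#' @param selected_ids character vector of ion ids present in `block`.
#' @param block a [feature_block()].
#' @param metadata design table aligned with the block rows.
#' @param by `"organ_site"` (default) or `"organ"`.
#' @return data.frame: one row per ion, one column per group mean, plus
#'   `max_group`.
#' @export
enrichment_by_group <- function(selected_ids, block, metadata,
                                by = c("organ_site", "organ")) {
  by <- match.arg(by)
  missing <- setdiff(selected_ids, block$ions$ion_id)
  abort_if(length(missing) > 0,
           paste("ion(s) not in block:", paste(missing, collapse = ", ")))
  grp <- if (by == "organ") metadata$organ else
    organ_site_key(metadata$organ, metadata$site)
  idx <- match(selected_ids, block$ions$ion_id)
  X <- block$intensities[, idx, drop = FALSE]
  means <- rowsum(X, grp) / as.vector(table(grp)[sort(unique(grp))])
  means <- t(means)
  out <- data.frame(ion_id = selected_ids, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(means))
  out$max_group <- colnames(means)[max.col(means, ties.method = "first")]
  rownames(out) <- NULL
  out
}
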