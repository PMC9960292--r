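#' Construct a feature block
#'
#' A feature block couples a samples-by-ions peak-area matrix from one
#' ionization mode with the per-ion annotation (mass-to-charge ratio and
#' retention time) needed for filtering.
#'
#' @param intensities numeric matrix, rows = samples, columns = ions; all
#'   entries must be non-negative peak areas.
#' @param ions data.frame with columns `ion_id`, `mode` (`"neg"` or `"pos"`),
#'   `mz` (Da) and `rt` (minutes); one row per column of `intensities`.
#' @param sample_ids character vector naming the rows of `intensities`.
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(intensities, ions, sample_ids = rownames(intensities)) {
  intensities <- as.matrix(intensities)
  abort_if(!is.numeric(intensities), "`intensities` must be a numeric matrix")
  abort_if(any(intensities < 0), "peak areas must be non-negative")
  abort_if(!is.data.frame(ions), "`ions` must be a data.frame")
  needed <- c("ion_id", "mode", "mz", "rt")
  abort_if(!all(needed %in% names(ions)),
           paste("`ions` must have columns", paste(needed, collapse = ", ")))
  abort_if(nrow(ions) != ncol(intensities),
           "ion table and intensity matrix disagree on ion count")
  abort_if(anyDuplicated(ions$ion_id) > 0, "ion_id must be unique within a block")
  abort_if(is.null(sample_ids) || length(sample_ids) != nrow(intensities),
           "`sample_ids` must name every row")
  ions$ion_id <- as.character(ions$ion_id)
  rownames(intensities) <- sample_ids
  colnames(intensities) <- ions$ion_id
  rownames(ions) <- NULL
  structure(list(intensities = intensities, ions = ions,
                 sample_ids = as.character(sample_ids)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %d samples x %d ions (%s mode), RT %.2f-%.2f min\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(unique(x$ions$mode), collapse = "/"),
              if (nrow(x$ions)) min(x$ions$rt) else NA_real_,
              if (nrow(x$ions)) max(x$ions$rt) else NA_real_))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$intensities)

# Extract the intensity matrix from either a feature_block or a plain matrix.
block_matrix <- function(x) {
  if (inherits(x, "feature_block")) x$intensities else as.matrix(x)
}

# Subset a feature block by ion index (keeps order) or sample index.
subset_ions <- function(block, keep) {
  feature_block(block$intensities[, keep, drop = FALSE],
                block$ions[keep, , drop = FALSE],
                block$sample_ids)
}
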