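# Plain-text readers/writers for the pipeline's tabular artifacts.

#' Write a feature block as CSV
#'
#' Layout: header row of ion ids, then two annotation rows labelled `mz` and
#' `rt` in the first column, then one row per sample of peak areas.
#'
#' @param block a [feature_block()].
#' @param path output file.
#' @export
write_feature_block_csv <- function(block, path) {
  hdr <- c("sample_id", block$ions$ion_id)
  mzrow <- c("mz", format(block$ions$mz, digits = 10, trim = TRUE))
  rtrow <- c("rt", format(block$ions$rt, digits = 10, trim = TRUE))
  body <- cbind(block$sample_ids,
                format(block$intensities, digits = 10, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(paste(mzrow, collapse = ","), con)
  writeLines(paste(rtrow, collapse = ","), con)
  apply(body, 1, function(r) writeLines(paste(r, collapse = ","), con))
  invisible(path)
}

#' Read a feature block CSV
#'
#' @param path file written by [write_feature_block_csv()].
#' @param mode ionization mode label for the ion table.
#' @return a [feature_block()].
#' @export
read_feature_block_csv <- function(path, mode) {
  abort_if(!file.exists(path), sprintf("block file not found: %s", path))
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- names(raw)[-1]
  mz <- as.numeric(raw[raw[[1]] == "mz", -1])
  rt <- as.numeric(raw[raw[[1]] == "rt", -1])
  body <- raw[!(raw[[1]] %in% c("mz", "rt")), , drop = FALSE]
  m <- as.matrix(body[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  feature_block(m, data.frame(ion_id = ids, mode = mode, mz = mz, rt = rt,
                              stringsAsFactors = FALSE),
                sample_ids = body[[1]])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The file may override any field of [generator_config()] (section
#' `generator`), [filter_config()] (section `filter`), and the `model`,
#' `selection` and `stats` sections of [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  abort_if(!file.exists(path), sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_cfg <- function(base, over) {
    for (nm in names(over)) base[[nm]] <- over[[nm]]
    base
  }
  if (!is.null(user$generator)) {
    gen <- user$generator
    if (!is.null(gen$organ_site_mean_inhibition))
      gen$organ_site_mean_inhibition <- unlist(gen$organ_site_mean_inhibition)
    cfg$generator <- do.call(generator_config,
                             merge_cfg(unclass(cfg$generator), gen))
  }
  if (!is.null(user$filter))
    cfg$filter <- do.call(filter_config,
                          merge_cfg(unclass(cfg$filter), user$filter))
  for (sec in c("model", "selection", "stats"))
    if (!is.null(user[[sec]])) cfg[[sec]] <- merge_cfg(cfg[[sec]], user[[sec]])
  cfg
}
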