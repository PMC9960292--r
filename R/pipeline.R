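#' Default end-to-end pipeline configuration
#'
#' One section per stage: `generator` ([generator_config()]), `filter`
#' ([filter_config()]), `model` (components, scaling, cross-validation folds,
#' permutations), `selection` (loading-coordinate threshold) and `stats`
#' (significance level, control label).
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(generator = generator_config(),
       filter = filter_config(),
       model = list(n_ortho = 1, scale = "uv", cv_folds = 7,
                    n_permutations = 99),
       selection = list(threshold = 5),
       stats = list(alpha = 0.05, control_label = "acarbose",
                    reference_concentration = 10))
}

# Named vectors must become JSON objects (not arrays) so the manifest config
# reproduces the run when read back.
generator_config_json <- function(gen) {
  g <- unclass(gen)
  for (f in c("organ_site_mean_inhibition", "n_clone_pairs", "n_subthreshold"))
    g[[f]] <- as.list(g[[f]])
  g
}

#' Run the complete simulated-study analysis
#'
#' Orchestrates simulate -> assay summary -> feature filtering -> consensus
#' OPLS (with cross-validated Q2 and permutation test) -> loading-based ion
#' selection -> group-wise enrichment -> nonparametric statistics, writing
#' every stage artifact plus a manifest of checksums, counts and metrics to
#' `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param config pipeline configuration list (see
#'   [default_pipeline_config()]) or path to a YAML file.
#' @param seed master seed; overrides the generator seed in `config`.
#' @param n_permutations override of the permutation count (`NULL`: use the
#'   config value; `0` skips the permutation test).
#' @return the run manifest (invisibly), also written as `manifest.json`.
#' @export
run_pipeline <- function(out_dir, config = default_pipeline_config(),
                         seed = NULL, n_permutations = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  gen <- config$generator
  if (!is.null(seed)) {
    gen$seed <- as.integer(seed)
    gen <- do.call(generator_config, unclass(gen))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files[[name]] <<- path
    path
  }

  # --- simulate -------------------------------------------------------------
  study <- simulate_study(gen)
  emit("metadata.tsv", function(p) write_tsv(study$design, p))
  emit("block_neg.csv", function(p) write_feature_block_csv(study$neg, p))
  emit("block_pos.csv", function(p) write_feature_block_csv(study$pos, p))
  emit("assay_plate.csv", function(p)
    utils::write.csv(study$plate, p, row.names = FALSE, quote = FALSE))
  emit("ground_truth.json", function(p)
    jsonlite::write_json(study$ground_truth[c("latent_activity",
                                              "active_ion_ids", "effect_sizes",
                                              "subthreshold_ion_ids")],
                         p, auto_unbox = FALSE, digits = NA, pretty = TRUE))

  # --- assay ----------------------------------------------------------------
  activity <- summarize_activity(study$plate,
                                 config$stats$reference_concentration)
  activity <- activity[match(study$design$sample_id, activity$sample_id), ]
  emit("activity.tsv", function(p) write_tsv(activity, p))

  # --- feature filtering ----------------------------------------------------
  filt <- assemble_blocks(study$neg, study$pos, study$design, config$filter)
  emit("block_neg_filtered.csv", function(p) write_feature_block_csv(filt$neg, p))
  emit("block_pos_filtered.csv", function(p) write_feature_block_csv(filt$pos, p))
  emit("filter_counts.tsv", function(p) write_tsv(filt$counts, p))
  emit("removal_log_neg.tsv", function(p) write_tsv(filt$removal_logs$neg, p))
  emit("removal_log_pos.tsv", function(p) write_tsv(filt$removal_logs$pos, p))

  # --- consensus OPLS -------------------------------------------------------
  blocks <- list(neg = filt$neg, pos = filt$pos)
  y <- activity$inhibition_percent
  strata <- organ_site_key(study$design$organ, study$design$site)
  model <- fit_consensus_opls(blocks, y, n_ortho = config$model$n_ortho,
                              scale = config$model$scale)
  model$q2 <- cross_validated_q2(blocks, y, n_ortho = config$model$n_ortho,
                                 k_folds = config$model$cv_folds,
                                 seed = stage_seed(gen$seed, 10L),
                                 strata = strata, scale = config$model$scale)
  n_perm <- if (is.null(n_permutations)) config$model$n_permutations else
    n_permutations
  perm <- NULL
  if (n_perm > 0) {
    perm <- permutation_test(blocks, y, n_ortho = config$model$n_ortho,
                             n_permutations = n_perm,
                             k_folds = config$model$cv_folds,
                             seed = stage_seed(gen$seed, 11L),
                             strata = strata, scale = config$model$scale)
  }
  scores <- data.frame(sample_id = study$design$sample_id,
                       organ = study$design$organ, site = study$design$site,
                       t_pred = model$t_pred)
  if (model$n_ortho > 0)
    scores <- cbind(scores, stats::setNames(
      as.data.frame(model$T_ortho),
      paste0("t_ortho_", seq_len(model$n_ortho))))
  emit("scores.tsv", function(p) write_tsv(scores, p))
  loadings <- back_project_loadings(model, blocks)
  emit("loadings.tsv", function(p) write_tsv(loadings, p))
  emit("model.json", function(p) jsonlite::write_json(list(
    block_weights = as.list(model$block_weights),
    r2y = model$r2y, q2 = model$q2,
    explained_variance = as.list(model$explained_variance),
    n_ortho = model$n_ortho, converged = model$converged,
    scale = model$scale_method,
    permutation_p = if (is.null(perm)) NULL else perm$p_value,
    seed = gen$seed), p, auto_unbox = TRUE, digits = NA, pretty = TRUE))

  # --- selection & enrichment ----------------------------------------------
  sel <- select_active_ions(loadings, config$selection$threshold)
  emit("selection.tsv", function(p) write_tsv(sel$table, p))
  enr <- list()
  for (b in c("neg", "pos")) {
    ids <- intersect(sel$selected_ids, filt[[b]]$ions$ion_id)
    if (length(ids))
      enr[[b]] <- enrichment_by_group(ids, filt[[b]], study$design)
  }
  enrichment <- if (length(enr)) do.call(rbind, unname(enr)) else
    data.frame(ion_id = character(), max_group = character())
  emit("enrichment.tsv", function(p) write_tsv(enrichment, p))

  # --- univariate statistics ------------------------------------------------
  groups6 <- strata
  kw <- kruskal_wallis(y, groups6)
  pw <- pairwise_posthoc(y, groups6, "bonferroni")
  med <- tapply(y, groups6, stats::median)
  letters6 <- compact_letter_display(pw, config$stats$alpha, med)
  letters_df <- data.frame(group = names(letters6), letters = unname(letters6),
                           median_inhibition = as.numeric(med[names(letters6)]))
  emit("inhibition_letters.tsv", function(p) write_tsv(letters_df, p))
  emit("inhibition_pairwise_p.tsv", function(p)
    write_tsv(data.frame(group = rownames(pw), pw, check.names = FALSE), p))
  rep_inh <- replicate_inhibition(study$plate)
  dunn_vals <- c(rep_inh$inhibition_percent,
                 activity$inhibition_percent)
  dunn_grps <- c(ifelse(rep_inh$role == "positive_control",
                        rep_inh$sample_id, NA),
                 groups6)
  keep <- !is.na(dunn_grps)
  dunn <- dunn_many_to_one(dunn_vals[keep], dunn_grps[keep],
                           config$stats$control_label)
  emit("dunn_vs_control.tsv", function(p) write_tsv(dunn, p))

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    tool = "mbopls",
    version = as.character(utils::packageVersion("mbopls")),
    seed = gen$seed,
    config = list(generator = generator_config_json(gen),
                  filter = unclass(config$filter),
                  model = config$model, selection = config$selection,
                  stats = config$stats),
    checksums = as.list(tools::md5sum(unlist(files))),
    ion_counts = stats::setNames(as.list(filt$counts$neg + filt$counts$pos),
                                 filt$counts$stage),
    ion_counts_per_block = filt$counts,
    metrics = list(
      r2y = model$r2y, q2 = model$q2,
      explained_variance = as.list(model$explained_variance),
      block_weights = as.list(model$block_weights),
      kw_statistic = kw$statistic, kw_p = kw$p_value,
      permutation_p = if (is.null(perm)) NA else perm$p_value,
      n_selected = length(sel$selected_ids)))
  names(manifest$checksums) <- names(files)
  # 17 significant digits: doubles survive the JSON round trip bit-exactly,
  # so the manifest alone reproduces the run
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       force = TRUE)
  invisible(c(manifest, list(
    study = study, activity = activity, filtered = filt, model = model,
    permutation = perm, selection = sel, enrichment = enrichment,
    letters = letters6, pairwise_p = pw, dunn = dunn)))
}
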