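#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the simulated plant-extract study: the balanced
#' 9-tree x 3-organ x 2-site design, organ/site mean inhibition levels, the
#' composition of the two ionization-mode feature blocks (active ions whose
#' log-intensity tracks inhibition, organ-structured inactive ions, redundant
#' co-eluting clones, sub-threshold ions), and the enzyme-assay plate layout.
#'
#' Default cell means reproduce the study conditions the generator emulates:
#' stem bark 84.7 (littoral) and 69.9 (mountain), fruit 13.6 at both sites,
#' leaves 49 at both sites, all in percent inhibition at the reference
#' extract concentration of 10 ug/mL.
#'
#' @param n_trees trees per organ x site cell (9 gives the 54-sample design).
#' @param organ_site_mean_inhibition named vector of 6 cell means (percent),
#'   names `organ.site` for organ in leaf/stem_bark/fruit, site in
#'   littoral/mountain.
#' @param activity_sd tree-level standard deviation of inhibition (percent).
#' @param n_ions_neg,n_ions_pos total ions simulated per block before any
#'   filtering.
#' @param n_active number of ions (split between the blocks) whose
#'   log-intensity increases with the latent inhibition.
#' @param effect_size mean log-intensity slope of an active ion against
#'   latent activity scaled to \[0, 1\]; per-ion slopes are jittered
#'   uniformly within +/-20%.
#' @param n_clone_pairs named vector (`neg`, `pos`): redundant clone ions
#'   planted at the exact retention time of a parent ion with correlation
#'   above 0.95, for the correlation-pruning stage.
#' @param n_subthreshold named vector (`neg`, `pos`): ions whose organ-mean
#'   peak areas all stay below the 2000 intensity threshold.
#' @param noise_sd_log_intensity residual standard deviation of log peak area.
#' @param organ_effect_sd standard deviation of the per-ion random organ
#'   effects that give inactive ions activity-independent structure (the
#'   source of the orthogonal component).
#' @param baseline_log_mean,baseline_log_sd distribution of per-ion baseline
#'   log peak areas for regular and active ions.
#' @param subthreshold_log_mean baseline log peak area of sub-threshold ions.
#' @param assay_cv coefficient of variation of replicate plate absorbances.
#' @param a_control absorbance of the negative control at 405 nm.
#' @param concentrations extract concentration series (ug/mL).
#' @param acarbose_concentrations positive-control series (mg/mL).
#' @param acarbose_inhibition_top acarbose percent inhibition at its top dose.
#' @param rt_range retention-time range (minutes) ions are drawn from; wider
#'   than the 0.5-5 min analysis window so the window filter has work to do.
#' @param mz_range mass-to-charge range (Da) for ion annotation.
#' @param seed master seed; stage-specific substreams are derived from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_trees = 9,
    organ_site_mean_inhibition = c(
      leaf.littoral = 49, leaf.mountain = 49,
      stem_bark.littoral = 84.7, stem_bark.mountain = 69.9,
      fruit.littoral = 13.6, fruit.mountain = 13.6),
    activity_sd = 6,
    n_ions_neg = 230, n_ions_pos = 190,
    n_active = 10,
    effect_size = 2,
    n_clone_pairs = c(neg = 10, pos = 10),
    n_subthreshold = c(neg = 15, pos = 12),
    noise_sd_log_intensity = 0.3,
    organ_effect_sd = 0.4,
    baseline_log_mean = log(3e4),
    baseline_log_sd = 0.6,
    subthreshold_log_mean = log(300),
    assay_cv = 0.05,
    a_control = 1.0,
    concentrations = c(0, 2, 4, 6, 8, 10),
    acarbose_concentrations = c(0.2, 0.4, 0.6, 0.8, 1.0),
    acarbose_inhibition_top = 99,
    rt_range = c(0.35, 5.15),
    mz_range = c(100, 1000),
    seed = 1L) {
  cfg <- list(n_trees = n_trees,
              organ_site_mean_inhibition = organ_site_mean_inhibition,
              activity_sd = activity_sd,
              n_ions_neg = n_ions_neg, n_ions_pos = n_ions_pos,
              n_active = n_active, effect_size = effect_size,
              n_clone_pairs = n_clone_pairs, n_subthreshold = n_subthreshold,
              noise_sd_log_intensity = noise_sd_log_intensity,
              organ_effect_sd = organ_effect_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              subthreshold_log_mean = subthreshold_log_mean,
              assay_cv = assay_cv, a_control = a_control,
              concentrations = concentrations,
              acarbose_concentrations = acarbose_concentrations,
              acarbose_inhibition_top = acarbose_inhibition_top,
              rt_range = rt_range, mz_range = mz_range,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  abort_if(cfg$n_trees < 1, "n_trees must be >= 1")
  abort_if(any(cfg$organ_site_mean_inhibition < 0) ||
             any(cfg$organ_site_mean_inhibition > 100),
           "cell mean inhibitions must lie in [0, 100]")
  abort_if(cfg$n_ions_neg < 1 || cfg$n_ions_pos < 1, "ion counts must be positive")
  abort_if(cfg$n_active < 0, "n_active must be >= 0")
  abort_if(cfg$assay_cv < 0, "assay_cv must be non-negative")
  abort_if(cfg$activity_sd < 0, "activity_sd must be non-negative")
  abort_if(cfg$rt_range[1] < 0 || cfg$rt_range[2] > 10 ||
             cfg$rt_range[1] >= cfg$rt_range[2],
           "rt_range must be increasing and within [0, 10]")
  invisible(cfg)
}

#' Generate the balanced sampling design
#'
#' Builds the full crossed design of trees x organs x sites in a fixed,
#' deterministic order (site, then organ, then tree). With `n_trees = 9` this
#' is the 54-extract design (9 trees x 3 organs x 2 sites).
#'
#' @param n_trees trees per organ x site cell.
#' @param seed ignored (the design is deterministic); accepted so all
#'   generator stages share one calling convention.
#' @return data.frame with columns `sample_id`, `tree_id`, `organ`, `site`.
#' @export
generate_design <- function(n_trees = 9, seed = 1L) {
  abort_if(!is_scalar_number(n_trees) || n_trees < 1, "n_trees must be >= 1")
  n_trees <- as.integer(n_trees)
  grid <- expand.grid(tree_id = seq_len(n_trees), organ = ORGANS, site = SITES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$site, SITES), match(grid$organ, ORGANS),
                     grid$tree_id), ]
  data.frame(
    sample_id = sprintf("%s_%s_t%02d", grid$site, grid$organ, grid$tree_id),
    tree_id = grid$tree_id, organ = grid$organ, site = grid$site,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Draw per-sample latent inhibition levels
#'
#' Each sample's latent activity (the true percent inhibition at the
#' reference concentration) is its organ x site cell mean plus tree-level
#' Gaussian noise, clipped to \[0, 100\].
#'
#' @param design output of [generate_design()].
#' @param config a [generator_config()].
#' @return A `ground_truth` list holding `latent_activity`, a named vector
#'   aligned to `design$sample_id`.
#' @export
generate_latent_activity <- function(design, config = generator_config()) {
  keys <- organ_site_key(design$organ, design$site)
  means <- config$organ_site_mean_inhibition[keys]
  abort_if(anyNA(means),
           paste("no mean inhibition configured for cell(s):",
                 paste(unique(keys[is.na(means)]), collapse = ", ")))
  act <- withr::with_seed(stage_seed(config$seed, 1L), {
    means + stats::rnorm(nrow(design), 0, config$activity_sd)
  })
  act <- pmin(pmax(as.numeric(act), 0), 100)
  names(act) <- design$sample_id
  structure(list(latent_activity = act,
                 active_ion_ids = character(), effect_sizes = numeric(),
                 redundant_pairs = data.frame(), subthreshold_ion_ids = character()),
            class = "ground_truth")
}

# Simulate one ionization-mode block. Ion layout: actives first, then regular
# organ-structured ions, then subthreshold ions, then clones of regular ions.
simulate_block <- function(design, activity, mode, n_ions, n_active_block,
                           n_clones, n_subthreshold, config, seed) {
  n_regular <- n_ions - n_active_block - n_clones - n_subthreshold
  abort_if(n_regular < 0 || (n_clones > 0 && n_regular < n_clones),
           sprintf("block %s: too few ions for the requested composition", mode))
  n_s <- nrow(design)
  act01 <- activity[design$sample_id] / 100
  organ_idx <- match(design$organ, ORGANS)

  # organ-mean activity pattern; inactive ions' organ profiles are built
  # orthogonal to it so "activity-independent" holds by construction
  a_pat <- tapply(act01, design$organ, mean)[ORGANS]
  a_pat <- a_pat - mean(a_pat)
  a_norm2 <- sum(a_pat^2)

  withr::with_seed(seed, {
    ids <- sprintf("%s_%04d", mode, seq_len(n_ions))
    rt <- stats::runif(n_ions, config$rt_range[1], config$rt_range[2])
    mz <- stats::runif(n_ions, config$mz_range[1], config$mz_range[2])
    logI <- matrix(NA_real_, n_s, n_ions)

    i_active <- seq_len(n_active_block)
    i_regular <- seq_len(n_regular) + n_active_block
    i_sub <- seq_len(n_subthreshold) + n_active_block + n_regular
    i_clone <- seq_len(n_clones) + n_active_block + n_regular + n_subthreshold
    if (n_subthreshold == 0L) i_sub <- integer()
    if (n_clones == 0L) i_clone <- integer()
    if (n_active_block == 0L) i_active <- integer()

    # actives elute inside the analysis window (as the study's identified
    # bioactive metabolites do), so the RT filter never discards planted signal
    rt[i_active] <- stats::runif(length(i_active),
                                 max(config$rt_range[1], 0.5),
                                 min(config$rt_range[2], 5))
    betas <- config$effect_size * stats::runif(length(i_active), 0.8, 1.2)
    for (k in seq_along(i_active)) {
      j <- i_active[k]
      base_j <- stats::rnorm(1, config$baseline_log_mean, config$baseline_log_sd)
      logI[, j] <- base_j + betas[k] * act01 +
        stats::rnorm(n_s, 0, config$noise_sd_log_intensity)
    }
    for (j in i_regular) {
      base_j <- stats::rnorm(1, config$baseline_log_mean, config$baseline_log_sd)
      org_eff <- stats::rnorm(3, 0, config$organ_effect_sd)
      org_eff <- org_eff - mean(org_eff)
      if (a_norm2 > 0)
        org_eff <- org_eff - sum(org_eff * a_pat) / a_norm2 * a_pat
      logI[, j] <- base_j + org_eff[organ_idx] +
        stats::rnorm(n_s, 0, config$noise_sd_log_intensity)
    }
    for (j in i_sub) {
      base_j <- stats::rnorm(1, config$subthreshold_log_mean, 0.3)
      logI[, j] <- base_j + stats::rnorm(n_s, 0, config$noise_sd_log_intensity)
    }
    intens <- exp(logI)

    # sub-threshold contract: every organ-mean peak area stays below 2000
    for (j in i_sub) {
      gm <- tapply(intens[, j], design$organ, mean)
      if (max(gm) >= 2000) intens[, j] <- intens[, j] * (1000 / max(gm))
    }

    # redundant clones: scaled copies of distinct regular parents at the
    # parent's exact retention time; the 0.8 factor keeps the parent the
    # higher-median representative during pruning
    parents <- if (n_clones > 0) sample(i_regular, n_clones) else integer()
    pairs <- data.frame(parent = character(), clone = character(),
                        mode = character(), stringsAsFactors = FALSE)
    for (k in seq_along(i_clone)) {
      j <- i_clone[k]; pj <- parents[k]
      intens[, j] <- intens[, pj] * 0.8 * (1 + stats::rnorm(n_s, 0, 0.03))
      intens[, j] <- pmax(intens[, j], 0)
      rt[j] <- rt[pj]
      mz[j] <- mz[pj] + 1.0034   # isotope-like neighbour
      pairs <- rbind(pairs, data.frame(parent = ids[pj], clone = ids[j],
                                       mode = mode, stringsAsFactors = FALSE))
    }

    ions <- data.frame(ion_id = ids, mode = mode, mz = mz, rt = rt,
                       stringsAsFactors = FALSE)
    list(block = feature_block(intens, ions, design$sample_id),
         active_ids = ids[i_active],
         effect_sizes = stats::setNames(betas, ids[i_active]),
         pairs = pairs, subthreshold_ids = ids[i_sub])
  })
}

#' Simulate the two ionization-mode feature blocks
#'
#' Active ions follow `log(area) = baseline + slope * activity/100 + noise`;
#' inactive ions carry random organ effects independent of activity (the
#' orthogonal structure); clone ions duplicate a parent at its retention time
#' with correlation > 0.95; sub-threshold ions stay under the intensity
#' filter. All intensities are log-normal peak areas.
#'
#' @param design output of [generate_design()].
#' @param ground_truth output of [generate_latent_activity()].
#' @param config a [generator_config()].
#' @return list with elements `neg`, `pos` (feature blocks) and
#'   `ground_truth` completed with active-ion ids, effect sizes, redundant
#'   pairs and sub-threshold ids.
#' @export
generate_feature_blocks <- function(design, ground_truth,
                                    config = generator_config()) {
  abort_if(is.null(ground_truth$latent_activity), "latent_activity not populated")
  abort_if(config$n_active > config$n_ions_neg + config$n_ions_pos,
           "n_active exceeds the total number of ions")
  n_act_neg <- ceiling(config$n_active / 2)
  n_act_pos <- config$n_active - n_act_neg
  neg <- simulate_block(design, ground_truth$latent_activity, "neg",
                        config$n_ions_neg, n_act_neg,
                        unname(config$n_clone_pairs["neg"]),
                        unname(config$n_subthreshold["neg"]),
                        config, stage_seed(config$seed, 2L))
  pos <- simulate_block(design, ground_truth$latent_activity, "pos",
                        config$n_ions_pos, n_act_pos,
                        unname(config$n_clone_pairs["pos"]),
                        unname(config$n_subthreshold["pos"]),
                        config, stage_seed(config$seed, 3L))
  gt <- ground_truth
  gt$active_ion_ids <- c(neg$active_ids, pos$active_ids)
  gt$effect_sizes <- c(neg$effect_sizes, pos$effect_sizes)
  gt$redundant_pairs <- rbind(neg$pairs, pos$pairs)
  gt$subthreshold_ion_ids <- c(neg$subthreshold_ids, pos$subthreshold_ids)
  list(neg = neg$block, pos = pos$block, ground_truth = gt)
}

#' Simulate enzyme-assay plate records
#'
#' For each extract, expected inhibition at concentration `c` is
#' `latent_activity * c / max(c)` (linear dose scaling, exact at the
#' reference 10 ug/mL dose); triplicate absorbances at 405 nm are
#' `A_ctrl * (1 - inhibition/100) * (1 + CV * z)`. Negative-control wells and
#' an acarbose positive-control series (mg/mL, near-complete inhibition at
#' the top dose) are included.
#'
#' @param design output of [generate_design()].
#' @param ground_truth with `latent_activity` populated.
#' @param config a [generator_config()].
#' @param n_replicates wells per sample x concentration.
#' @param n_control_wells enzyme-only wells; more than the per-sample
#'   triplicate because every inhibition value is referenced against their
#'   mean, so control error propagates into all samples.
#' @return data.frame (long format) with columns `sample_id`, `role`,
#'   `concentration`, `conc_unit`, `replicate`, `absorbance`.
#' @export
generate_assay_plate <- function(design, ground_truth,
                                 config = generator_config(),
                                 n_replicates = 3, n_control_wells = 6) {
  abort_if(is.null(ground_truth$latent_activity), "latent_activity not populated")
  abort_if(config$assay_cv < 0, "assay_cv must be non-negative")
  act <- ground_truth$latent_activity[design$sample_id]
  conc <- config$concentrations
  cmax <- max(conc)
  ac_conc <- config$acarbose_concentrations
  ac_cmax <- max(ac_conc)

  rows_per <- function(id, role, concs, unit, inh_at,
                       n_rep = n_replicates) {
    g <- expand.grid(concentration = concs, replicate = seq_len(n_rep),
                     KEEP.OUT.ATTRS = FALSE)
    data.frame(sample_id = id, role = role, concentration = g$concentration,
               conc_unit = unit, replicate = g$replicate,
               expected_inh = inh_at(g$concentration),
               stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, c(
    list(rows_per("NEG_CTRL", "negative_control", 0, "ug/mL",
                  function(c) rep(0, length(c)), n_rep = n_control_wells)),
    lapply(seq_len(nrow(design)), function(i)
      rows_per(design$sample_id[i], "extract", conc, "ug/mL",
               function(c) act[i] * c / cmax)),
    list(rows_per("acarbose", "positive_control", ac_conc, "mg/mL",
                  function(c) config$acarbose_inhibition_top * c / ac_cmax))))
  recs$absorbance <- withr::with_seed(stage_seed(config$seed, 4L), {
    config$a_control * (1 - recs$expected_inh / 100) *
      (1 + config$assay_cv * stats::rnorm(nrow(recs)))
  })
  recs$absorbance <- pmax(recs$absorbance, 0)
  recs$expected_inh <- NULL
  recs
}

#' Simulate a complete study
#'
#' Convenience wrapper running design, latent activity, feature blocks and
#' assay plate generation under one configuration.
#'
#' @param config a [generator_config()].
#' @return list with `design`, `ground_truth`, `neg`, `pos`, `plate`, and the
#'   `config` used.
#' @export
simulate_study <- function(config = generator_config()) {
  design <- generate_design(config$n_trees, config$seed)
  gt <- generate_latent_activity(design, config)
  fb <- generate_feature_blocks(design, gt, config)
  plate <- generate_assay_plate(design, fb$ground_truth, config)
  list(design = design, ground_truth = fb$ground_truth,
       neg = fb$neg, pos = fb$pos, plate = plate, config = config)
}
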