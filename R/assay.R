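#' Percent inhibition from paired absorbances
#'
#' Computes `(A_ctrl - A_sample) / A_ctrl * 100`, the percent inhibition of
#' alpha-glucosidase read from p-nitrophenol absorbance at 405 nm. Values
#' above the control give negative inhibition and are deliberately not
#' clipped.
#'
#' @param a_negative_control absorbance of the enzyme-only control (> 0).
#' @param a_sample absorbance in the presence of inhibitor.
#' @return Percent inhibition (vectorized over `a_sample`).
#' @export
inhibition_percent <- function(a_negative_control, a_sample) {
  abort_if(!is.numeric(a_negative_control) || any(!is.finite(a_negative_control)) ||
             any(a_negative_control <= 0),
           "a_negative_control must be a positive finite number")
  abort_if(!is.numeric(a_sample) || any(!is.finite(a_sample)),
           "a_sample must be finite")
  (a_negative_control - a_sample) / a_negative_control * 100
}

#' Summarize per-sample inhibition at a reference concentration
#'
#' For every extract on the plate, replicate absorbances at the reference
#' concentration are converted to percent inhibition against the mean
#' negative-control absorbance, then summarized as mean, standard deviation
#' and replicate count.
#'
#' @param plate long-format assay table with columns `sample_id`, `role`,
#'   `concentration`, `replicate`, `absorbance` (see
#'   [generate_assay_plate()]).
#' @param reference_concentration concentration (same units as the extract
#'   series) at which inhibition is reported; default 10.
#' @return data.frame with `sample_id`, `inhibition_percent`, `sd_percent`,
#'   `n_replicates`.
#' @export
summarize_activity <- function(plate, reference_concentration = 10) {
  needed <- c("sample_id", "role", "concentration", "replicate", "absorbance")
  abort_if(!all(needed %in% names(plate)),
           paste("plate table needs columns", paste(needed, collapse = ", ")))
  ctrl <- plate$absorbance[plate$role == "negative_control"]
  abort_if(length(ctrl) == 0, "no negative-control records on the plate")
  a0 <- mean(ctrl)
  extracts <- plate[plate$role == "extract", , drop = FALSE]
  samples <- unique(extracts$sample_id)
  out <- lapply(samples, function(sid) {
    a <- extracts$absorbance[extracts$sample_id == sid &
                               extracts$concentration == reference_concentration]
    abort_if(length(a) == 0,
             sprintf("sample '%s' has no record at the reference concentration %g",
                     sid, reference_concentration))
    inh <- inhibition_percent(a0, a)
    data.frame(sample_id = sid, inhibition_percent = mean(inh),
               sd_percent = if (length(inh) > 1) stats::sd(inh) else 0,
               n_replicates = length(inh), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Replicate-level inhibition values
#'
#' Returns one percent-inhibition value per replicate well at the requested
#' concentration, for extracts and/or controls; used for rank-based group
#' comparisons where replicate values (not means) are needed.
#'
#' @inheritParams summarize_activity
#' @param roles which plate roles to return values for.
#' @param concentration dose at which to read inhibition; by default the
#'   maximum dose available within each role (reference dose for extracts,
#'   top dose for a positive control with its own unit).
#' @return data.frame with `sample_id`, `role`, `replicate`,
#'   `inhibition_percent`.
#' @export
replicate_inhibition <- function(plate, roles = c("extract", "positive_control"),
                                 concentration = NULL) {
  ctrl <- plate$absorbance[plate$role == "negative_control"]
  abort_if(length(ctrl) == 0, "no negative-control records on the plate")
  a0 <- mean(ctrl)
  keep <- plate[plate$role %in% roles, , drop = FALSE]
  out <- lapply(split(keep, keep$sample_id), function(d) {
    cc <- if (is.null(concentration)) max(d$concentration) else concentration
    d <- d[d$concentration == cc, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(sample_id = d$sample_id[1], role = d$role[1],
               replicate = d$replicate,
               inhibition_percent = inhibition_percent(a0, d$absorbance),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate IC50 from a concentration series
#'
#' Two estimators are provided. `monotone_interpolation` (default) smooths
#' the mean dose-response curve with pool-adjacent-violators isotonic
#' regression and linearly interpolates the 50% crossing between the
#' bracketing doses; it makes no model assumption. `four_param_logistic`
#' fits `y = bottom + (top - bottom) * c^h / (c^h + e^h)` by
#' Levenberg-Marquardt least squares and inverts the fitted curve at 50%.
#'
#' @param concentrations dose values (>= 2 distinct for interpolation, >= 4
#'   for the logistic fit).
#' @param inhibitions percent inhibition, same length.
#' @param method `"monotone_interpolation"` or `"four_param_logistic"`.
#' @return list of class `ic50_result` with `ic50` (NA when 50% is never
#'   crossed), `method`, `converged`, and `reason` when undefined.
#' @export
estimate_ic50 <- function(concentrations, inhibitions,
                          method = c("monotone_interpolation",
                                     "four_param_logistic")) {
  method <- match.arg(method)
  abort_if(!is.numeric(concentrations) || !is.numeric(inhibitions) ||
             any(!is.finite(concentrations)) || any(!is.finite(inhibitions)),
           "concentrations and inhibitions must be finite numbers")
  abort_if(length(concentrations) != length(inhibitions),
           "concentrations and inhibitions must have equal length")
  nd <- length(unique(concentrations))
  res <- function(ic50, converged, reason = NA_character_)
    structure(list(ic50 = ic50, method = method, converged = converged,
                   reason = reason), class = "ic50_result")

  # mean response per dose, sorted
  xs <- sort(unique(concentrations))
  ys <- vapply(xs, function(c0) mean(inhibitions[concentrations == c0]), 0)

  if (method == "monotone_interpolation") {
    abort_if(nd < 2, "need >= 2 distinct concentrations for interpolation")
    ysm <- stats::isoreg(xs, ys)$yf
    if (max(ysm) < 50) return(res(NA_real_, FALSE, "50% inhibition never reached"))
    if (ysm[1] >= 50) return(res(NA_real_, FALSE, "50% already exceeded at the lowest dose"))
    i <- which(ysm >= 50)[1]
    ic <- if (ysm[i] == ysm[i - 1]) xs[i] else
      xs[i - 1] + (50 - ysm[i - 1]) * (xs[i] - xs[i - 1]) / (ysm[i] - ysm[i - 1])
    return(res(ic, TRUE))
  }

  abort_if(nd < 4, "need >= 4 distinct concentrations for the logistic fit")
  dat <- data.frame(c = concentrations, y = inhibitions)
  start <- list(bottom = min(ys), top = max(ys),
                e = xs[which.min(abs(ys - 50))] + 1e-6, h = 1)
  fit <- try(minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) * ifelse(c > 0, c^h / (c^h + e^h), 0),
    data = dat, start = start,
    lower = c(-Inf, -Inf, 1e-9, 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)), silent = TRUE)
  if (inherits(fit, "try-error")) return(res(NA_real_, FALSE, "logistic fit failed"))
  p <- as.list(stats::coef(fit))
  if (!(p$bottom < 50 && p$top > 50))
    return(res(NA_real_, FALSE, "50% outside the fitted response range"))
  ic <- p$e * ((50 - p$bottom) / (p$top - 50))^(1 / p$h)
  res(ic, TRUE)
}

#' @export
print.ic50_result <- function(x, ...) {
  if (is.na(x$ic50)) {
    cat(sprintf("<ic50_result> undefined (%s; %s)\n", x$method, x$reason))
  } else {
    cat(sprintf("<ic50_result> IC50 = %.4g (%s)\n", x$ic50, x$method))
  }
  invisible(x)
}
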