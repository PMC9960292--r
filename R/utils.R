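#' @keywords internal
"_PACKAGE"

ORGANS <- c("leaf", "stem_bark", "fruit")
SITES <- c("littoral", "mountain")

# Deterministic per-stage substream of a master seed (kept < 2^31 - 1 so it is
# a valid R integer seed).
stage_seed <- function(seed, stage) {
  s <- (as.numeric(seed) %% 1000003) * 2017 + stage * 7919
  as.integer(s %% 2147483647)
}

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

organ_site_key <- function(organ, site) paste(organ, site, sep = ".")
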