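# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Canonical stimulus-energy levels
#'
#' The four laser energy levels used throughout the package. Energy labels in
#' trial metadata must come from this set.
#'
#' @return Character vector `c("E1", "E2", "E3", "E4")`.
#' @export
energy_levels <- function() c("E1", "E2", "E3", "E4")

# Validate a trial metadata data.frame (subject_id, trial_index, energy, rating).
validate_trial_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  required <- c("subject_id", "trial_index", "energy", "rating")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L)
    stop("trial metadata lacks columns: ", paste(missing, collapse = ", "))
  if (!all(meta$energy %in% energy_levels()))
    stop("energy labels must be one of ", paste(energy_levels(), collapse = "/"))
  if (any(!is.finite(meta$rating)) || any(meta$rating < 0 | meta$rating > 10))
    stop("ratings must lie in [0, 10]")
  if (anyDuplicated(meta[, c("subject_id", "trial_index")]))
    stop("trial_index must be unique within subject")
  invisible(meta)
}

# Deterministic derived seed for a pipeline sub-stage; stays below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# EEG frequency-band label for naming discovered patterns.
band_label <- function(freq_hz) {
  mid <- mean(range(freq_hz))
  if (mid < 4) "delta" else if (mid < 8) "theta" else if (mid < 16) "alpha"
  else if (mid < 31) "beta" else "gamma"
}

# Full-precision numeric formatting so CSV round trips are exact.
format_exact <- function(x) formatC(x, digits = 17, format = "g")
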