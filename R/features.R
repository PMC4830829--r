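# Trial x feature matrices with pre/post phase tags and per-energy
# normalization. Feature order is fixed and documented so that serialization
# round trips are bit-identical.

new_feature_matrix <- function(values, coords, phase, meta, grid,
                               normalized = FALSE, group_means = NULL) {
  stopifnot(nrow(values) == nrow(meta), ncol(values) == nrow(coords),
            length(phase) == nrow(coords), all(phase %in% c("pre", "post")))
  structure(
    list(values = values, coords = coords, phase = phase, meta = meta,
         grid = grid, normalized = normalized, group_means = group_means),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d trials x %d features (%d pre, %d post), grid '%s'%s\n",
    nrow(x$values), ncol(x$values), sum(x$phase == "pre"),
    sum(x$phase == "post"), x$grid$type,
    if (isTRUE(x$normalized)) ", energy-normalized" else ""))
  invisible(x)
}

#' Time-frequency features from per-trial spectrograms
#'
#' Flattens spectrogram pixels falling in the pre-stimulus and post-stimulus
#' analysis windows into one feature row per trial. Windows are half-open
#' `[start, end)`, so a bin centered exactly at 0 ms is post-stimulus. Features
#' are ordered by time bin (ascending) and, within a time bin, by frequency bin
#' (ascending); this order is stable across extraction, serialization and
#' re-reading.
#'
#' @param specs List of [compute_spectrogram()] results, one per trial, all on
#'   the same time-frequency grid.
#' @param meta Trial metadata data.frame with columns `subject_id`,
#'   `trial_index`, `energy`, `rating`, one row per spectrogram.
#' @param pre_window,post_window Length-2 numeric vectors, ms relative to
#'   stimulus onset; defaults `(-500, 0)` and `(0, 1000)`.
#' @return A `feature_matrix` with per-feature `coords` columns `freq_hz`,
#'   `time_ms`, `fi`, `ti` (grid indices) and `phase` tags.
#' @export
extract_tf_features <- function(specs, meta, pre_window = c(-500, 0),
                                post_window = c(0, 1000)) {
  validate_trial_meta(meta)
  stopifnot(length(specs) == nrow(meta), length(specs) >= 1L)
  ref <- specs[[1L]]
  for (s in specs) {
    if (!isTRUE(all.equal(s$freqs_hz, ref$freqs_hz)) ||
        !isTRUE(all.equal(s$times_ms, ref$times_ms)))
      stop("spectrogram grids differ across trials")
  }
  t_ms <- ref$times_ms
  phase_of_bin <- rep(NA_character_, length(t_ms))
  phase_of_bin[t_ms >= pre_window[1] & t_ms < pre_window[2]] <- "pre"
  phase_of_bin[t_ms >= post_window[1] & t_ms < post_window[2]] <- "post"
  keep_t <- which(!is.na(phase_of_bin))
  if (length(keep_t) == 0L) stop("no spectrogram bins fall inside the analysis windows")

  nf <- length(ref$freqs_hz)
  coords <- data.frame(
    freq_hz = rep(ref$freqs_hz, times = length(keep_t)),
    time_ms = rep(t_ms[keep_t], each = nf),
    fi = rep(seq_len(nf), times = length(keep_t)),
    ti = rep(keep_t, each = nf)
  )
  phase <- rep(phase_of_bin[keep_t], each = nf)

  values <- matrix(NA_real_, nrow = length(specs), ncol = nrow(coords))
  for (i in seq_along(specs)) {
    values[i, ] <- as.numeric(specs[[i]]$power[, keep_t, drop = FALSE])
  }

  grid <- list(type = "tf", dims = c(nf, length(t_ms)), freqs_hz = ref$freqs_hz,
               times_ms = t_ms, window_ms = ref$window_ms, step_ms = ref$step_ms)
  new_feature_matrix(values, coords, phase, meta, grid)
}

#' Onset-scan and peak-scan features from a BOLD series
#'
#' For each trial the onset scan is the last scan whose acquisition start is at
#' or before the stimulus onset, and the peak scan is `peak_lag_scans` scans
#' later (default 4, the scan at the hemodynamic response maximum). In-mask
#' voxels of the onset scan become pre-stimulus features, the same voxels of
#' the peak scan post-stimulus features. Voxels are flattened in column-major
#' array order (x fastest), which is stable across write/read round trips.
#'
#' Scan indices are reported 0-based (acquisition numbering), so an onset at
#' 15.0 s with TR 1.5 s maps to onset scan 10 and peak scan 14.
#'
#' @param bold 4-D numeric array (x, y, z, scan).
#' @param mask 3-D array; nonzero voxels are in-brain.
#' @param onsets_s Stimulus onset times in seconds, one per trial.
#' @param tr_s Repetition time in seconds.
#' @param peak_lag_scans Scans between onset scan and peak scan (>= 1).
#' @param meta Trial metadata data.frame (see [extract_tf_features()]).
#' @return A `feature_matrix` with voxel coordinates `i, j, k`, a `voxel`
#'   linear index, and per-trial onset/peak scan indices stored in `meta`
#'   (`onset_scan`, `peak_scan`, 0-based).
#' @export
extract_bold_features <- function(bold, mask, onsets_s, tr_s,
                                  peak_lag_scans = 4L, meta) {
  validate_trial_meta(meta)
  stopifnot(length(dim(bold)) == 4L, length(dim(mask)) == 3L,
            all(dim(bold)[1:3] == dim(mask)), tr_s > 0, peak_lag_scans >= 1L,
            length(onsets_s) == nrow(meta))
  vox <- which(mask != 0)
  if (length(vox) == 0L) stop("mask is empty")
  n_scans <- dim(bold)[4]
  nvx <- prod(dim(mask))

  onset_idx <- floor(onsets_s / tr_s)          # 0-based: last scan starting <= onset
  peak_idx <- onset_idx + peak_lag_scans
  bad <- which(peak_idx > n_scans - 1L | onset_idx < 0L)
  if (length(bad) > 0L)
    stop("trial ", meta$trial_index[bad[1L]],
         ": onset/peak scan outside the acquired series")

  ijk <- arrayInd(vox, dim(mask))
  coords <- data.frame(
    i = c(ijk[, 1], ijk[, 1]), j = c(ijk[, 2], ijk[, 2]),
    k = c(ijk[, 3], ijk[, 3]), voxel = c(vox, vox)
  )
  phase <- rep(c("pre", "post"), each = length(vox))

  flat <- matrix(bold, nrow = nvx)             # voxels x scans
  values <- matrix(NA_real_, nrow = nrow(meta), ncol = 2L * length(vox))
  for (p in seq_len(nrow(meta))) {
    values[p, ] <- c(flat[vox, onset_idx[p] + 1L], flat[vox, peak_idx[p] + 1L])
  }
  meta$onset_scan <- as.integer(onset_idx)
  meta$peak_scan <- as.integer(peak_idx)

  grid <- list(type = "voxel", dims = dim(mask), mask_voxels = vox, tr_s = tr_s,
               peak_lag_scans = as.integer(peak_lag_scans))
  new_feature_matrix(values, coords, phase, meta, grid)
}

#' Undo per-energy feature normalization
#'
#' Reconstructs the raw feature values of a normalized `feature_matrix` by
#' adding back the retained energy-group means. Classification consumes
#' features on this scale: stimulus-driven response amplitude is informative
#' about high versus low pain and only the trial-to-trial relationship
#' assessment (pattern discovery, regression on fluctuation) removes it.
#'
#' @param fm A `feature_matrix`.
#' @return The trials x features value matrix on the raw scale.
#' @export
raw_values <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!isTRUE(fm$normalized) || is.null(fm$group_means)) return(fm$values)
  gm <- fm$group_means$feature_means
  out <- fm$values + gm[match(fm$meta$energy, rownames(gm)), , drop = FALSE]
  dimnames(out) <- dimnames(fm$values)
  out
}

#' Normalize features and ratings within stimulus-energy groups
#'
#' Removes, for each energy group, the group mean from every feature column
#' and from the ratings, isolating trial-to-trial fluctuation under identical
#' stimulus energy. The removed group means are retained in the result
#' (`group_means$feature_means`, `group_means$rating_means`) so predictions on
#' the normalized scale can be mapped back to the 0-10 VAS scale. Normalized
#' ratings are stored in `meta$rating_norm`. The operation is idempotent:
#' applying it twice equals applying it once (group means accumulate).
#'
#' @param fm A `feature_matrix`.
#' @return The normalized `feature_matrix`.
#' @export
normalize_by_energy <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  energies <- fm$meta$energy
  groups <- sort(unique(energies))
  fmeans <- matrix(0, nrow = length(groups), ncol = ncol(fm$values),
                   dimnames = list(groups, NULL))
  rmeans <- stats::setNames(numeric(length(groups)), groups)
  values <- fm$values
  base_rating <- fm$meta$rating_norm %||% fm$meta$rating
  rating_norm <- base_rating
  for (g in seq_along(groups)) {
    rows <- which(energies == groups[g])
    fmeans[g, ] <- colMeans(values[rows, , drop = FALSE])
    values[rows, ] <- sweep(values[rows, , drop = FALSE], 2L, fmeans[g, ])
    rmeans[g] <- mean(base_rating[rows])
    rating_norm[rows] <- base_rating[rows] - rmeans[g]
  }
  prev <- fm$group_means
  if (!is.null(prev)) {                        # accumulate so the map back to VAS survives re-application
    fmeans <- fmeans[rownames(prev$feature_means), , drop = FALSE] + prev$feature_means
    rmeans <- rmeans[names(prev$rating_means)] + prev$rating_means
  }
  fm$values <- values
  fm$meta$rating_norm <- rating_norm
  fm$normalized <- TRUE
  fm$group_means <- list(feature_means = fmeans, rating_means = rmeans)
  fm
}
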