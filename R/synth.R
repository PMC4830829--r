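# Synthetic cohorts with planted pre- and post-stimulus pain-related effects
# and stored ground truth. The generator emulates the study design the
# pipeline targets: 4 stimulus energies x 10 trials per subject, VAS ratings
# whose energy-group means follow the psychophysics of the modeled experiment
# (E1 3.81, E2 4.86, E3 6.63, E4 7.75), a latent pre-stimulus state that
# modulates rating fluctuation within energy, and a post-stimulus response
# latent. Planted effects are calibrated so that a pattern's region-mean
# feature moves `d` residual standard deviations per SD of its latent.

#' Default planted EEG time-frequency patterns
#'
#' The five time-frequency clusters reported to modulate perceived pain:
#' pre-stimulus alpha (negative), pre-stimulus gamma (negative), the
#' low-frequency post-stimulus response (positive), post-stimulus alpha
#' (negative) and post-stimulus gamma (positive).
#'
#' @param d_pre,d_post Planted effect sizes (standardized within-subject
#'   slope, see the package vignette) for pre- and post-stimulus patterns.
#'   Defaults 0.5 and 1: pre-stimulus state modulates perception more weakly
#'   than the stimulus-driven response.
#' @return List of pattern specifications with `name`, `phase`,
#'   `time_ms`, `freq_hz`, `sign`, `d`.
#' @export
default_planted_patterns <- function(d_pre = 0.5, d_post = 1) {
  list(
    list(name = "Pre-ABO", phase = "pre", time_ms = c(-221, -31),
         freq_hz = c(8, 15), sign = -1L, d = d_pre),
    list(name = "Pre-GBO", phase = "pre", time_ms = c(-180, -85),
         freq_hz = c(74, 87), sign = -1L, d = d_pre),
    list(name = "LEP", phase = "post", time_ms = c(74, 470),
         freq_hz = c(1, 22), sign = 1L, d = d_post),
    list(name = "Post-ABO", phase = "post", time_ms = c(637, 935),
         freq_hz = c(8, 20), sign = -1L, d = d_post),
    list(name = "Post-GBO", phase = "post", time_ms = c(127, 377),
         freq_hz = c(62, 100), sign = 1L, d = d_post)
  )
}

#' Default planted fMRI blobs for the small synthetic grid
#'
#' @param d_pre,d_post Planted effect sizes as in
#'   [default_planted_patterns()].
#' @return List of blob specifications with `name`, `phase`, `center`,
#'   `radius` (voxels), `sign`, `d`.
#' @export
default_planted_blobs <- function(d_pre = 0.5, d_post = 1) {
  list(
    list(name = "Pre-Blob", phase = "pre", center = c(7, 10, 8),
         radius = 2.5, sign = -1L, d = d_pre),
    list(name = "Post-Blob-Pos", phase = "post", center = c(14, 10, 8),
         radius = 2.5, sign = 1L, d = d_post),
    list(name = "Post-Blob-Neg", phase = "post", center = c(10, 15, 8),
         radius = 2, sign = -1L, d = d_post)
  )
}

#' Configuration for a synthetic cohort
#'
#' @param n_subjects Number of subjects.
#' @param seed Mandatory integer seed; cohorts are bit-reproducible.
#' @param mode `"eeg"` or `"fmri"`.
#' @param trials_per_energy Trials per stimulus energy (default 10, i.e. 40
#'   trials per subject).
#' @param energy_means Mean VAS rating per energy (defaults 3.81, 4.86, 6.63,
#'   7.75).
#' @param rating_noise_sd SD of trial-wise rating noise (default 1.0,
#'   matching the within-energy rating SDs of the modeled psychophysics
#'   together with the two state SDs below).
#' @param pre_state_sd,post_state_sd SD of the contribution of the latent
#'   pre-stimulus state and of the post-stimulus response latent to the
#'   rating (defaults 0.6 and 0.8).
#' @param planted Pattern list ([default_planted_patterns()] /
#'   [default_planted_blobs()] depending on mode).
#' @param ar1_phi Serial correlation of the pre-stimulus latent across trials
#'   (default 0: i.i.d.; an AR(1) option for robustness checks).
#' @param fs,epoch_ms EEG sampling rate and epoch span (defaults 1000 Hz,
#'   -500..1000 ms).
#' @param window_ms,step_ms,freq_range STFT settings used to calibrate the
#'   planted effects on the analysis grid.
#' @param fmri_dims,tr_s,isi_range_s,peak_lag_scans fMRI grid and timing.
#' @param subject_scale_sd Log-SD of the per-subject background amplitude.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects, seed, mode = c("eeg", "fmri"),
                         trials_per_energy = 10L,
                         energy_means = c(3.81, 4.86, 6.63, 7.75),
                         rating_noise_sd = 1.0,
                         pre_state_sd = 0.6, post_state_sd = 0.8,
                         planted = NULL, ar1_phi = 0,
                         fs = 1000, epoch_ms = c(-500, 1000),
                         window_ms = 200, step_ms = 10,
                         freq_range = c(1, 100),
                         fmri_dims = c(20L, 20L, 16L), tr_s = 1.5,
                         isi_range_s = c(10, 15), peak_lag_scans = 4L,
                         subject_scale_sd = 0.2) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(energy_means) == 4L, all(energy_means >= 0 & energy_means <= 10),
            n_subjects >= 1L, trials_per_energy >= 1L)
  if (is.null(planted))
    planted <- if (mode == "eeg") default_planted_patterns() else default_planted_blobs()
  for (p in planted) {
    if (p$d < 0) stop("planted effect sizes must be >= 0")
    if (mode == "eeg") {
      if (p$time_ms[1] < epoch_ms[1] || p$time_ms[2] > epoch_ms[2] ||
          p$freq_hz[1] < freq_range[1] || p$freq_hz[2] > freq_range[2])
        stop("planted pattern '", p$name, "' lies off the analysis grid")
    } else {
      if (any(p$center - p$radius < 1) || any(p$center + p$radius > fmri_dims))
        stop("planted blob '", p$name, "' lies off the voxel grid")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         mode = mode, trials_per_energy = as.integer(trials_per_energy),
         energy_means = energy_means, rating_noise_sd = rating_noise_sd,
         pre_state_sd = pre_state_sd, post_state_sd = post_state_sd,
         planted = planted, ar1_phi = ar1_phi, fs = fs, epoch_ms = epoch_ms,
         window_ms = window_ms, step_ms = step_ms, freq_range = freq_range,
         fmri_dims = as.integer(fmri_dims), tr_s = tr_s,
         isi_range_s = isi_range_s, peak_lag_scans = as.integer(peak_lag_scans),
         subject_scale_sd = subject_scale_sd),
    class = "synth_config")
}

# --- EEG background and burst machinery ------------------------------------

# amplitude spectral profile of the EEG background: 1/f^1.3 power with an
# alpha bump and a white floor
bg_amp_profile <- function(freq_hz) {
  pmax(freq_hz, 0.5)^(-0.65) + 0.5 * exp(-(freq_hz - 10)^2 / (2 * 2^2)) + 0.02
}

# background epochs with per-subject amplitude scale; trials x samples
eeg_background <- function(n_trials, n_samples, fs, scale) {
  freqs <- (seq_len(n_samples) - 1L) * fs / n_samples
  freqs <- pmin(freqs, fs - freqs)             # two-sided symmetric profile
  amp <- bg_amp_profile(freqs)
  out <- matrix(NA_real_, n_trials, n_samples)
  for (i in seq_len(n_trials)) {
    w <- stats::rnorm(n_samples)
    out[i, ] <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n_samples
  }
  out * scale
}

# Multi-tone burst with cosine ramps, supported on [t1, t2] ms around onset.
# Tone frequencies sit inside the band with a margin so that spectral energy
# stays concentrated in the declared rectangle after windowed analysis, and
# each tone's amplitude follows the background spectral profile so that the
# planted signal-to-background ratio is uniform across the band (edges of the
# planted rectangle then cut off sharply in relative terms).
burst_tones <- function(freq_hz) {
  w <- diff(freq_hz)
  margin <- min(2.5, w / 4)
  lo <- freq_hz[1] + margin
  hi <- freq_hz[2] - margin
  # 6 Hz spacing keeps tone mainlobes (half-power +-3 Hz for a 200 ms window)
  # from overlapping, so the planted power pattern barely depends on the
  # random tone phases and stays consistent across subjects
  tones <- if (hi <= lo) mean(freq_hz) else seq(lo, hi, by = 6)
  if (length(tones) == 1L) tones <- mean(freq_hz)
  list(freqs = tones, weights = bg_amp_profile(tones))
}

make_burst <- function(n_samples, fs, t0_ms, time_ms, tones, phases = NULL,
                       ramp_ms = 50, window_ms = 200) {
  t_ms <- t0_ms + (seq_len(n_samples) - 1L) / fs * 1000
  env <- numeric(n_samples)
  # Full support with a smooth taper: the envelope's own duration sets the
  # spectral mainlobe width, so the longest possible envelope keeps planted
  # energy spectrally narrow, and Hann-like tapering keeps envelope sidelobes
  # (which would otherwise bleed into spectrally quiet bands) at the -31 dB
  # level. Rectangles shorter than ~1.2 analysis windows get a pure Hann
  # envelope; longer ones a Tukey envelope with generous ramps.
  span <- diff(time_ms)
  t1 <- time_ms[1]; t2 <- time_ms[2]
  r <- if (span <= 1.2 * window_ms) span / 2 else min(100, span / 3)
  inside <- t_ms >= t1 & t_ms <= t2
  env[inside] <- 1
  up <- inside & t_ms < t1 + r
  env[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - t1) / r))
  down <- inside & t_ms > t2 - r
  env[down] <- 0.5 * (1 - cos(pi * (t2 - t_ms[down]) / r))
  if (is.null(phases)) phases <- numeric(length(tones$freqs))
  sig <- numeric(n_samples)
  t_s <- t_ms / 1000
  for (j in seq_along(tones$freqs))
    sig <- sig + tones$weights[j] * cos(2 * pi * tones$freqs[j] * t_s + phases[j])
  sig * env
}

# Region bins (fi, ti index pairs) of one planted rectangle on a spectrogram.
region_bins <- function(spec, time_ms, freq_hz) {
  fi <- which(spec$freqs_hz >= freq_hz[1] & spec$freqs_hz <= freq_hz[2])
  ti <- which(spec$times_ms >= time_ms[1] & spec$times_ms <= time_ms[2])
  if (length(fi) == 0L || length(ti) == 0L)
    stop("planted rectangle contains no spectrogram bins")
  list(fi = fi, ti = ti)
}

# --- ratings and latents ----------------------------------------------------

draw_trial_table <- function(cfg, subject_id) {
  n <- 4L * cfg$trials_per_energy
  energy <- sample(rep(energy_levels(), each = cfg$trials_per_energy))
  emean <- cfg$energy_means[match(energy, energy_levels())]
  if (cfg$ar1_phi != 0) {
    z_pre <- numeric(n)
    z_pre[1] <- stats::rnorm(1)
    for (i in 2:n)
      z_pre[i] <- cfg$ar1_phi * z_pre[i - 1] +
        sqrt(1 - cfg$ar1_phi^2) * stats::rnorm(1)
  } else {
    z_pre <- stats::rnorm(n)
  }
  z_post <- stats::rnorm(n)
  noise <- stats::rnorm(n, sd = cfg$rating_noise_sd)
  s_pre <- cfg$pre_state_sd * z_pre
  s_post <- cfg$post_state_sd * z_post
  unclipped <- emean + s_pre + s_post + noise
  data.frame(subject_id = subject_id, trial_index = seq_len(n),
             energy = energy, rating = clip_range(unclipped, 0, 10),
             energy_mean = emean, s_pre = s_pre, s_post = s_post,
             noise = noise, rating_unclipped = unclipped,
             z_pre = z_pre, z_post = z_post)
}

# --- generator --------------------------------------------------------------

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws per-trial ratings as `clip(energy_mean + s_pre + s_post + noise,
#' 0, 10)`, where `s_pre` is the rating contribution of a latent pre-stimulus
#' state (statistically independent of stimulus energy) and `s_post` that of
#' the post-stimulus response latent, and expresses those latents in the
#' brain data: for EEG, amplitude-calibrated oscillatory bursts inside each
#' planted time-frequency rectangle; for fMRI, uniform offsets on spherical
#' blobs of the onset or peak scan. The planted slope is calibrated per
#' subject against the measured background variability of the region-mean
#' feature (including the burst-background interference term for EEG), so
#' that the realized standardized slope matches the configured `d`.
#'
#' @param cfg A [synth_config()].
#' @return A `trial_cohort` with elements `mode`, `subjects` (per subject:
#'   `epochs` + `meta` for EEG; `bold`, `mask`, `onsets_s`, `meta` for fMRI),
#'   timing fields, the `config`, and `ground_truth` (per-pattern feature
#'   masks on the default analysis grid, per-trial latents and the exact
#'   rating decomposition).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  if (cfg$mode == "eeg") generate_cohort_eeg(cfg) else generate_cohort_fmri(cfg)
}

generate_cohort_eeg <- function(cfg) {
  n_samples <- round(diff(cfg$epoch_ms) * cfg$fs / 1000)
  n_trials <- 4L * cfg$trials_per_energy
  spec_of <- function(x, complex = FALSE) compute_spectrogram(
    eeg_epoch(x, cfg$fs, cfg$epoch_ms[1]),
    window_ms = cfg$window_ms, step_ms = cfg$step_ms,
    freq_range = cfg$freq_range, keep_complex = complex)

  probe <- spec_of(numeric(n_samples))         # grid reference
  pat_rb <- lapply(cfg$planted, function(p)
    region_bins(probe, p$time_ms, p$freq_hz))
  active <- which(vapply(cfg$planted, `[[`, 0, "d") > 0)
  c0 <- 3                                      # headroom: added power stays >= 0 for |z| < 3

  subjects <- list()
  trials <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%03d", s)
    scale <- exp(stats::rnorm(1, sd = cfg$subject_scale_sd))
    tt <- draw_trial_table(cfg, sid)
    epochs <- eeg_background(n_trials, n_samples, cfg$fs, scale)

    if (length(active) > 0L) {
      # one burst waveform per pattern and subject (tone phases drawn per
      # subject), with its exact complex STFT on the region bins
      bursts <- lapply(active, function(pi) {
        p <- cfg$planted[[pi]]
        tones <- burst_tones(p$freq_hz)
        wave <- make_burst(n_samples, cfg$fs, cfg$epoch_ms[1], p$time_ms,
                           tones,
                           phases = stats::runif(length(tones$freqs), 0, 2 * pi),
                           window_ms = cfg$window_ms)
        bs <- spec_of(wave, complex = TRUE)
        rb <- pat_rb[[pi]]
        A <- bs$stft[rb$fi, rb$ti]
        list(wave = wave, A = A, P1 = mean(Mod(A)^2))
      })
      # per-trial background power in each region and its interference with
      # the burst; per-bin SDs give the pixel-level noise reference
      K <- vapply(bursts, function(b) length(b$A), 0L)
      bg_bins <- lapply(seq_along(active), function(j)
        matrix(NA_real_, n_trials, K[j]))
      cross <- matrix(NA_real_, n_trials, length(active))
      for (i in seq_len(n_trials)) {
        sp <- spec_of(epochs[i, ], complex = TRUE)
        for (j in seq_along(active)) {
          rb <- pat_rb[[active[j]]]
          B <- sp$stft[rb$fi, rb$ti]
          bg_bins[[j]][i, ] <- Mod(B)^2
          cross[i, j] <- 2 * sum(Re(B * Conj(bursts[[j]]$A))) / K[j]
        }
      }
      for (j in seq_along(active)) {
        p <- cfg$planted[[active[j]]]
        # region-mean reference: effect size d moves the pattern's region-mean
        # power by d of its trial-to-trial SD per SD of the latent state, the
        # same quantity the decoder consumes as a predictor
        tau <- stats::sd(rowMeans(bg_bins[[j]]))
        slope <- p$d * tau
        z <- if (p$phase == "pre") tt$z_pre else tt$z_post
        p_add <- slope * (c0 + p$sign * z)
        if (p$phase == "post") {             # stimulus-energy-driven amplitude, removed by normalization
          eidx <- match(tt$energy, energy_levels())
          p_add <- p_add + 0.5 * slope * (eidx - 2.5)
        }
        p_add <- pmax(p_add, 0)
        # amplitude solving P1 a^2 + cross a = p_add exactly, so the realized
        # region power equals background + planted power by construction
        P1 <- bursts[[j]]$P1
        a <- (-cross[, j] + sqrt(cross[, j]^2 + 4 * P1 * p_add)) / (2 * P1)
        a[p_add == 0] <- 0
        epochs <- epochs + tcrossprod(a, bursts[[j]]$wave)
      }
    }
    subjects[[sid]] <- list(epochs = epochs,
                            meta = tt[, c("subject_id", "trial_index",
                                          "energy", "rating")])
    trials[[sid]] <- tt
  }

  trial_table <- do.call(rbind, trials)
  rownames(trial_table) <- NULL
  n_clip <- sum(trial_table$rating != trial_table$rating_unclipped)
  if (n_clip > 0.05 * nrow(trial_table))
    warning(sprintf("%.1f%% of ratings clipped to [0, 10]",
                    100 * n_clip / nrow(trial_table)))

  gt_masks <- eeg_ground_truth_masks(cfg, probe)
  structure(
    list(mode = "eeg", fs = cfg$fs, t0_offset_ms = cfg$epoch_ms[1],
         subjects = subjects, config = cfg,
         ground_truth = list(patterns = gt_masks, trials = trial_table)),
    class = "trial_cohort")
}

# Feature-index masks of the planted rectangles on the default analysis grid
# (the grid extract_tf_features() produces from cfg's STFT settings).
eeg_ground_truth_masks <- function(cfg, probe) {
  meta1 <- data.frame(subject_id = "probe", trial_index = 1L,
                      energy = "E1", rating = 5)
  fm1 <- extract_tf_features(list(probe), meta1)
  lapply(cfg$planted, function(p) {
    mask <- which(fm1$phase == p$phase &
                    fm1$coords$time_ms >= p$time_ms[1] &
                    fm1$coords$time_ms <= p$time_ms[2] &
                    fm1$coords$freq_hz >= p$freq_hz[1] &
                    fm1$coords$freq_hz <= p$freq_hz[2])
    list(name = p$name, phase = p$phase, sign = p$sign, d = p$d,
         spec = p, feature_mask = mask)
  })
}

# --- fMRI mode --------------------------------------------------------------

gaussian_kernel <- function(sd = 1.2, half = 2L) {
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k / sum(k)
}

# separable spatial smoothing of a 4-D array (x, y, z, scan) by circular-shift
# convolution along each spatial axis
smooth_spatial <- function(arr, kernel) {
  half <- (length(kernel) - 1L) / 2L
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    out <- array(0, dim(arr))
    for (k in -half:half) {
      idx <- ((seq_len(n) - 1L + k) %% n) + 1L
      sl <- switch(ax,
                   arr[idx, , , , drop = FALSE],
                   arr[, idx, , , drop = FALSE],
                   arr[, , idx, , drop = FALSE])
      out <- out + kernel[k + half + 1L] * sl
    }
    arr <- out
  }
  arr
}

sphere_voxels <- function(center, radius, dims) {
  rng <- lapply(1:3, function(ax)
    max(1L, floor(center[ax] - radius)):min(dims[ax], ceiling(center[ax] + radius)))
  g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  keep <- sqrt(rowSums(sweep(g, 2L, center)^2)) <= radius
  g[keep, , drop = FALSE]
}

generate_cohort_fmri <- function(cfg) {
  dims <- cfg$fmri_dims
  n_trials <- 4L * cfg$trials_per_energy
  center <- (dims + 1) / 2
  radii <- dims / 2 - 1
  g <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                             k = seq_len(dims[3])))
  inside <- rowSums(sweep(sweep(g, 2L, center), 2L, radii, `/`)^2) <= 1
  mask <- array(0L, dim = dims)
  mask[g[inside, , drop = FALSE]] <- 1L

  blob_vox <- lapply(cfg$planted, function(p) {
    v <- sphere_voxels(p$center, p$radius, dims)
    if (any(mask[v] == 0)) stop("planted blob '", p$name, "' leaves the brain mask")
    v
  })

  subjects <- list()
  trials <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%03d", s)
    scale <- exp(stats::rnorm(1, sd = cfg$subject_scale_sd))
    tt <- draw_trial_table(cfg, sid)
    isi <- stats::runif(n_trials - 1L, cfg$isi_range_s[1], cfg$isi_range_s[2])
    onsets <- 12 + c(0, cumsum(isi))
    n_scans <- ceiling((max(onsets) + (cfg$peak_lag_scans + 2) * cfg$tr_s) / cfg$tr_s)
    bold <- array(stats::rnorm(prod(dims) * n_scans), dim = c(dims, n_scans))
    bold <- smooth_spatial(bold, gaussian_kernel()) * scale

    onset_scan <- floor(onsets / cfg$tr_s) + 1L      # 1-based array index
    peak_scan <- onset_scan + cfg$peak_lag_scans
    flat <- matrix(bold, nrow = prod(dims))
    for (pi in seq_along(cfg$planted)) {
      p <- cfg$planted[[pi]]
      if (p$d == 0) next
      v <- blob_vox[[pi]]
      vlin <- v[, 1] + (v[, 2] - 1L) * dims[1] + (v[, 3] - 1L) * dims[1] * dims[2]
      scan_idx <- if (p$phase == "pre") onset_scan else peak_scan
      reg <- colMeans(flat[vlin, scan_idx, drop = FALSE])
      tau <- stats::sd(reg)
      slope <- p$d * tau
      z <- if (p$phase == "pre") tt$z_pre else tt$z_post
      add <- slope * (3 + p$sign * z)
      if (p$phase == "post") {
        eidx <- match(tt$energy, energy_levels())
        add <- add + 0.5 * slope * (eidx - 2.5)
      }
      for (i in seq_len(n_trials))
        flat[vlin, scan_idx[i]] <- flat[vlin, scan_idx[i]] + add[i]
    }
    bold <- array(flat, dim = c(dims, n_scans))
    subjects[[sid]] <- list(bold = bold, mask = mask, onsets_s = onsets,
                            tr_s = cfg$tr_s,
                            meta = tt[, c("subject_id", "trial_index",
                                          "energy", "rating")])
    trials[[sid]] <- tt
  }
  trial_table <- do.call(rbind, trials)
  rownames(trial_table) <- NULL
  n_clip <- sum(trial_table$rating != trial_table$rating_unclipped)
  if (n_clip > 0.05 * nrow(trial_table))
    warning(sprintf("%.1f%% of ratings clipped to [0, 10]",
                    100 * n_clip / nrow(trial_table)))

  mask_lin <- which(mask != 0)
  gt <- lapply(seq_along(cfg$planted), function(pi) {
    p <- cfg$planted[[pi]]
    v <- blob_vox[[pi]]
    vlin <- v[, 1] + (v[, 2] - 1L) * dims[1] + (v[, 3] - 1L) * dims[1] * dims[2]
    pos <- match(sort(vlin), mask_lin)         # feature order: pre block then post block
    mask_idx <- if (p$phase == "pre") pos else pos + length(mask_lin)
    list(name = p$name, phase = p$phase, sign = p$sign, d = p$d, spec = p,
         feature_mask = mask_idx)
  })
  structure(
    list(mode = "fmri", tr_s = cfg$tr_s, subjects = subjects, config = cfg,
         ground_truth = list(patterns = gt, trials = trial_table)),
    class = "trial_cohort")
}

#' @export
print.trial_cohort <- function(x, ...) {
  n_tr <- nrow(x$subjects[[1]]$meta)
  cat(sprintf("<trial_cohort> mode %s, %d subjects x %d trials, %d planted pattern(s)\n",
              x$mode, length(x$subjects), n_tr,
              length(x$ground_truth$patterns)))
  invisible(x)
}
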