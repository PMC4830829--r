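# Generator tests. Cohorts are kept small; the statistically demanding
# calibration checks live in the acceptance suite alongside the other
# simulation-based properties.

no_plant <- function(d = 0) default_planted_patterns(d_pre = d, d_post = d)

test_that("the same seed reproduces a cohort bit for bit", {
  cfg <- synth_config(n_subjects = 2, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$ground_truth, c2$ground_truth)
  c3 <- generate_cohort(synth_config(n_subjects = 2, seed = 78))
  expect_false(identical(c1$subjects, c3$subjects))
})

test_that("the rating decomposition sums exactly and clipping is rare", {
  co <- generate_cohort(synth_config(n_subjects = 6, seed = 42,
                                     planted = no_plant()))
  tt <- co$ground_truth$trials
  expect_identical(tt$energy_mean + tt$s_pre + tt$s_post + tt$noise,
                   tt$rating_unclipped)
  expect_identical(tt$rating, pmin(pmax(tt$rating_unclipped, 0), 10))
  expect_lt(mean(tt$rating != tt$rating_unclipped), 0.05)
  expect_true(all(tt$rating >= 0 & tt$rating <= 10))
})

test_that("per-energy rating means converge to the configured psychophysics", {
  cfg <- synth_config(n_subjects = 1, seed = 42, trials_per_energy = 500,
                      planted = no_plant())
  co <- generate_cohort(cfg)
  tt <- co$ground_truth$trials
  sem <- sqrt(0.6^2 + 0.8^2 + 1) / sqrt(500)
  for (i in 1:4) {
    got <- mean(tt$rating_unclipped[tt$energy == energy_levels()[i]])
    expect_lt(abs(got - cfg$energy_means[i]), 3 * sem)
  }
})

test_that("the pre-stimulus latent is independent of energy and can be AR(1)", {
  co <- generate_cohort(synth_config(n_subjects = 1, seed = 5,
                                     trials_per_energy = 250,
                                     planted = no_plant()))
  tt <- co$ground_truth$trials
  expect_gt(stats::kruskal.test(tt$z_pre, factor(tt$energy))$p.value, 1e-3)
  expect_lt(abs(stats::cor(tt$z_pre[-1], tt$z_pre[-1000])), 0.1)

  co_ar <- generate_cohort(synth_config(n_subjects = 1, seed = 5,
                                        trials_per_energy = 250,
                                        planted = no_plant(), ar1_phi = 0.6))
  z <- co_ar$ground_truth$trials$z_pre
  expect_lt(abs(stats::cor(z[-1], z[-length(z)]) - 0.6), 0.15)
})

test_that("planted rectangles map to valid feature masks on the analysis grid", {
  co <- generate_cohort(synth_config(n_subjects = 1, seed = 9))
  fm <- paindecode:::extract_cohort_features(co, run_config(seed = 1))[[1]]
  for (m in co$ground_truth$patterns) {
    expect_gt(length(m$feature_mask), 0)
    expect_true(all(m$feature_mask >= 1 & m$feature_mask <= ncol(fm$values)))
    expect_true(all(fm$phase[m$feature_mask] == m$phase))
    expect_true(all(fm$coords$time_ms[m$feature_mask] >= m$spec$time_ms[1] &
                      fm$coords$time_ms[m$feature_mask] <= m$spec$time_ms[2]))
    expect_true(all(fm$coords$freq_hz[m$feature_mask] >= m$spec$freq_hz[1] &
                      fm$coords$freq_hz[m$feature_mask] <= m$spec$freq_hz[2]))
  }
  expect_error(synth_config(n_subjects = 1, seed = 1, planted = list(
    list(name = "bad", phase = "pre", time_ms = c(-800, -600),
         freq_hz = c(8, 15), sign = 1L, d = 1))), "off the analysis grid")
})

test_that("burst energy concentrates in and around its declared rectangle", {
  n <- 1500
  for (p in default_planted_patterns()) {
    tones <- paindecode:::burst_tones(p$freq_hz)
    expect_true(all(tones$freqs >= p$freq_hz[1] & tones$freqs <= p$freq_hz[2]))
    wave <- paindecode:::make_burst(n, 1000, -500, p$time_ms, tones)
    sp <- compute_spectrogram(eeg_epoch(wave, 1000, -500))
    inmask <- outer(sp$freqs_hz >= p$freq_hz[1] & sp$freqs_hz <= p$freq_hz[2],
                    sp$times_ms >= p$time_ms[1] & sp$times_ms <= p$time_ms[2],
                    `&`)
    # the power-weighted centroid sits inside the rectangle and the in-mask
    # power density dominates the out-of-mask density
    tot <- sum(sp$power)
    fc <- sum(rowSums(sp$power) * sp$freqs_hz) / tot
    tc <- sum(colSums(sp$power) * sp$times_ms) / tot
    expect_true(fc >= p$freq_hz[1] && fc <= p$freq_hz[2])
    expect_true(tc >= p$time_ms[1] && tc <= p$time_ms[2])
    dens_in <- sum(sp$power[inmask]) / sum(inmask)
    dens_out <- sum(sp$power[!inmask]) / sum(!inmask)
    expect_gt(dens_in / dens_out, 10)
  }
})

test_that("a d=0 pattern leaves no region-rating association", {
  pl <- default_planted_patterns(d_pre = 0, d_post = 0)
  co <- generate_cohort(synth_config(n_subjects = 8, seed = 11, planted = pl))
  fms <- paindecode:::extract_cohort_features(co, run_config(seed = 1))
  tt <- co$ground_truth$trials
  for (m in co$ground_truth$patterns[c(1, 3)]) {
    rs <- vapply(names(fms), function(sid) {
      fm <- fms[[sid]]
      stats::cor(rowMeans(fm$values[, m$feature_mask, drop = FALSE]),
                 fm$meta$rating_norm)
    }, 0)
    expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(length(rs)))
  }
})

test_that("fMRI cohorts have valid masks, blobs, timing and planted geometry", {
  cfg <- synth_config(n_subjects = 2, seed = 21, mode = "fmri")
  co <- generate_cohort(cfg)
  s <- co$subjects[[1]]
  expect_equal(length(dim(s$bold)), 4)
  expect_true(all(dim(s$bold)[1:3] == cfg$fmri_dims))
  expect_true(all(diff(s$onsets_s) >= cfg$isi_range_s[1] &
                    diff(s$onsets_s) <= cfg$isi_range_s[2]))
  v <- sum(s$mask != 0)
  fm <- extract_bold_features(s$bold, s$mask, s$onsets_s, s$tr_s,
                              cfg$peak_lag_scans, s$meta)
  expect_equal(ncol(fm$values), 2 * v)
  for (m in co$ground_truth$patterns) {
    expect_true(all(m$feature_mask >= 1 & m$feature_mask <= 2 * v))
    expect_true(all(fm$phase[m$feature_mask] == m$phase))
  }
  # onset scans are distinct given the >= 10 s inter-stimulus interval
  expect_false(anyDuplicated(fm$meta$onset_scan) > 0)
})

test_that("planted fMRI effects express the latent with the configured sign", {
  pl <- default_planted_blobs(d_pre = 1.5, d_post = 1.5)
  co <- generate_cohort(synth_config(n_subjects = 6, seed = 31, mode = "fmri",
                                     planted = pl))
  tt <- co$ground_truth$trials
  for (m in co$ground_truth$patterns) {
    rs <- vapply(names(co$subjects), function(sid) {
      s <- co$subjects[[sid]]
      fm <- extract_bold_features(s$bold, s$mask, s$onsets_s, s$tr_s, 4L, s$meta)
      ttS <- tt[tt$subject_id == sid, ]
      z <- if (m$phase == "pre") ttS$z_pre else ttS$z_post
      zc <- z - stats::ave(z, ttS$energy)
      x <- rowMeans(fm$values[, m$feature_mask, drop = FALSE])
      xc <- x - stats::ave(x, ttS$energy)
      stats::cor(xc, zc)
    }, 0)
    expect_gt(mean(rs) * m$sign, 0.3)
  }
})
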