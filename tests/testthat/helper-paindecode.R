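# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# Minimal trial metadata for n trials cycling through the four energies; the
# default ratings vary both across and within energy groups.
make_meta <- function(n, subject = "S1", ratings = NULL) {
  data.frame(
    subject_id = subject,
    trial_index = seq_len(n),
    energy = rep(energy_levels(), length.out = n),
    rating = ratings %||% (rep(c(3, 4.5, 6.5, 8), length.out = n) +
                             rep(c(-0.8, 0.5, 0.2), length.out = n))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built spectrogram object on a small grid.
make_spec <- function(power, freqs, times) {
  structure(list(power = power, freqs_hz = freqs, times_ms = times,
                 window_ms = 200, step_ms = 10, nfft = 1024, fs = 1000),
            class = "spectrogram")
}

# Feature matrix on a tiny 2-D grid, values supplied or random.
make_tiny_fm <- function(n_trials = 8, nf = 4, nt = 6, values = NULL,
                         meta = NULL, seed = 1) {
  set.seed(seed)
  n_feat <- nf * nt
  coords <- data.frame(
    freq_hz = rep(seq_len(nf), nt), time_ms = rep(seq_len(nt) * 100 - 350, each = nf),
    fi = rep(seq_len(nf), nt), ti = rep(seq_len(nt), each = nf))
  phase <- ifelse(coords$time_ms < 0, "pre", "post")
  values <- values %||% matrix(rnorm(n_trials * n_feat), n_trials)
  paindecode:::new_feature_matrix(
    values, coords, phase, meta %||% make_meta(n_trials),
    grid = list(type = "tf", dims = c(nf, nt)))
}

# Promote a generator ground-truth entry to a pattern object, for decoding
# tests that bypass discovery.
mask_pattern <- function(m) {
  structure(list(name = m$name, phase = m$phase, features = m$feature_mask,
                 coords = NULL, sign = m$sign, cluster_p = 0.001),
            class = "pattern")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
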