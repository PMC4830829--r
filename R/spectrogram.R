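#' Construct an epoched EEG trial
#'
#' Bundles one trial's single-electrode samples with its sampling rate and the
#' latency of the first sample relative to stimulus onset. The default epoch
#' spans -500 ms to 1000 ms around the stimulus.
#'
#' @param samples Numeric vector of voltage samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param t0_offset_ms Time of the first sample relative to stimulus onset, ms.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, fs, t0_offset_ms = -500) {
  stopifnot(is.numeric(samples), length(samples) > 0L, fs > 0)
  if (any(!is.finite(samples))) stop("epoch contains non-finite samples")
  structure(
    list(samples = as.numeric(samples), fs = fs, t0_offset_ms = t0_offset_ms),
    class = "eeg_epoch"
  )
}

#' Short-time Fourier transform spectrogram of one epoch
#'
#' Computes time-frequency power with a Hann window of fixed length. Each
#' windowed segment has its time-domain mean removed before the DFT (to
#' suppress DC leakage), is Hann-tapered, zero-padded to `nfft` points and
#' transformed; power is the squared magnitude. Only windows fully contained
#' in the epoch are emitted, so no time bin mixes samples from outside the
#' epoch, and bin times are window centers. Frequencies are restricted to
#' `freq_range`.
#'
#' @param epoch An [eeg_epoch()].
#' @param window_ms Window length in ms (default 200, a 200 ms Hann window).
#' @param step_ms Hop between successive windows in ms.
#' @param freq_range Length-2 numeric, Hz; bins outside are dropped.
#' @param nfft DFT length; default is the next power of two at or above the
#'   sampling rate, giving approximately 1 Hz frequency spacing.
#' @param log_power If `TRUE`, return `log10` of power (a floor of
#'   `.Machine$double.xmin` guards exact zeros).
#' @param keep_complex If `TRUE`, also return the complex STFT coefficients
#'   (`$stft`); used where interference between signal components matters,
#'   e.g. by the synthetic-cohort generator. Incompatible with `log_power`.
#' @return An object of class `spectrogram`: list with `power` (freq x time
#'   matrix), `freqs_hz`, `times_ms` (bin centers relative to stimulus onset),
#'   `window_ms`, `step_ms`, `nfft`, `fs`.
#' @export
compute_spectrogram <- function(epoch, window_ms = 200, step_ms = 10,
                                freq_range = c(1, 100), nfft = NULL,
                                log_power = FALSE, keep_complex = FALSE) {
  stopifnot(inherits(epoch, "eeg_epoch"), window_ms > 0, step_ms > 0)
  fs <- epoch$fs
  x <- epoch$samples
  nw <- round(window_ms * fs / 1000)
  hop <- max(1L, round(step_ms * fs / 1000))
  if (length(x) < nw) stop("epoch too short for the requested window")
  if (freq_range[2] > fs / 2)
    stop("freq_range exceeds the Nyquist frequency (", fs / 2, " Hz)")
  if (is.null(nfft)) nfft <- 2^ceiling(log2(max(nw, fs)))
  if (nfft < nw) stop("nfft must be at least the window length")

  starts <- seq.int(1L, length(x) - nw + 1L, by = hop)
  # segment matrix: nw x nseg
  idx <- outer(seq_len(nw) - 1L, starts, `+`)
  seg <- matrix(x[idx], nrow = nw)
  seg <- sweep(seg, 2L, colMeans(seg))            # per-segment demeaning
  win <- e1071::hanning.window(nw)
  seg <- seg * win
  padded <- matrix(0, nrow = nfft, ncol = ncol(seg))
  padded[seq_len(nw), ] <- seg
  spec <- stats::mvfft(padded)

  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  keep <- which(freqs >= freq_range[1] & freqs <= freq_range[2])
  coef <- spec[keep, , drop = FALSE]
  power <- Mod(coef)^2
  if (log_power) {
    if (keep_complex) stop("keep_complex and log_power are incompatible")
    power <- log10(pmax(power, .Machine$double.xmin))
  }

  centers_ms <- epoch$t0_offset_ms + (starts - 1 + (nw - 1) / 2) / fs * 1000
  out <- list(power = power, freqs_hz = freqs[keep], times_ms = centers_ms,
              window_ms = window_ms, step_ms = step_ms, nfft = nfft, fs = fs)
  if (keep_complex) out$stft <- coef
  structure(out, class = "spectrogram")
}
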