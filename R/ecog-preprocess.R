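#' Construct a raw multichannel recording
#'
#' Light container for raw voltage traces prior to referencing and spectral
#' decomposition.
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param bad_channels integer indices of channels to exclude (flat/noisy).
#' @return a `raw_recording` list.
#' @export
raw_recording <- function(signal, fs, bad_channels = integer(0)) {
  stopifnot(is.matrix(signal), fs > 0)
  structure(list(signal = signal, fs = fs,
                 bad_channels = as.integer(bad_channels)),
            class = "raw_recording")
}

#' Common average referencing per electrode grid
#'
#' Subtracts, at every sample, the instantaneous mean across the channels of
#' each group (one group per implanted grid; a high-density grid is
#' referenced separately from the clinical grids). Bad channels are excluded
#' from the averages and left untouched.
#'
#' @param raw a `raw_recording`.
#' @param groups list of integer channel-index vectors partitioning the good
#'   channels; default: one group of all good channels.
#' @return a `raw_recording` with referenced signal; within each group the
#'   cross-channel mean is zero at every sample.
#' @export
common_average_reference <- function(raw, groups = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  good <- setdiff(seq_len(nrow(raw$signal)), raw$bad_channels)
  if (is.null(groups)) groups <- list(good)
  if (any(vapply(groups, length, 1L) == 0)) {
    stop("empty referencing group", call. = FALSE)
  }
  flat <- as.integer(sort(unlist(groups)))
  if (!identical(flat, as.integer(sort(good))) || anyDuplicated(flat) > 0) {
    stop("`groups` must partition the good channels", call. = FALSE)
  }
  sig <- raw$signal
  for (g in groups) {
    mu <- colMeans(sig[g, , drop = FALSE])
    sig[g, ] <- sweep(sig[g, , drop = FALSE], 2, mu)
  }
  raw$signal <- sig
  raw
}

#' Notch out line-noise frequencies
#'
#' Applies a zero-phase second-order Butterworth band-stop filter (+/- 2 Hz)
#' at each frequency in `notch_hz` to every channel.
#'
#' @param raw a `raw_recording`.
#' @param notch_hz frequencies to remove (default 50 and 100 Hz).
#' @return the filtered `raw_recording`.
#' @export
notch_filter <- function(raw, notch_hz = c(50, 100)) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$fs
  for (f0 in notch_hz) {
    if (f0 >= fs / 2) next
    bf <- signal::butter(2, c(f0 - 2, f0 + 2) / (fs / 2), type = "stop")
    for (ch in seq_len(nrow(raw$signal))) {
      raw$signal[ch, ] <- signal::filtfilt(bf, raw$signal[ch, ])
    }
  }
  raw
}

# Complex Morlet amplitude at one centre frequency via FFT convolution of the
# analytic (one-sided) spectrum. Temporal FWHM of the Gaussian envelope is
# `fwhm_cycles` wavelengths at the centre frequency.
morlet_amplitude <- function(x_fft, n, fs, f0, fwhm_cycles = 4) {
  sigma_t <- (fwhm_cycles / f0) / (2 * sqrt(2 * log(2)))
  freqs <- (seq_len(n) - 1) / n * fs
  freqs[freqs > fs / 2] <- freqs[freqs > fs / 2] - fs
  sigma_f <- 1 / (2 * pi * sigma_t)
  h <- exp(-(freqs - f0)^2 / (2 * sigma_f^2))
  h[freqs < 0] <- 0                       # analytic signal: one-sided
  Mod(stats::fft(x_fft * h, inverse = TRUE)) / n
}

#' High-frequency-band amplitude at the film frame rate
#'
#' Converts raw traces to high-frequency-band (HFB) amplitude: line-noise
#' notch filters, a complex Morlet wavelet decomposition over `band` in
#' `step`-Hz bins with a temporal full-width-at-half-maximum of
#' `wavelet_fwhm_cycles` wavelengths per centre frequency, averaging of the
#' per-bin amplitudes, and anti-alias low-pass filtering followed by
#' resampling to `out_rate`. Edges are reflect-padded; the first and last
#' second of the output are flagged as edge-affected.
#'
#' @param raw a `raw_recording` (use [common_average_reference()] first).
#' @param notch_hz line-noise frequencies to notch out (default 50 and 100 Hz).
#' @param band inclusive frequency band, default `c(60, 120)` Hz.
#' @param step bin width in Hz (default 1).
#' @param wavelet_fwhm_cycles temporal FWHM in wavelengths (default 4).
#' @param out_rate output sampling rate in Hz (default 25, the frame rate).
#' @return a `neural_recording` with non-negative `hfb`
#'   (electrodes x frames), `frame_rate = out_rate` and an `edge_frames`
#'   attribute flagging the first/last second.
#' @export
hfb_amplitude <- function(raw, notch_hz = c(50, 100), band = c(60, 120),
                          step = 1, wavelet_fwhm_cycles = 4, out_rate = 25) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$fs
  if (band[2] >= fs / 2) stop("`band` must lie below the Nyquist frequency", call. = FALSE)
  sig <- notch_filter(raw, notch_hz)$signal
  n_ch <- nrow(sig)
  n <- ncol(sig)

  pad <- round(fs)                       # 1 s reflect padding per edge
  freqs <- seq(band[1], band[2], by = step)
  amp <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    x <- c(rev(sig[ch, seq_len(pad)]), sig[ch, ],
           rev(sig[ch, seq.int(n - pad + 1, n)]))
    xf <- stats::fft(x)
    a <- numeric(length(x))
    for (f0 in freqs) a <- a + morlet_amplitude(xf, length(x), fs, f0, wavelet_fwhm_cycles)
    amp[ch, ] <- (a / length(freqs))[(pad + 1):(pad + n)]
  }

  # anti-alias low-pass, then resample at the output frame times
  lp <- signal::butter(4, (0.8 * out_rate / 2) / (fs / 2), type = "low")
  n_out <- floor(n / fs * out_rate)
  t_out <- (seq_len(n_out) - 0.5) / out_rate
  t_in <- (seq_len(n) - 0.5) / fs
  hfb <- matrix(0, n_ch, n_out)
  for (ch in seq_len(n_ch)) {
    sm <- signal::filtfilt(lp, amp[ch, ])
    hfb[ch, ] <- stats::approx(t_in, sm, xout = t_out, rule = 2)$y
  }
  hfb <- pmax(hfb, 0)

  out <- structure(list(hfb = hfb, frame_rate = out_rate, geometry = NULL),
                   class = "neural_recording")
  attr(out, "edge_frames") <- unique(c(seq_len(min(out_rate, n_out)),
                                       seq.int(max(1, n_out - out_rate + 1), n_out)))
  out
}
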