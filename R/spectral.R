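#' Complex Morlet wavelet bank
#'
#' Log-spaced center frequencies with a cycle count growing linearly from
#' `cycles[1]` at the lowest to `cycles[2]` at the highest frequency, so
#' temporal resolution tightens as frequency rises. Each wavelet
#' `exp(2 pi i f t) exp(-t^2 / (2 sigma^2))` with `sigma = cycles / (2 pi f)`
#' is tabulated over `+/- n_sd` Gaussian widths at the sampling rate and
#' normalised by its maximum value.
#'
#' @param fmin,fmax Frequency range, Hz (1-35 for EEG, 1-80 for model LFPs).
#' @param n_freqs Number of log-spaced frequencies.
#' @param fs Sampling rate, Hz.
#' @param cycles Cycle rule. A single number means cycles proportional to
#'   frequency (`cycles` cycles at `fmin`), i.e. every wavelet spans the same
#'   time-window, which with max-value normalisation gives a frequency-flat
#'   amplitude response. A length-2 vector interpolates the cycle count
#'   linearly in frequency between the two endpoints (tighter time-windows
#'   at high frequency, at the cost of boosting low-frequency power).
#' @param n_sd Half-support in Gaussian widths.
#' @return List of class `wavelet_bank`: `freqs`, `cycles`, `fs`, `wavelets`
#'   (complex vectors), `support` (samples per wavelet).
#' @export
morlet_bank <- function(fmin = 1, fmax = 35, n_freqs = 50L, fs = 500,
                        cycles = 3, n_sd = 4) {
  stopifnot(fmin > 0, fmax > fmin, n_freqs >= 2, fs > 0)
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_freqs))
  cyc <- if (length(cycles) == 1) cycles * freqs / fmin
         else cycles[1] + (cycles[2] - cycles[1]) * (freqs - fmin) /
           (fmax - fmin)
  stopifnot(!is.unsorted(cyc))
  wavelets <- vector("list", n_freqs)
  support <- integer(n_freqs)
  for (i in seq_len(n_freqs)) {
    sigma <- cyc[i] / (2 * pi * freqs[i])
    half <- ceiling(n_sd * sigma * fs)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * freqs[i] * tt) * exp(-tt^2 / (2 * sigma^2))
    wavelets[[i]] <- w / max(Mod(w))
    support[i] <- length(w)
  }
  structure(list(freqs = freqs, cycles = cyc, fs = fs, wavelets = wavelets,
                 support = support, cache = new.env(parent = emptyenv())),
            class = "wavelet_bank")
}

# FFTs of the bank's wavelets zero-padded to nfft, memoised per nfft.
bank_ffts <- function(bank, nfft) {
  key <- as.character(nfft)
  if (!is.null(bank$cache[[key]])) return(bank$cache[[key]])
  ffts <- lapply(bank$wavelets, function(w) {
    stats::fft(c(w, rep(0+0i, nfft - length(w))))
  })
  bank$cache[[key]] <- ffts
  ffts
}

#' Time-frequency power via frequency-domain wavelet convolution
#'
#' Multiplies the FFT of the signal with the FFT of each wavelet, inverts,
#' and squares the real part of the analytic result, giving power at every
#' time-frequency point. Samples within half a wavelet support of either end
#' carry edge artefacts and are flagged for exclusion from time averages.
#'
#' @param signal Numeric vector.
#' @param bank A [morlet_bank()].
#' @return List of class `tf_power`: `power` (n_freqs x n_samples), `valid`
#'   (logical, same shape), `freqs`, `fs`.
#' @export
tf_power <- function(signal, bank) {
  n <- length(signal)
  if (any(!is.finite(signal))) stop("tf_power: non-finite signal")
  if (n < max(bank$support))
    stop("tf_power: signal shorter than the lowest-frequency wavelet (",
         max(bank$support), " samples needed, ", n, " given)")
  # remove the mean: low-cycle Morlet wavelets have a small but nonzero DC
  # response (exp(-cycles^2/2)) that would otherwise contaminate the lowest
  # frequencies of offset signals such as membrane-potential LFPs
  signal <- signal - mean(signal)
  nfft <- stats::nextn(n + max(bank$support) - 1L, 2L)
  sig_fft <- stats::fft(c(signal, rep(0, nfft - n)))
  wf <- bank_ffts(bank, nfft)
  nf <- length(bank$freqs)
  power <- matrix(0, nf, n)
  valid <- matrix(TRUE, nf, n)
  for (i in seq_len(nf)) {
    conv <- stats::fft(sig_fft * wf[[i]], inverse = TRUE) / nfft
    half <- (bank$support[i] - 1L) %/% 2L
    power[i, ] <- Re(conv[(half + 1L):(half + n)])^2
    if (half > 0) valid[i, c(seq_len(half), n - seq_len(half) + 1L)] <- FALSE
  }
  structure(list(power = power, valid = valid, freqs = bank$freqs,
                 fs = bank$fs), class = "tf_power")
}

#' Time-averaged wavelet power spectrum
#'
#' [tf_power()] averaged over edge-free samples per frequency.
#'
#' @inheritParams tf_power
#' @return List of class `power_spectrum`: `freqs`, `power`.
#' @export
power_spectrum <- function(signal, bank) {
  tf <- tf_power(signal, bank)
  pw <- vapply(seq_along(tf$freqs),
               function(i) mean(tf$power[i, tf$valid[i, ]]), 0)
  structure(list(freqs = tf$freqs, power = pw), class = "power_spectrum")
}

#' Canonical frequency-band partition
#'
#' delta 1.0-4.0 Hz, theta 4.2-7.9 Hz, alpha 8.3-11.9 Hz, beta 12.4-30.6 Hz,
#' plus gamma (30.6-80 Hz) for model LFPs. The small gaps between printed
#' band edges are real: grid frequencies falling inside a gap belong to no
#' band.
#'
#' @param model Include the gamma band.
#' @return data.frame with columns `band`, `lo`, `hi` (inclusive bounds;
#'   gamma's lower bound is exclusive so beta and gamma stay disjoint).
#' @export
band_set <- function(model = FALSE) {
  b <- data.frame(band = c("delta", "theta", "alpha", "beta"),
                  lo = c(1.0, 4.2, 8.3, 12.4),
                  hi = c(4.0, 7.9, 11.9, 30.6))
  if (model) b <- rbind(b, data.frame(band = "gamma", lo = 30.6, hi = 80))
  b
}

#' Mean spectral energy per band
#'
#' Average power over the grid frequencies falling inside each band interval.
#' Bands containing no grid point yield `NA`.
#'
#' @param spectrum A [power_spectrum()] (or any list with `freqs`, `power`).
#' @param bands A [band_set()] data.frame.
#' @return Named numeric vector, one value per band.
#' @export
band_mse <- function(spectrum, bands = band_set()) {
  if (max(spectrum$freqs) < max(bands$hi) - 1e-8 ||
      min(spectrum$freqs) > min(bands$lo) + 1e-8)
    warning("spectrum does not cover all band edges")
  out <- vapply(seq_len(nrow(bands)), function(i) {
    lo_open <- bands$band[i] == "gamma"
    sel <- (if (lo_open) spectrum$freqs > bands$lo[i]
            else spectrum$freqs >= bands$lo[i]) &
      spectrum$freqs <= bands$hi[i]
    if (!any(sel)) NA_real_ else mean(spectrum$power[sel])
  }, 0)
  names(out) <- bands$band
  out
}

#' Dominant spectral peak
#'
#' Frequency of maximal power inside a search window; ties break toward the
#' lower frequency. The 6-13 Hz window brackets the alpha rhythm and its
#' pathological slowed variants.
#'
#' @param spectrum A [power_spectrum()].
#' @param search_range `c(lo, hi)` Hz, within the grid.
#' @return Peak frequency, Hz.
#' @export
dominant_peak <- function(spectrum, search_range = c(6, 13)) {
  sel <- which(spectrum$freqs >= search_range[1] &
                 spectrum$freqs <= search_range[2])
  if (!length(sel)) stop("dominant_peak: search range outside the grid")
  spectrum$freqs[sel[which.max(spectrum$power[sel])]]
}

#' Population local field potential
#'
#' Per-step mean membrane potential over the non-lesioned neurons of one
#' population.
#'
#' @param membrane_traces Matrix, neurons x time steps.
#' @param lesion_mask Logical per neuron; `TRUE` rows are excluded.
#' @return Numeric time series.
#' @export
compute_lfp <- function(membrane_traces,
                        lesion_mask = logical(nrow(membrane_traces))) {
  stopifnot(nrow(membrane_traces) == length(lesion_mask), any(!lesion_mask))
  colMeans(membrane_traces[!lesion_mask, , drop = FALSE])
}
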