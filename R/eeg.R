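#' Standard electrode montage
#'
#' The 17 electrodes of the international 10-20 system common to both
#' groups.
#' @return Character vector of labels.
#' @export
eeg_electrodes <- function() {
  c("F3", "F4", "F7", "F8", "Fz", "C3", "C4", "Cz",
    "P3", "P4", "Pz", "T3", "T4", "T5", "T6", "O1", "O2")
}

# Homologous lateral pairs swapped when mirroring a left-hemisphere lesion.
mirror_pairs <- function() {
  matrix(c("F3", "F4", "F7", "F8", "C3", "C4", "P3", "P4",
           "T3", "T4", "T5", "T6", "O1", "O2"),
         ncol = 2, byrow = TRUE)
}

#' Multichannel EEG recording container
#'
#' @param data Channels x samples matrix (microvolts); rownames must be the
#'   electrode labels.
#' @param fs Sampling rate, Hz.
#' @param group `"patient"`, `"control"` or `NA`.
#' @param lesion_side `"left"`, `"right"` or `"none"`.
#' @param subject_id Free-form identifier.
#' @return List of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs = 500, group = NA_character_,
                          lesion_side = "none", subject_id = NA_character_) {
  stopifnot(is.matrix(data), fs > 0, !is.null(rownames(data)),
            !anyDuplicated(rownames(data)))
  structure(list(data = data, fs = fs, labels = rownames(data),
                 group = group, lesion_side = lesion_side,
                 subject_id = subject_id, pipeline = character(0)),
            class = "eeg_recording")
}

#' Read a delimited-text EEG recording
#'
#' Plain-text dialect: one column per electrode with a header of labels,
#' one row per sample.
#'
#' @param path File path (tab- or comma-separated, autodetected from the
#'   header line).
#' @inheritParams eeg_recording
#' @return An [eeg_recording()].
#' @export
read_eeg_table <- function(path, fs = 500, group = NA_character_,
                           lesion_side = "none",
                           subject_id = basename(path)) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE)
  m <- t(as.matrix(d))
  eeg_recording(m, fs = fs, group = group, lesion_side = lesion_side,
                subject_id = subject_id)
}

#' Write a recording in the delimited-text dialect
#' @param recording An [eeg_recording()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_eeg_table <- function(recording, path) {
  d <- as.data.frame(t(recording$data))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bandpass filter a recording
#'
#' 2nd-order Butterworth bandpass 0.5-35 Hz (12 dB/octave asymptotic
#' roll-off per edge), applied forward and backward (zero phase), so the
#' effective attenuation is double that of a single pass while epoch timing
#' is preserved.
#'
#' @param recording An [eeg_recording()].
#' @param lo,hi Passband edges, Hz.
#' @return The filtered recording.
#' @export
bandpass <- function(recording, lo = 0.5, hi = 35) {
  fs <- recording$fs
  flt <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  recording$data <- t(apply(recording$data, 1, function(x)
    signal::filtfilt(flt, x)))
  rownames(recording$data) <- recording$labels
  recording$pipeline <- c(recording$pipeline, "bandpass")
  recording
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over all electrodes from every channel;
#' the output channel mean is exactly zero at every sample.
#'
#' @param recording An [eeg_recording()].
#' @return The re-referenced recording.
#' @export
rereference_car <- function(recording) {
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording$pipeline <- c(recording$pipeline, "car")
  recording
}

#' Extract artifact-free epochs
#'
#' Scans consecutive non-overlapping windows of `epoch_samples` from the
#' start of the recording, rejecting any window in which any channel exceeds
#' the `threshold` in absolute value, and stops after `max_epochs` accepted
#' windows or the end of the data (a shortfall triggers a warning).
#'
#' @param recording An [eeg_recording()].
#' @param epoch_samples Samples per epoch (1024 = 2048 ms at 500 Hz).
#' @param max_epochs Accepted-epoch cap.
#' @param threshold Artifact amplitude bound, microvolts.
#' @param strict Require the recording to have passed through [bandpass()]
#'   then [rereference_car()] (the orchestrator's provenance check).
#' @return List of class `epoch_set`: `epochs` (array n x channels x
#'   samples), `accepted` (flag per candidate window), `n_scanned` (windows
#'   actually examined before the cap was reached), `labels`, `fs`.
#' @export
extract_epochs <- function(recording, epoch_samples = 1024L,
                           max_epochs = 45L, threshold = 75,
                           strict = FALSE) {
  if (strict && !identical(recording$pipeline, c("bandpass", "car")))
    stop("pipeline order violated: expected bandpass -> common average ",
         "reference before epoching, got [",
         paste(recording$pipeline, collapse = ", "), "]")
  d <- recording$data
  n_cand <- ncol(d) %/% epoch_samples
  accepted <- logical(n_cand)
  kept <- list()
  scanned <- 0L
  for (w in seq_len(n_cand)) {
    if (length(kept) >= max_epochs) break
    scanned <- w
    idx <- ((w - 1L) * epoch_samples + 1L):(w * epoch_samples)
    seg <- d[, idx, drop = FALSE]
    if (max(abs(seg)) <= threshold) {
      accepted[w] <- TRUE
      kept[[length(kept) + 1L]] <- seg
    }
  }
  if (length(kept) < max_epochs)
    warning("only ", length(kept), " artifact-free epochs found (wanted ",
            max_epochs, ")")
  epochs <- if (length(kept))
    aperm(simplify2array(kept), c(3, 1, 2)) else
    array(0, dim = c(0, nrow(d), epoch_samples))
  structure(list(epochs = epochs, accepted = accepted, n_scanned = scanned,
                 labels = recording$labels, fs = recording$fs),
            class = "epoch_set")
}

#' Mirror lateral electrodes for left-hemisphere lesions
#'
#' Swaps every homologous lateral pair (F3/F4, F7/F8, C3/C4, P3/P4, T3/T4,
#' T5/T6, O1/O2) so that, across subjects, one side of the montage is always
#' ipsi-lesional; midline electrodes are untouched. Identity for
#' right-lesion and lesion-free subjects. Applying it twice is the identity.
#'
#' @param x Named vector or matrix with electrode rownames.
#' @param lesion_side `"left"`, `"right"` or `"none"`.
#' @return `x` with rows/elements swapped where appropriate.
#' @export
mirror_electrodes <- function(x, lesion_side) {
  if (!identical(lesion_side, "left")) return(x)
  nm <- if (is.matrix(x)) rownames(x) else names(x)
  stopifnot(!is.null(nm))
  perm <- seq_along(nm)
  for (i in seq_len(nrow(mirror_pairs()))) {
    a <- match(mirror_pairs()[i, 1], nm)
    b <- match(mirror_pairs()[i, 2], nm)
    if (!is.na(a) && !is.na(b)) { perm[a] <- b; perm[b] <- a }
  }
  if (is.matrix(x)) { out <- x[perm, , drop = FALSE]; rownames(out) <- nm }
  else { out <- x[perm]; names(out) <- nm }
  out
}

#' Full single-subject spectral analysis
#'
#' The fixed preprocessing order - bandpass filter, common-average
#' reference, artifact-free epoching - followed by Morlet decomposition of
#' the accepted epochs (concatenated per channel), time-averaging, and
#' channel-averaging. Also returns the per-electrode band summaries used for
#' topographic maps.
#'
#' @param recording An [eeg_recording()].
#' @param bank A [morlet_bank()]; default 1-35 Hz at the recording's rate.
#' @param max_epochs,threshold Passed to [extract_epochs()].
#' @return List of class `subject_result`: `spectrum` (channel-average),
#'   `alpha_peak` (dominant peak in 6-13 Hz), `band_mse` (named vector),
#'   `electrode_band_mse` (electrodes x bands), `n_epochs`, `group`,
#'   `lesion_side`, `subject_id`.
#' @export
analyze_subject <- function(recording, bank = NULL, max_epochs = 45L,
                            threshold = 75) {
  if (is.null(bank)) bank <- morlet_bank(1, 35, fs = recording$fs)
  rec <- rereference_car(bandpass(recording))
  eps <- extract_epochs(rec, max_epochs = max_epochs, threshold = threshold,
                        strict = TRUE)
  if (dim(eps$epochs)[1] == 0) stop("no artifact-free epochs for subject ",
                                    recording$subject_id)
  n_ch <- dim(eps$epochs)[2]
  bands <- band_set()
  per_ch <- vapply(seq_len(n_ch), function(ch) {
    sig <- as.vector(t(eps$epochs[, ch, ]))
    power_spectrum(sig, bank)$power
  }, numeric(length(bank$freqs)))
  avg <- structure(list(freqs = bank$freqs, power = rowMeans(per_ch)),
                   class = "power_spectrum")
  emse <- t(vapply(seq_len(n_ch), function(ch) {
    band_mse(structure(list(freqs = bank$freqs, power = per_ch[, ch]),
                       class = "power_spectrum"), bands)
  }, numeric(nrow(bands))))
  rownames(emse) <- eps$labels
  structure(list(spectrum = avg,
                 alpha_peak = dominant_peak(avg, c(6, 13)),
                 band_mse = band_mse(avg, bands),
                 electrode_band_mse = emse,
                 n_epochs = dim(eps$epochs)[1],
                 group = recording$group,
                 lesion_side = recording$lesion_side,
                 subject_id = recording$subject_id),
            class = "subject_result")
}

#' Group comparison of patients versus controls
#'
#' Two-sided Wilcoxon rank-sum tests on per-band mean spectral energy
#' (averaged over time and electrodes) and on dominant alpha-peak
#' frequencies, plus per-electrode band-difference maps (patient mean minus
#' control mean, with non-midline electrodes mirrored for left-lesion
#' patients so the map's right side is ipsi-lesional).
#'
#' @param patients,controls Lists of [analyze_subject()] results (>= 2
#'   each).
#' @return List of class `group_comparison`: `band_tests` (data.frame with
#'   per-band group means, s.e.m., 95% CIs, W and p), `peak_test` (same for
#'   alpha peaks), `electrode_diff` (electrodes x bands matrix),
#'   `peaks` (per-subject values by group).
#' @export
compare_groups <- function(patients, controls) {
  stopifnot(length(patients) >= 2, length(controls) >= 2)
  bands <- band_set()$band
  pm <- t(vapply(patients, `[[`, numeric(length(bands)), "band_mse"))
  cm <- t(vapply(controls, `[[`, numeric(length(bands)), "band_mse"))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  row_for <- function(p, c, label) {
    wt <- suppressWarnings(stats::wilcox.test(p, c, exact = NULL))
    data.frame(measure = label,
               patient_mean = mean(p), patient_sem = sem(p),
               patient_ci_lo = mean(p) - 1.96 * sem(p),
               patient_ci_hi = mean(p) + 1.96 * sem(p),
               control_mean = mean(c), control_sem = sem(c),
               control_ci_lo = mean(c) - 1.96 * sem(c),
               control_ci_hi = mean(c) + 1.96 * sem(c),
               W = unname(wt$statistic), p_value = wt$p.value)
  }
  band_tests <- do.call(rbind, lapply(seq_along(bands), function(i)
    row_for(pm[, i], cm[, i], bands[i])))
  pk_p <- vapply(patients, `[[`, 0, "alpha_peak")
  pk_c <- vapply(controls, `[[`, 0, "alpha_peak")
  peak_test <- row_for(pk_p, pk_c, "alpha_peak")
  mirrored <- lapply(patients, function(s)
    mirror_electrodes(s$electrode_band_mse, s$lesion_side))
  pat_map <- Reduce(`+`, mirrored) / length(mirrored)
  ctl_map <- Reduce(`+`, lapply(controls, `[[`, "electrode_band_mse")) /
    length(controls)
  structure(list(band_tests = band_tests, peak_test = peak_test,
                 electrode_diff = pat_map - ctl_map,
                 peaks = list(patients = pk_p, controls = pk_c)),
            class = "group_comparison")
}

#' Exact rank-sum enumeration (small-sample oracle)
#'
#' Two-sided Wilcoxon rank-sum p-value computed by complete enumeration of
#' all assignments of the pooled ranks, intended as an independent check of
#' the large-sample machinery for n <= 8 per group. Ties are handled by
#' midranks over the enumerated statistic distribution.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @export
ranksum_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(nx)])
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(pooled[idx]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}
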