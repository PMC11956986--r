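#' Construct an epoch set
#'
#' @param data trials x channels x samples array (uV).
#' @param fs sampling rate (Hz).
#' @param condition condition label.
#' @param onset_offset_s seconds already trimmed from stimulus onset.
#' @return An `epoch_set` list.
#' @export
epoch_set <- function(data, fs, condition = NA_character_, onset_offset_s = 0) {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = data, fs = fs, condition = condition,
                 onset_offset_s = onset_offset_s),
            class = "epoch_set")
}

#' Re-reference epochs to the average of all channels
#'
#' Subtracts, at every time sample of every trial, the instantaneous mean
#' across channels, so the channel mean is zero everywhere afterwards.
#'
#' @param epochs an [epoch_set()].
#' @return The re-referenced `epoch_set`.
#' @export
average_reference <- function(epochs) {
  d <- epochs$data
  if (dim(d)[2] < 2) stop("average reference requires >= 2 channels", call. = FALSE)
  chan_mean <- apply(d, c(1, 3), mean)            # trials x samples
  for (ch in seq_len(dim(d)[2])) d[, ch, ] <- d[, ch, ] - chan_mean
  epochs$data <- d
  epochs
}

#' Zero-phase Butterworth high-pass filter
#'
#' Forward-backward (zero-phase) Butterworth high-pass, default 0.1 Hz cutoff
#' and order 4, removing slow drift while leaving the 0.8-2.4 Hz band of
#' interest untouched (passband ripple < 1% at 2.4 Hz). The signal is
#' demeaned and padded by odd reflection before the forward-backward pass so
#' the slow filter poles (time constant of seconds at a 0.1 Hz cutoff) do
#' not leave start-up transients inside the analysis window; the padding is
#' stripped afterwards.
#'
#' @param x numeric signal, or a matrix (channels x samples, filtered
#'   row-wise).
#' @param fs sampling rate (Hz).
#' @param cutoff high-pass cutoff (Hz).
#' @param order filter order (applied twice by filtering both directions).
#' @return Filtered signal, same shape as `x`.
#' @export
highpass <- function(x, fs, cutoff = 0.1, order = 4) {
  if (fs <= 2 * cutoff) stop("fs must exceed twice the cutoff", call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  flt <- function(v) {
    n <- length(v)
    if (n < 3 * max(length(bf$a), length(bf$b)))
      stop("signal too short for the filter", call. = FALSE)
    mu <- mean(v)
    v <- v - mu
    pad <- min(n - 1L, as.integer(round(3 * fs / cutoff)))
    left <- 2 * v[1] - v[seq.int(pad + 1L, 2L)]
    right <- 2 * v[n] - v[seq.int(n - 1L, n - pad)]
    y <- signal::filtfilt(bf, c(left, v, right))
    y[seq.int(pad + 1L, pad + n)]
  }
  if (is.matrix(x)) t(apply(x, 1, flt)) else flt(x)
}

#' Extract the analysis epoch from a continuous recording
#'
#' Returns the window starting `start_offset_s` after stimulus onset and
#' lasting `length_s` (default: 1 s after onset, 32 s long).
#'
#' @param continuous channels x samples matrix (or numeric vector).
#' @param fs sampling rate (Hz).
#' @param stim_onset_s stimulus onset (s from recording start).
#' @param start_offset_s offset of the epoch from the onset (s).
#' @param length_s epoch duration (s).
#' @return Matrix (channels x `round(length_s * fs)` samples).
#' @export
epoch_extract <- function(continuous, fs, stim_onset_s = 0,
                          start_offset_s = 1, length_s = 32) {
  if (is.null(dim(continuous))) continuous <- matrix(continuous, nrow = 1)
  start <- round((stim_onset_s + start_offset_s) * fs) + 1L
  n <- round(length_s * fs)
  if (start + n - 1L > ncol(continuous))
    stop("epoch exceeds the recording", call. = FALSE)
  continuous[, seq.int(start, start + n - 1L), drop = FALSE]
}

#' Average epochs across trials
#'
#' Element-wise mean over the trial dimension; with phase-locked activity
#' this preserves the steady-state sinusoids while incoherent noise shrinks
#' as `1/sqrt(n_trials)`.
#'
#' @param epochs an [epoch_set()].
#' @return channels x samples matrix.
#' @export
trial_average <- function(epochs) {
  d <- epochs$data
  if (dim(d)[1] < 1) stop("no trials to average", call. = FALSE)
  apply(d, c(2, 3), mean)
}

#' Single-sided amplitude spectrum
#'
#' Plain DFT of the trial-averaged signal, no window or zero-padding:
#' amplitude `2|X_k|/N` for `0 < k < N/2` (DC and Nyquist unscaled by 2), so
#' a sinusoid of amplitude A at an exact bin reads A. Frequency resolution is
#' `fs/N` (1/32 Hz for 32-s epochs).
#'
#' @param avg channels x samples matrix (or numeric vector).
#' @param fs sampling rate (Hz).
#' @return An `amplitude_spectrum`: list with `freqs`, `amps` (channels x
#'   bins, uV), `delta_f`, `noise_subtracted = FALSE`.
#' @export
amplitude_spectrum <- function(avg, fs) {
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1)
  n <- ncol(avg)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  nb <- floor(n / 2) + 1L
  amps <- t(apply(avg, 1, function(v) {
    a <- Mod(stats::fft(v))[seq_len(nb)] / n
    sc <- rep(2, nb); sc[1] <- 1
    if (n %% 2 == 0) sc[nb] <- 1
    a * sc
  }))
  structure(list(freqs = (seq_len(nb) - 1) * fs / n,
                 amps = amps, delta_f = fs / n,
                 noise_subtracted = FALSE),
            class = "amplitude_spectrum")
}

#' Neighbor-bin noise subtraction
#'
#' Subtracts from every bin the mean amplitude at bin offsets {-4, -3, +3,
#' +4}: the only integer offsets whose center frequencies fall in the
#' 0.09-0.15 Hz exclusion window on each side at the 1/32 Hz resolution, and
#' exactly two bins per side. Removes the broadband background so residual
#' peaks reflect periodic signal; corrected amplitudes may be negative. Edge
#' bins use whichever of the four offsets exist.
#'
#' @param spec an [amplitude_spectrum()].
#' @param offsets integer bin offsets to average as the local noise estimate.
#' @return The corrected `amplitude_spectrum` (`noise_subtracted = TRUE`).
#' @export
noise_subtract <- function(spec, offsets = c(-4L, -3L, 3L, 4L)) {
  if (isTRUE(spec$noise_subtracted))
    stop("spectrum is already noise-subtracted", call. = FALSE)
  a <- spec$amps
  nb <- ncol(a)
  corr <- a
  for (k in seq_len(nb)) {
    nbrs <- k + offsets
    nbrs <- nbrs[nbrs >= 1 & nbrs <= nb]
    corr[, k] <- a[, k] - rowMeans(a[, nbrs, drop = FALSE])
  }
  spec$amps <- corr
  spec$noise_subtracted <- TRUE
  spec
}

#' SSEP amplitude at a target frequency
#'
#' Averages the amplitude at the three bins centered on the bin nearest the
#' target frequency (`k = round(f0 / delta_f)`, banker's rounding), per
#' channel, and returns the unweighted mean across channels alongside.
#'
#' @param spec an [amplitude_spectrum()] (normally noise-subtracted).
#' @param f0 target frequency (Hz).
#' @return List with `per_channel` (uV) and `average` (scalar uV).
#' @export
target_amplitude <- function(spec, f0) {
  k <- round(f0 / spec$delta_f) + 1L       # 1-based bin index
  nb <- ncol(spec$amps)
  if (k - 1L < 1L || k + 1L > nb)
    stop("target frequency outside the spectrum", call. = FALSE)
  per_ch <- rowMeans(spec$amps[, (k - 1L):(k + 1L), drop = FALSE])
  list(per_channel = per_ch, average = mean(per_ch))
}

#' Full SSEP pipeline for one epoch set
#'
#' average reference -> zero-phase high-pass (on the concatenated trial
#' signal, trial-wise) -> epoch extraction (1-33 s) -> trial average ->
#' amplitude spectrum -> neighbor-bin noise subtraction -> 3-bin target
#' amplitudes at 0.8/1.2/1.6/2.4 Hz, averaged over channels.
#'
#' @param epochs an [epoch_set()] holding raw trials from stimulus onset.
#' @param target_freqs frequencies of interest (Hz).
#' @param start_offset_s,length_s epoching window relative to onset.
#' @param hp_cutoff,hp_order high-pass parameters; `hp_cutoff = NULL` skips
#'   filtering (e.g. for pre-cleaned or noiseless input).
#' @return Named numeric vector of channel-averaged SSEP amplitudes (uV).
#' @export
ssep_amplitudes <- function(epochs, target_freqs = ssep_frequencies(),
                            start_offset_s = 1, length_s = 32,
                            hp_cutoff = 0.1, hp_order = 4) {
  ep <- average_reference(epochs)
  d <- ep$data
  n_tr <- dim(d)[1]
  epoched <- NULL
  for (tr in seq_len(n_tr)) {
    x <- d[tr, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (!is.null(hp_cutoff)) x <- highpass(x, ep$fs, hp_cutoff, hp_order)
    e <- epoch_extract(x, ep$fs, stim_onset_s = -ep$onset_offset_s,
                       start_offset_s = start_offset_s, length_s = length_s)
    if (is.null(epoched))
      epoched <- array(0, dim = c(n_tr, nrow(e), ncol(e)))
    epoched[tr, , ] <- e
  }
  avg <- trial_average(epoch_set(epoched, ep$fs, ep$condition))
  spec <- noise_subtract(amplitude_spectrum(avg, ep$fs))
  vapply(target_freqs, function(f) target_amplitude(spec, f)$average,
         numeric(1))
}

#' Tidy SSEP estimates for a simulated (or ingested) dataset
#'
#' Runs the full pipeline for every `lab_XX/sub_YY/epochs_<condition>.rds`
#' under `data_dir` and returns one row per subject, condition and target
#' frequency. Subjects missing a condition are flagged in the `complete`
#' attribute rather than silently dropped.
#'
#' @param data_dir dataset root (layout of [simulate_multilab()]).
#' @param target_freqs frequencies of interest (Hz).
#' @param ... passed to [ssep_amplitudes()].
#' @return data.frame: `lab_id, subject_id, condition, frequency_hz,
#'   amplitude_uv`.
#' @export
subject_ssep_table <- function(data_dir, target_freqs = ssep_frequencies(), ...) {
  rows <- list(); incomplete <- character(0)
  labs <- sort(list.dirs(data_dir, recursive = FALSE))
  for (lab_dir in labs) {
    subs <- sort(list.dirs(lab_dir, recursive = FALSE))
    for (sdir in subs) {
      for (cond in c("control", "binary", "ternary")) {
        f <- file.path(sdir, paste0("epochs_", cond, ".rds"))
        if (!file.exists(f)) {
          incomplete <- c(incomplete, paste(basename(lab_dir),
                                            basename(sdir), cond))
          next
        }
        ep <- readRDS(f)
        amps <- ssep_amplitudes(ep, target_freqs, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          lab_id = basename(lab_dir), subject_id = basename(sdir),
          condition = cond, frequency_hz = target_freqs,
          amplitude_uv = unname(amps), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "incomplete") <- incomplete
  out
}
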