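#' Configuration for the synthetic multi-lab generator
#'
#' Defines the study conditions the generator emulates: a multi-lab sample
#' (13 labs, 12 subjects each by default), per-condition trial counts
#' (10 imagery / 12 control), and the population distribution of SSEP
#' amplitudes at the four frequencies of interest. Defaults mirror the
#' cross-lab descriptive pattern: a stimulus-frequency (2.4 Hz) amplitude of
#' about 0.07 uV, near-zero amplitudes at the imagery frequencies in the
#' control task, and an imagery-congruent increment of about 0.03 uV at the
#' imagined-beat frequency (1.2 Hz for binary, 0.8 Hz for ternary imagery).
#'
#' @param n_labs number of labs.
#' @param subjects_per_lab subjects per lab.
#' @param trials_imagery,trials_control trials per imagery / control block.
#' @param n_channels EEG channels.
#' @param fs sampling rate (Hz).
#' @param trial_duration_s recorded trial duration (s); epochs of 32 s
#'   starting 1 s post-onset are cut from it downstream.
#' @param amp_base baseline SSEP amplitude (uV) at the imagery frequencies.
#' @param amp_stim SSEP amplitude (uV) at the stimulus frequency (2.4 Hz).
#' @param amp_increment imagery-congruent amplitude increment (uV) added at
#'   the imagined-beat frequency.
#' @param amp_sd between-subject SD (uV) of every amplitude cell.
#' @param meas_sd within-subject SD (uV) of a measured amplitude around the
#'   subject's true value (residual spectral noise after trial averaging and
#'   noise subtraction); used by the amplitude-level simulator.
#' @param pink_alpha exponent of the 1/f^alpha background noise.
#' @param pink_sd,white_sd SDs (uV) of the pink and white noise added per
#'   channel and trial.
#' @param music_years_rate,dance_years_rate rate parameters of the
#'   exponential distributions for years of music / dance training.
#' @param behavior_coefs named list of logistic coefficients used by
#'   [simulate_behavior()]: `intercept`, `beta_amp_imagery`,
#'   `beta_amp_stimulus` (per uV), `beta_probe_off` (probe OFF vs ON).
#' @param rating_cutpoints ordered-logit cutpoints for the 1-7 imagery
#'   success rating.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_labs = 13, subjects_per_lab = 12,
                       trials_imagery = 10, trials_control = 12,
                       n_channels = 64, fs = 1000, trial_duration_s = 36,
                       amp_base = 0.0, amp_stim = 0.07,
                       amp_increment = 0.03, amp_sd = 0.02,
                       meas_sd = 0.05,
                       pink_alpha = 1.0, pink_sd = 15, white_sd = 5,
                       music_years_rate = 1 / 4, dance_years_rate = 1 / 2,
                       behavior_coefs = list(intercept = 0.5,
                                             beta_amp_imagery = 0,
                                             beta_amp_stimulus = 10,
                                             beta_probe_off = 0),
                       rating_cutpoints = c(-3, -2, -1, 0, 1, 2)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_labs >= 1, cfg$subjects_per_lab >= 1,
            cfg$trials_imagery >= 1, cfg$trials_control >= 1,
            cfg$n_channels >= 1, cfg$amp_sd >= 0, cfg$meas_sd >= 0,
            cfg$pink_alpha >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' The four frequencies of interest
#'
#' Ternary beat (0.8 Hz), binary beat (1.2 Hz), first ternary harmonic
#' (1.6 Hz) and stimulus (2.4 Hz).
#' @return Numeric vector of frequencies (Hz).
#' @export
ssep_frequencies <- function() c(0.8, 1.2, 1.6, 2.4)

#' Population mean SSEP amplitude for one condition/frequency cell
#'
#' The generating counterpart of the lab summary table: baseline amplitude at
#' the imagery frequencies, `amp_stim` at 2.4 Hz, plus the imagery-congruent
#' increment at 1.2 Hz under binary imagery and at 0.8 Hz under ternary
#' imagery.
#'
#' @param cfg a [sim_config()].
#' @param condition `"control"`, `"binary"` or `"ternary"`.
#' @param frequency one of 0.8, 1.2, 1.6, 2.4 (Hz).
#' @return Mean amplitude in uV.
#' @export
cell_mean <- function(cfg, condition, frequency) {
  base <- if (frequency == 2.4) cfg$amp_stim else cfg$amp_base
  inc <- (condition == "binary" && frequency == 1.2) ||
         (condition == "ternary" && frequency == 0.8)
  base + if (inc) cfg$amp_increment else 0
}

rtruncnorm0 <- function(n, mean, sd) {
  # truncated-at-zero normal via inverse CDF; degenerates to `mean` when sd=0
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Draw one subject's generating parameters
#'
#' Each subject gets one baseline SSEP amplitude per frequency, drawn from a
#' truncated-at-zero normal around the configured baseline mean (shared
#' across conditions, reflecting subject-level gain factors such as anatomy
#' and electrode impedance), plus the deterministic imagery-congruent
#' increment in the matching condition cells. Sharing the baseline across
#' conditions keeps the within-subject condition contrast exactly equal to
#' the injected increment in expectation, which an independent
#' truncated-at-zero draw per cell would not (truncation near zero biases
#' the contrast). SSEP phases are uniform on `[0, 2pi)` and constant across
#' trials (steady-state, phase-locked assumption); training years are
#' exponential.
#'
#' @param cfg a [sim_config()].
#' @param lab_id lab identifier.
#' @param subject_id subject identifier.
#' @return A `subject_params` list with `ssep_amp` (3 conditions x 4
#'   frequencies matrix, uV), `ssep_phase`, `music_years`, `dance_years`.
#' @export
draw_subject <- function(cfg, lab_id, subject_id = 1L) {
  conds <- c("control", "binary", "ternary")
  freqs <- ssep_frequencies()
  amp <- matrix(0, 3, 4, dimnames = list(conds, paste0(freqs)))
  base <- vapply(freqs, function(f)
    rtruncnorm0(1, cell_mean(cfg, "control", f), cfg$amp_sd), numeric(1))
  for (cn in conds) for (j in seq_along(freqs))
    amp[cn, j] <- base[j] +
      (cell_mean(cfg, cn, freqs[j]) - cell_mean(cfg, "control", freqs[j]))
  structure(list(
    subject_id = subject_id, lab_id = lab_id,
    ssep_amp = amp,
    ssep_phase = stats::setNames(stats::runif(4, 0, 2 * pi), paste0(freqs)),
    music_years = stats::rexp(1, cfg$music_years_rate),
    dance_years = stats::rexp(1, cfg$dance_years_rate),
    noise_scale = cfg$pink_sd,
    behavior_coefs = cfg$behavior_coefs
  ), class = "subject_params")
}

#' Generate 1/f^alpha ("pink") noise by spectral shaping
#'
#' White Gaussian noise is transformed to the frequency domain, its spectrum
#' scaled by `1/f^(alpha/2)` above a 0.1 Hz floor (flat below, so power does
#' not diverge at DC), and transformed back. The output is zero-mean and
#' rescaled to the requested standard deviation.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate (Hz).
#' @param alpha spectral exponent (>= 0); `alpha = 0` gives white noise.
#' @param sd target standard deviation.
#' @return Numeric vector of length `n_samples`.
#' @export
make_pink_noise <- function(n_samples, fs, alpha = 1, sd = 1) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  x <- stats::rnorm(n_samples)
  X <- stats::fft(x)
  f <- seq(0, n_samples - 1) * fs / n_samples
  f <- pmin(f, fs - f)            # fold to [0, fs/2]
  f <- pmax(f, 0.1)               # flat below the 0.1 Hz floor
  scale <- f^(-alpha / 2)
  scale[1] <- 0                   # remove DC
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n_samples
  y <- y - mean(y)
  if (stats::sd(y) > 0) y <- y * (sd / stats::sd(y))
  y
}

#' Simulate an epoch set of raw EEG trials for one subject and condition
#'
#' Each trial is the sum of phase-locked sinusoids at 0.8/1.2/1.6/2.4 Hz with
#' the subject's condition-specific amplitudes, projected to the channels
#' through a spatial gain map, plus independent pink and white noise per
#' channel and trial. Trials start at stimulus onset (t = 0), so downstream
#' epoching (1-33 s) is exercised.
#'
#' The default gain map alternates +1/-1 across channels (zero spatial mean,
#' unit magnitude): average-referenced EEG has zero-sum topographies by
#' construction, so this choice makes the average-reference step of the
#' pipeline exact (it neither removes nor distorts the signal) and the
#' channel-averaged amplitude estimate recovers the injected amplitude. A
#' spatially uniform gain map would be annihilated by average referencing.
#'
#' @param subj a [draw_subject()] result.
#' @param condition `"control"`, `"binary"` or `"ternary"`.
#' @param cfg a [sim_config()].
#' @param channel_gains optional per-channel gain vector (recycled /
#'   truncated to `n_channels`).
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array, uV), `fs`, `condition`, `onset_offset_s = 0`.
#' @export
simulate_epochs <- function(subj, condition, cfg, channel_gains = NULL) {
  n_trials <- if (condition == "control") cfg$trials_control else cfg$trials_imagery
  n <- round(cfg$trial_duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  freqs <- ssep_frequencies()
  sig <- rep(0, n)
  for (j in seq_along(freqs))
    sig <- sig + subj$ssep_amp[condition, j] *
      sin(2 * pi * freqs[j] * t + subj$ssep_phase[j])
  if (is.null(channel_gains)) {
    g <- rep_len(c(1, -1), cfg$n_channels)
    g <- g - mean(g)
    if (mean(abs(g)) > 0) g <- g / mean(abs(g))
  } else {
    g <- rep_len(channel_gains, cfg$n_channels)
  }
  dat <- array(0, dim = c(n_trials, cfg$n_channels, n))
  for (tr in seq_len(n_trials)) for (ch in seq_len(cfg$n_channels)) {
    noise <- 0
    if (cfg$pink_sd > 0)
      noise <- make_pink_noise(n, cfg$fs, cfg$pink_alpha, cfg$pink_sd)
    if (cfg$white_sd > 0)
      noise <- noise + stats::rnorm(n, 0, cfg$white_sd)
    dat[tr, ch, ] <- g[ch] * sig + noise
  }
  epoch_set(dat, cfg$fs, condition)
}

#' Score a probe-task response
#'
#' A binary probe is "ON beat" during binary imagery only, and a ternary
#' probe is "ON beat" during ternary imagery only; a response is correct when
#' it matches that mapping.
#'
#' @param imagery_type `"binary"` or `"ternary"`.
#' @param probe_type `"binary"` or `"ternary"` (which beat the probe fell on).
#' @param response `"ON"` or `"OFF"`.
#' @return 1 if correct, 0 otherwise.
#' @export
score_probe <- function(imagery_type, probe_type, response) {
  truth <- ifelse(probe_type == imagery_type, "ON", "OFF")
  as.integer(response == truth)
}

#' Simulate trial-level behavior for one subject and imagery condition
#'
#' Accuracy is Bernoulli with success probability
#' `plogis(intercept + beta_amp_imagery * amp_imagery +
#' beta_amp_stimulus * amp_stimulus + beta_probe_off * (probe == "ternary-ON"...))`;
#' the imagery success rating comes from an ordered-logit cutpoint model on
#' the same linear predictor.
#'
#' @param subj a [draw_subject()] result.
#' @param imagery_type `"binary"` or `"ternary"`.
#' @param trial_amp_imagery per-trial amplitudes (uV) at the imagined-beat
#'   frequency; recycled to the number of trials.
#' @param trial_amp_stimulus per-trial amplitudes (uV) at 2.4 Hz.
#' @param probe_type per-trial probe positions (`"binary"`/`"ternary"`);
#'   default alternates.
#' @param n_trials number of test trials.
#' @return A data.frame with one row per trial: `lab_id, subject_id,
#'   condition, trial, probe_type, accuracy, rating, amp_imagery,
#'   amp_stimulus`.
#' @export
simulate_behavior <- function(subj, imagery_type,
                              trial_amp_imagery, trial_amp_stimulus,
                              probe_type = NULL, n_trials = 10) {
  cf <- subj$behavior_coefs
  if (is.null(probe_type))
    probe_type <- rep(c("binary", "ternary"), length.out = n_trials)
  ai <- rep_len(trial_amp_imagery, n_trials)
  as_ <- rep_len(trial_amp_stimulus, n_trials)
  off <- as.numeric(probe_type != imagery_type)   # probe OFF the imagined beat
  eta <- cf$intercept + cf$beta_amp_imagery * ai +
    cf$beta_amp_stimulus * as_ + cf$beta_probe_off * off
  acc <- stats::rbinom(n_trials, 1, stats::plogis(eta))
  # ordered-logit rating on 1..7
  cuts <- c(-Inf, subj$behavior_coefs$rating_cutpoints %||%
              c(-3, -2, -1, 0, 1, 2), Inf)
  u <- stats::rlogis(n_trials, location = eta)
  rating <- findInterval(u, cuts[-c(1, length(cuts))]) + 1L
  data.frame(lab_id = subj$lab_id, subject_id = subj$subject_id,
             condition = imagery_type, trial = seq_len(n_trials),
             probe_type = probe_type, accuracy = acc, rating = rating,
             amp_imagery = ai, amp_stimulus = as_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete multi-lab dataset on disk
#'
#' Writes `lab_XX/sub_YY/epochs_<condition>.rds` (trials x channels x samples
#' arrays with fs/condition/units attributes) plus one `behavior.csv` and
#' `participants.csv` per lab. Fully reproducible from the RNG state: set a
#' seed before calling.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param write_epochs write the (large) epoch arrays? Set `FALSE` to produce
#'   only the CSVs and subject parameter table.
#' @return Invisibly, a list with `participants` and `behavior` data frames
#'   and the per-subject true amplitude table `truth`.
#' @export
simulate_multilab <- function(cfg, out_dir, write_epochs = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  part_all <- list(); beh_all <- list(); truth <- list()
  for (lab in seq_len(cfg$n_labs)) {
    lab_id <- sprintf("lab_%02d", lab)
    lab_dir <- file.path(out_dir, lab_id)
    part <- list(); beh <- list()
    for (s in seq_len(cfg$subjects_per_lab)) {
      sub_id <- sprintf("sub_%02d", s)
      subj <- draw_subject(cfg, lab_id, sub_id)
      sdir <- file.path(lab_dir, sub_id)
      if (write_epochs) dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      for (cond in c("control", "binary", "ternary")) {
        if (write_epochs) {
          ep <- simulate_epochs(subj, cond, cfg)
          saveRDS(ep, file.path(sdir, paste0("epochs_", cond, ".rds")))
        }
      }
      for (im in c("binary", "ternary")) {
        amp_i <- subj$ssep_amp[im, if (im == "binary") "1.2" else "0.8"]
        amp_s <- subj$ssep_amp[im, "2.4"]
        beh[[paste(s, im)]] <- simulate_behavior(
          subj, im,
          trial_amp_imagery = amp_i, trial_amp_stimulus = amp_s,
          n_trials = cfg$trials_imagery)
      }
      part[[s]] <- data.frame(lab_id = lab_id, subject_id = sub_id,
                              tested = TRUE, excluded_reason = "none",
                              music_years = subj$music_years,
                              dance_years = subj$dance_years,
                              stringsAsFactors = FALSE)
      truth[[paste(lab, s)]] <- data.frame(
        lab_id = lab_id, subject_id = sub_id,
        condition = rep(rownames(subj$ssep_amp), 4),
        frequency_hz = rep(ssep_frequencies(), each = 3),
        amplitude_uv = as.vector(subj$ssep_amp),
        stringsAsFactors = FALSE)
    }
    part <- do.call(rbind, part)
    beh <- do.call(rbind, beh)
    dir.create(lab_dir, showWarnings = FALSE, recursive = TRUE)
    write_participants(part, file.path(lab_dir, "participants.csv"))
    write_behavior(beh, file.path(lab_dir, "behavior.csv"))
    part_all[[lab]] <- part; beh_all[[lab]] <- beh
  }
  invisible(list(participants = do.call(rbind, part_all),
                 behavior = do.call(rbind, beh_all),
                 truth = do.call(rbind, truth)))
}
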