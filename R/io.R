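#' Apply the participant and lab-size exclusion rules
#'
#' Two-phase filtering: individually excluded participants (any
#' `excluded_reason` other than `"none"`) are dropped first; then every lab
#' whose remaining sample is below `min_lab_n` is dropped entirely, its
#' members marked `lab_too_small`. An audit log counts exclusions per
#' reason.
#'
#' @param participants data.frame with at least `lab_id, subject_id,
#'   excluded_reason`.
#' @param min_lab_n minimum per-lab sample after individual exclusions.
#' @return List: `included` (data.frame), `excluded` (data.frame with final
#'   reasons), `audit` (named counts per reason).
#' @export
apply_exclusions <- function(participants, min_lab_n = 8) {
  p <- participants
  reasons <- c("none", "failed_training", "artifacts_gt_50pct",
               "experimenter_error", "rhythmic_movement", "lab_too_small")
  bad <- setdiff(unique(p$excluded_reason), reasons)
  if (length(bad))
    stop("unknown exclusion reason(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  indiv <- p$excluded_reason != "none"
  kept <- p[!indiv, , drop = FALSE]
  lab_n <- table(kept$lab_id)
  small <- names(lab_n)[lab_n < min_lab_n]
  lab_small <- kept$lab_id %in% small
  kept$excluded_reason[lab_small] <- "lab_too_small"
  excluded <- rbind(p[indiv, , drop = FALSE], kept[lab_small, , drop = FALSE])
  included <- kept[!lab_small, , drop = FALSE]
  audit <- table(factor(excluded$excluded_reason, levels = reasons[-1]))
  list(included = included, excluded = excluded,
       audit = c(as.list(audit), list(included = nrow(included),
                                      tested = nrow(p))))
}

csv_check <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

fmt_num <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  df
}

#' Readers and writers for the pipeline's tabular schemas
#'
#' Schema-checked RFC 4180 CSV I/O; floats are written with 6 significant
#' digits. Readers raise an error naming any missing column.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return The data.frame (readers) or `path` invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_participants <- function(df, path) {
  csv_check(df, c("lab_id", "subject_id", "excluded_reason",
                  "music_years", "dance_years"), "participants")
  utils::write.csv(fmt_num(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_participants <- function(path) {
  csv_check(utils::read.csv(path, stringsAsFactors = FALSE),
            c("lab_id", "subject_id", "excluded_reason",
              "music_years", "dance_years"), "participants")
}

#' @rdname pipeline_io
#' @export
write_behavior <- function(df, path) {
  csv_check(df, c("lab_id", "subject_id", "condition", "trial",
                  "probe_type", "accuracy", "rating"), "behavior")
  utils::write.csv(fmt_num(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_behavior <- function(path) {
  csv_check(utils::read.csv(path, stringsAsFactors = FALSE),
            c("lab_id", "subject_id", "condition", "trial",
              "probe_type", "accuracy", "rating"), "behavior")
}

#' @rdname pipeline_io
#' @export
write_ssep_estimates <- function(df, path) {
  csv_check(df, c("lab_id", "subject_id", "condition", "frequency_hz",
                  "amplitude_uv"), "ssep_estimates")
  utils::write.csv(fmt_num(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ssep_estimates <- function(path) {
  csv_check(utils::read.csv(path, stringsAsFactors = FALSE),
            c("lab_id", "subject_id", "condition", "frequency_hz",
              "amplitude_uv"), "ssep_estimates")
}

#' Read the packaged lab summary fixture
#'
#' A transcription of the published per-lab descriptive table: for each of
#' the 14 labs, total tested/included counts and the mean (SD) amplitude of
#' brain activity (uV) at 0.8/1.2/1.6/2.4 Hz under the control, binary- and
#' ternary-imagery conditions. One row per lab x condition x frequency
#' (14 x 3 x 4 = 168 rows).
#'
#' @param path fixture path; defaults to the copy shipped in the package.
#' @return data.frame: `lab, total_tested, total_included, condition,
#'   frequency_hz, mean_uv, sd_uv`.
#' @export
read_table1_fixture <- function(path = system.file("extdata",
                                                   "table1_fixture.csv",
                                                   package = "beatssep")) {
  csv_check(utils::read.csv(path, stringsAsFactors = FALSE),
            c("lab", "total_tested", "total_included", "condition",
              "frequency_hz", "mean_uv", "sd_uv"), "table1_fixture")
}

#' Run the full synthetic-study pipeline
#'
#' Simulate a multi-lab dataset, extract SSEP amplitudes, run per-lab
#' statistics, pool the four imagery effects (means and medians, with and
#' without moderators), and fit the trial-level accuracy regression. All
#' randomness flows from `seed`, so two runs with the same configuration and
#' seed produce identical reports.
#'
#' @param cfg a [sim_config()]; small settings recommended (the EEG stage is
#'   the expensive part).
#' @param seed integer seed.
#' @param out_dir working directory for the simulated dataset and outputs.
#' @param run_eeg run the EEG extraction stage (`FALSE` uses the generator's
#'   subject amplitudes plus measurement noise, the amplitude-level
#'   shortcut).
#' @return List: `ssep`, `labstats`, `meta` (per effect x statistic x
#'   moderator), `trial`, `seed`, `config`.
#' @export
run_all <- function(cfg, seed, out_dir = tempfile("beatssep_"),
                    run_eeg = FALSE) {
  set.seed(seed)
  sim <- simulate_multilab(cfg, out_dir, write_epochs = run_eeg)
  if (run_eeg) {
    ssep <- subject_ssep_table(out_dir)
  } else {
    truth <- sim$truth
    truth$amplitude_uv <- truth$amplitude_uv +
      stats::rnorm(nrow(truth), 0, cfg$meas_sd)
    ssep <- truth
  }
  write_ssep_estimates(ssep, file.path(out_dir, "ssep_estimates.csv"))
  # per-lab RM-ANOVAs at each frequency
  labstats <- list()
  for (f0 in ssep_frequencies()) {
    sub <- ssep[ssep$frequency_hz == f0, ]
    for (lab in unique(sub$lab_id)) {
      wide <- stats::reshape(
        sub[sub$lab_id == lab, c("subject_id", "condition", "amplitude_uv")],
        idvar = "subject_id", timevar = "condition", direction = "wide")
      m <- as.matrix(wide[, -1])
      an <- rm_anova_oneway(m)
      labstats[[paste(lab, f0)]] <- data.frame(
        lab_id = lab, frequency_hz = f0, F = an$F, df1 = an$df1,
        df2 = an$df2, p = an$p, partial_eta2 = an$partial_eta2,
        epsilon_gg = an$epsilon_gg, stringsAsFactors = FALSE)
    }
  }
  labstats <- do.call(rbind, c(labstats, make.row.names = FALSE))
  # the 24 pooled analyses: 4 effects x {mean, median} x {none, music, dance}
  meta <- list()
  for (en in effect_definitions()$effect_name) {
    for (st in c("mean", "median")) {
      eff <- lab_effects(ssep, en, statistic = st,
                         participants = sim$participants)
      meta[[paste(en, st, "none", sep = ".")]] <- re_meta(eff)
      for (mod in c("music_years_mean", "dance_years_mean"))
        meta[[paste(en, st, mod, sep = ".")]] <-
          meta_regression(eff, mod)
    }
  }
  beh <- sim$behavior
  beh$imagery_type <- beh$condition
  part <- sim$participants
  beh <- merge(beh, part[, c("lab_id", "subject_id", "music_years",
                             "dance_years")],
               by = c("lab_id", "subject_id"))
  trial <- trial_regression(beh)
  list(ssep = ssep, labstats = labstats, meta = meta, trial = trial,
       seed = seed, config = cfg)
}

#' Write a pipeline report as JSON
#'
#' @param results a [run_all()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  meta <- lapply(results$meta, function(m)
    m[c("estimate", "tau2", "Q", "df_Q", "I2", "H2", "method", "k")])
  out <- list(seed = results$seed,
              labstats = results$labstats,
              meta = meta,
              trial = results$trial$terms)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
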