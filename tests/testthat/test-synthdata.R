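test_that("subject draws degenerate to the configured cell means when SD is zero", {
  cfg <- sim_config(amp_sd = 0)
  subj <- draw_subject(cfg, "lab_01")
  expect_equal(unname(subj$ssep_amp["control", ]), c(0, 0, 0, 0.07))
  expect_equal(unname(subj$ssep_amp["binary", ]), c(0, 0.03, 0, 0.07))
  expect_equal(unname(subj$ssep_amp["ternary", ]), c(0.03, 0, 0, 0.07))
})

test_that("subject draws are deterministic under a fixed seed and unbiased in the mean", {
  cfg <- sim_config()
  set.seed(11); s1 <- draw_subject(cfg, "lab_01")
  set.seed(11); s2 <- draw_subject(cfg, "lab_01")
  expect_identical(s1, s2)
  # Monte-Carlo mean of the stimulus-frequency cell over many subjects
  set.seed(12)
  draws <- replicate(4000, draw_subject(cfg, "lab_01")$ssep_amp["control", "2.4"])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.07), 3 * se)
  expect_true(all(draws >= 0))
})

test_that("pink noise has the requested spectral slope and is zero-mean", {
  set.seed(21)
  n <- 4096; fs <- 100
  # averaged periodogram over realizations, log-log slope over 0.5-50 Hz
  psd_sum <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    x <- make_pink_noise(n, fs, alpha = 1)
    psd_sum <- psd_sum + Mod(stats::fft(x))[2:(n / 2)]^2
  }
  freqs <- (1:(n / 2 - 1)) * fs / n
  keep <- freqs >= 0.5 & freqs <= 50
  slope <- coef(lm(log(psd_sum[keep] / reps) ~ log(freqs[keep])))[2]
  expect_lt(abs(slope + 1), 0.1)
  x <- make_pink_noise(n, fs, alpha = 1)
  expect_lt(abs(mean(x)), 1e-10)  # mean removed by construction
  # alpha = 0 limit: flat spectrum (slope ~ 0)
  psd_sum <- 0
  for (i in seq_len(100)) {
    x <- make_pink_noise(n, fs, alpha = 0)
    psd_sum <- psd_sum + Mod(stats::fft(x))[2:(n / 2)]^2
  }
  slope0 <- coef(lm(log(psd_sum[keep] / 100) ~ log(freqs[keep])))[2]
  expect_lt(abs(slope0), 0.1)
  expect_error(make_pink_noise(100, 100, alpha = -1))
})

test_that("simulated epoch sets have the contracted shape", {
  cfg <- sim_config(n_labs = 1, subjects_per_lab = 1, n_channels = 3,
                    fs = 100, trial_duration_s = 4, trials_imagery = 5,
                    trials_control = 6, pink_sd = 0, white_sd = 1)
  set.seed(31)
  subj <- draw_subject(cfg, "lab_01")
  ep <- simulate_epochs(subj, "binary", cfg)
  expect_equal(dim(ep$data), c(5, 3, 400))
  ep_c <- simulate_epochs(subj, "control", cfg)
  expect_equal(dim(ep_c$data)[1], 6)
})

test_that("noiseless epochs recover injected amplitudes through the pipeline to oracle precision", {
  cfg <- sim_config(n_channels = 2, fs = 200, pink_sd = 0, white_sd = 0,
                    amp_sd = 0, trials_imagery = 2)
  set.seed(41)
  subj <- draw_subject(cfg, "lab_01")
  ep <- simulate_epochs(subj, "binary", cfg)
  est <- ssep_amplitudes(ep, hp_cutoff = NULL)
  oracle <- oracle_ssep(A = unname(subj$ssep_amp["binary", ]),
                        f = ssep_frequencies(),
                        phi = unname(subj$ssep_phase),
                        fs = 200, target_freqs = ssep_frequencies())
  expect_equal(unname(est), oracle, tolerance = 1e-9)
})

test_that("phase-locked trials average coherently, randomized phases do not", {
  fs <- 100; n <- 32 * fs; n_tr <- 20
  t <- (seq_len(n) - 1) / fs
  set.seed(51)
  coh <- array(0, dim = c(n_tr, 2, n))
  inc <- array(0, dim = c(n_tr, 2, n))
  for (tr in seq_len(n_tr)) {
    coh[tr, 1, ] <- sin(2 * pi * 1.2 * t + 0.7)
    coh[tr, 2, ] <- -coh[tr, 1, ]
    ph <- runif(1, 0, 2 * pi)
    inc[tr, 1, ] <- sin(2 * pi * 1.2 * t + ph)
    inc[tr, 2, ] <- -inc[tr, 1, ]
  }
  amp_coh <- amplitude_spectrum(trial_average(epoch_set(coh, fs)), fs)
  amp_inc <- amplitude_spectrum(trial_average(epoch_set(inc, fs)), fs)
  k <- round(1.2 / amp_coh$delta_f) + 1
  expect_gt(mean(amp_coh$amps[, k]), 0.7)      # coherent: near the off-bin leakage value
  expect_lt(mean(amp_inc$amps[, k]), 0.4)      # incoherent: shrunk toward 0
})

test_that("behavioral generator matches its logistic model in the null and degenerate cases", {
  cfg <- sim_config()
  set.seed(61)
  subj <- draw_subject(cfg, "lab_01")
  subj$behavior_coefs <- list(intercept = 0, beta_amp_imagery = 0,
                              beta_amp_stimulus = 0, beta_probe_off = 0)
  beh <- simulate_behavior(subj, "binary", 0.03, 0.07, n_trials = 4000)
  expect_lt(abs(mean(beh$accuracy) - 0.5), 3 * sqrt(0.25 / 4000))
  expect_true(all(beh$rating %in% 1:7))
  # degenerate rating model: all cutpoints far below the linear predictor
  subj$behavior_coefs$rating_cutpoints <- rep(-1e6, 6)
  beh7 <- simulate_behavior(subj, "binary", 0.03, 0.07, n_trials = 50)
  expect_true(all(beh7$rating == 7))
})

test_that("probe scoring follows the ON-beat mapping", {
  expect_equal(score_probe("binary", "binary", "ON"), 1L)
  expect_equal(score_probe("binary", "ternary", "ON"), 0L)
  expect_equal(score_probe("binary", "ternary", "OFF"), 1L)
  expect_equal(score_probe("ternary", "ternary", "ON"), 1L)
})

test_that("multi-lab simulation writes a reproducible dataset tree", {
  cfg <- sim_config(n_labs = 2, subjects_per_lab = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  set.seed(71); sim1 <- simulate_multilab(cfg, d1, write_epochs = FALSE)
  set.seed(71); sim2 <- simulate_multilab(cfg, d2, write_epochs = FALSE)
  expect_equal(length(list.dirs(d1, recursive = FALSE)), 2)
  expect_equal(nrow(sim1$participants), 6)
  for (f in c("lab_01/participants.csv", "lab_01/behavior.csv",
              "lab_02/behavior.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(sim1$truth, sim2$truth)
})
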