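test_that("average reference zeroes the channel mean and is idempotent", {
  # two channels: closed form [(a-b)/2, (b-a)/2]
  a <- sin(seq(0, 10, length.out = 200)); b <- cos(seq(0, 10, length.out = 200))
  ep <- epoch_set(array(c(a, b), dim = c(1, 2, 200))* NA, 100)
  ep$data[1, 1, ] <- a; ep$data[1, 2, ] <- b
  rr <- average_reference(ep)
  expect_equal(rr$data[1, 1, ], (a - b) / 2, tolerance = 1e-12)
  expect_equal(rr$data[1, 2, ], (b - a) / 2, tolerance = 1e-12)
  rr2 <- average_reference(rr)
  expect_equal(rr2$data, rr$data, tolerance = 1e-12)
  # random 8-channel input: channel mean is zero at machine precision
  set.seed(1)
  ep8 <- epoch_set(array(rnorm(2 * 8 * 500), dim = c(2, 8, 500)), 100)
  rr8 <- average_reference(ep8)
  expect_lt(max(abs(apply(rr8$data, c(1, 3), mean))), 1e-10)
  expect_error(average_reference(epoch_set(array(1, dim = c(1, 1, 10)), 100)),
               "2 channels")
})

test_that("zero-phase high-pass rejects DC and slow drift but preserves the band of interest", {
  fs <- 200
  const <- rep(2, 40 * fs)
  out <- highpass(const, fs)
  expect_lt(max(abs(out)), 1e-3 * 2)
  t <- (seq_len(40 * fs) - 1) / fs
  x24 <- sin(2 * pi * 2.4 * t)
  y24 <- highpass(x24, fs)
  mid <- (8 * fs):(32 * fs)
  expect_lt(abs(sqrt(mean(y24[mid]^2)) / sqrt(mean(x24[mid]^2)) - 1), 0.01)
  fs2 <- 20
  t2 <- (seq_len(400 * fs2) - 1) / fs2
  slow <- sin(2 * pi * 0.01 * t2)
  yslow <- highpass(slow, fs2)
  mid2 <- (100 * fs2):(300 * fs2)
  expect_lt(sqrt(mean(yslow[mid2]^2)) / sqrt(mean(slow[mid2]^2)), 0.1)
  expect_error(highpass(1:5, fs = 100), "too short")
})

test_that("epoch extraction returns the 1-33 s window with the documented resolution", {
  fs <- 1000
  x <- matrix(seq_len(40 * fs), nrow = 1)
  e <- epoch_extract(x, fs)
  expect_equal(ncol(e), 32000)
  expect_equal(1000 / 32000 * 32, 1)  # delta_f = fs/N = 1/32 Hz
  expect_equal(e[1, 1], fs + 1)       # starts 1 s after onset
  e2 <- epoch_extract(x, fs, stim_onset_s = 3, start_offset_s = 1)
  expect_equal(e2[1, 1], 4 * fs + 1)
  fs2 <- 1024
  e3 <- epoch_extract(matrix(seq_len(40 * fs2), nrow = 1), fs2)
  expect_equal(ncol(e3), 32768)
  expect_error(epoch_extract(matrix(1:100, nrow = 1), 100), "exceeds")
})

test_that("trial averaging is the element-wise mean with 1/sqrt(n) noise shrinkage", {
  set.seed(2)
  x <- matrix(rnorm(3 * 50), 3, 50)
  same <- epoch_set(array(rep(x, each = 4), dim = c(4, 3, 50)) * 0, 100)
  for (tr in 1:4) same$data[tr, , ] <- x
  expect_equal(trial_average(same), x, tolerance = 1e-12)
  anti <- epoch_set(array(0, dim = c(2, 3, 50)), 100)
  anti$data[1, , ] <- x; anti$data[2, , ] <- -x
  expect_equal(max(abs(trial_average(anti))), 0)
  # noise shrinkage: residual SD of a 10-trial average of unit noise
  set.seed(3)
  noisy <- epoch_set(array(rnorm(10 * 1 * 20000), dim = c(10, 1, 20000)), 100)
  avg <- trial_average(noisy)
  expect_lt(abs(sd(avg) - 1 / sqrt(10)), 0.02)
})

test_that("amplitude spectrum is exact on-bin and matches the Dirichlet oracle off-bin", {
  fs <- 100; N <- 3200
  t <- (seq_len(N) - 1) / fs
  # exact bin: 2 Hz = 64 * delta_f
  x <- 0.1 * sin(2 * pi * 2 * t + 0.3)
  sp <- amplitude_spectrum(x, fs)
  k <- round(2 / sp$delta_f) + 1
  expect_equal(sp$amps[1, k], 0.1, tolerance = 1e-10)
  expect_lt(max(sp$amps[1, -k][-1]), 1e-10)
  # constant input: DC bin only
  spc <- amplitude_spectrum(rep(3, N), fs)
  expect_equal(spc$amps[1, 1], 3, tolerance = 1e-12)
  expect_lt(max(abs(spc$amps[1, -1])), 1e-10)
  # off-bin 2.4 Hz over 32 s: full-bin agreement with the closed-form oracle
  y <- 0.1 * sin(2 * pi * 2.4 * t + 1.1)
  spy <- amplitude_spectrum(y, fs)
  oracle <- dirichlet_spectrum(0.1, 2.4, 1.1, fs, N)
  expect_equal(unname(spy$amps[1, ]), oracle, tolerance = 1e-9)
})

test_that("neighbor-bin subtraction removes flat background and leaves isolated lines", {
  flat <- structure(list(freqs = (0:99) * 0.03125, delta_f = 0.03125,
                         amps = matrix(2, 1, 100), noise_subtracted = FALSE),
                    class = "amplitude_spectrum")
  out <- noise_subtract(flat)
  expect_lt(max(abs(out$amps)), 1e-12)
  expect_error(noise_subtract(out), "already")
  peak <- flat; peak$amps <- matrix(0, 1, 100); peak$amps[1, 50] <- 0.7
  outp <- noise_subtract(peak)
  expect_equal(outp$amps[1, 50], 0.7)
  for (o in c(-4, -3, 3, 4)) expect_equal(outp$amps[1, 50 + o], -0.7 / 4)
  expect_equal(outp$amps[1, 40], 0)
})

test_that("3-bin target amplitude matches the oracle, scales linearly, and is zero on silence", {
  fs <- 200; N <- 32 * fs
  t <- (seq_len(N) - 1) / fs
  x <- 0.05 * sin(2 * pi * 1.2 * t + 0.4)
  sp <- noise_subtract(amplitude_spectrum(x, fs))
  est <- target_amplitude(sp, 1.2)
  oracle <- oracle_target(dirichlet_spectrum(0.05, 1.2, 0.4, fs, N),
                          fs / N, 1.2)
  expect_equal(est$average, oracle, tolerance = 1e-9)
  sp2 <- noise_subtract(amplitude_spectrum(2 * x, fs))
  expect_equal(target_amplitude(sp2, 1.2)$average, 2 * est$average,
               tolerance = 1e-9)
  zero <- noise_subtract(amplitude_spectrum(rep(0, N), fs))
  expect_equal(target_amplitude(zero, 1.2)$average, 0)
  expect_error(target_amplitude(sp, 150), "outside")
})

test_that("the tidy subject table runs the full chain and is invariant to trial order", {
  cfg <- sim_config(n_labs = 1, subjects_per_lab = 2, n_channels = 2,
                    fs = 200, pink_sd = 0, white_sd = 0, amp_sd = 0.01,
                    trials_imagery = 2, trials_control = 2)
  dir <- withr::local_tempdir()
  set.seed(5)
  simulate_multilab(cfg, dir, write_epochs = TRUE)
  tab <- subject_ssep_table(dir, hp_cutoff = NULL)
  expect_equal(nrow(tab), 2 * 3 * 4)  # 2 subjects x 3 conditions x 4 freqs
  expect_setequal(unique(tab$condition), c("control", "binary", "ternary"))
  # permute trials of one file: estimates unchanged
  f <- file.path(dir, "lab_01", "sub_01", "epochs_binary.rds")
  ep <- readRDS(f)
  ep$data <- ep$data[c(2, 1), , , drop = FALSE]
  saveRDS(ep, f)
  tab2 <- subject_ssep_table(dir, hp_cutoff = NULL)
  expect_equal(tab2$amplitude_uv, tab$amplitude_uv, tolerance = 1e-12)
})

test_that("the pipeline is homogeneous of degree one in input scaling", {
  cfg <- sim_config(n_labs = 1, subjects_per_lab = 1, n_channels = 2,
                    fs = 200, pink_sd = 2, white_sd = 1, trials_imagery = 2)
  set.seed(6)
  subj <- draw_subject(cfg, "lab_01")
  ep <- simulate_epochs(subj, "binary", cfg)
  ep3 <- ep; ep3$data <- 3 * ep$data
  a1 <- ssep_amplitudes(ep, hp_cutoff = NULL)
  a3 <- ssep_amplitudes(ep3, hp_cutoff = NULL)
  expect_equal(unname(a3), 3 * unname(a1), tolerance = 1e-9)
})
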