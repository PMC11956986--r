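#!/usr/bin/env Rscript
# Simulate a small multi-lab EEG + behavior dataset with the statistical
# structure the analysis assumes: phase-locked sinusoidal SSEPs at
# 0.8/1.2/1.6/2.4 Hz in 1/f-plus-white noise, an imagery-congruent 0.03 uV
# increment, and trial-level probe behavior. Scaled down from the full study
# (4 labs x 8 subjects, 8 channels, 200 Hz, 4-5 trials) so the whole
# workflow runs in minutes; the generator's defaults hold the full study
# conditions. The noise SDs are scaled with the reduced trial count,
# channel count and epoch sample count so the per-bin spectral noise after
# trial averaging keeps the signal-to-noise ratio of the full-size design:
# an SSEP is only readable in the amplitude spectrum when the residual
# per-bin noise amplitude sits at or below the sub-microvolt signal.

library(beatssep)

set.seed(20260301)
cfg <- sim_config(n_labs = 4, subjects_per_lab = 8, n_channels = 8,
                  fs = 200, trials_imagery = 4, trials_control = 5,
                  pink_sd = 0.5, white_sd = 0.25)

out <- "scratch/simdata"
unlink(out, recursive = TRUE)
sim <- simulate_multilab(cfg, out, write_epochs = TRUE)

cat("Labs:", cfg$n_labs, " subjects/lab:", cfg$subjects_per_lab, "\n")
cat("Participants:", nrow(sim$participants), "\n")
cat("Behavior trials:", nrow(sim$behavior), "\n")
cat("Mean probe accuracy:", round(mean(sim$behavior$accuracy), 3), "\n")
cat("Dataset written to", out, "\n")
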