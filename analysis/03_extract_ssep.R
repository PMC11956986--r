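#!/usr/bin/env Rscript
# Extract SSEP amplitudes from the simulated epochs: average reference,
# 0.1 Hz zero-phase high-pass, 1-33 s epoch, trial average, DFT amplitude
# spectrum (1/32 Hz resolution), neighbor-bin noise subtraction, 3-bin
# estimates at 0.8/1.2/1.6/2.4 Hz averaged over channels.

library(beatssep)

ssep <- subject_ssep_table("scratch/simdata")
write_ssep_estimates(ssep, "results/ssep_estimates.csv")

cat("Estimates:", nrow(ssep), "rows",
    "(", length(unique(paste(ssep$lab_id, ssep$subject_id))), "subjects x 3",
    "conditions x 4 frequencies )\n")
agg <- aggregate(amplitude_uv ~ condition + frequency_hz, ssep, mean)
print(agg, row.names = FALSE)
cat("Wrote results/ssep_estimates.csv\n")
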