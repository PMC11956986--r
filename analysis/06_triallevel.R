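#!/usr/bin/env Rscript
# Trial-level logistic regression predicting probe-task accuracy from the
# neural amplitudes (imagined-beat frequency and stimulus frequency) plus
# lab, training and probe-type covariates, with cluster-robust standard
# errors by subject; then the per-imagery-condition variant.

library(beatssep)

beh <- do.call(rbind, lapply(
  list.files("scratch/simdata", "behavior.csv", recursive = TRUE,
             full.names = TRUE), read_behavior))
parts <- do.call(rbind, lapply(
  list.files("scratch/simdata", "participants.csv", recursive = TRUE,
             full.names = TRUE), read_participants))

beh$imagery_type <- beh$condition
rec <- merge(beh, parts[, c("lab_id", "subject_id", "music_years",
                            "dance_years")],
             by = c("lab_id", "subject_id"))

fit <- trial_regression(rec)
cat("Trials:", fit$n_used, " converged:", fit$converged, "\n\n")
print(fit$terms, row.names = FALSE, digits = 3)
write.csv(fit$terms, "results/triallevel_full.csv", row.names = FALSE)

fits <- fit_by_imagery(rec)
for (im in names(fits)) {
  f <- file.path("results", paste0("triallevel_", im, ".csv"))
  write.csv(fits[[im]]$terms, f, row.names = FALSE)
  amp <- fits[[im]]$terms[fits[[im]]$terms$term == "amp_stimulus", ]
  cat(sprintf("\n%s imagery: stimulus-frequency amplitude Wald chi2 = %.3f, p = %.3f\n",
              im, amp$wald_chi2, amp$p))
}
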