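#!/usr/bin/env Rscript
# Stage 3: latency-window classification.
#
# Reads the stage-1 tables, converts ground-truth saccades to event form,
# and applies the window rules: latency in [0, FP + 100) is early, >= FP +
# 100 is a visually guided candidate, then excluded if slower than 1000 ms
# after go, after an early saccade, or landing outside the target box.

library(saccmix)

indir <- "results/simulation"
outdir <- "results/classification"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ex <- list(trials = read_tsv(file.path(indir, "trials.tsv")),
           truth = read_tsv(file.path(indir, "truth.tsv")))
events <- truth_to_events(ex)
classified <- classify_experiment(ex$trials, events)
write_tsv(classified, file.path(outdir, "classified_events.tsv"))

audit <- boundary_rule_audit(classified, n_trials = nrow(ex$trials))
cat("category counts:\n")
print(audit$category_counts)
cat("rejection reasons:\n")
print(audit$reason_counts)
cat(sprintf("early-saccade trials: %.1f%%  (paradigm guide: ~10%%)\n",
            100 * audit$early_trial_fraction))
cat(sprintf("surviving VG trials:  %.1f%%  (paradigm guide: ~78%%)\n",
            100 * audit$vg_trial_fraction))
cat("classified events written to", outdir, "\n")
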