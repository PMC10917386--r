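#!/usr/bin/env Rscript
# 02 — Apply the phenotype exclusion criteria per sample.
#
# Mirrors the cohort's row-level exclusions (handedness, FIQ, scan
# length, peak motion, mean FD, missing score) followed by the
# minimum-site-size rule, and tabulates who was excluded and why.

source("analysis/config.R")

ds <- make_dataset()
excl <- NULL
kept <- 0
for (sm in unique(ds$pheno$sample)) {
  fr <- filter_subjects(ds$pheno[ds$pheno$sample == sm, ], filter_config())
  kept <- kept + length(fr$included)
  if (nrow(fr$excluded)) {
    excl <- rbind(excl, cbind(sample = sm, fr$excluded))
  }
}
if (is.null(excl)) excl <- data.frame(sample = character(),
                                      subject_id = character(),
                                      reason = character())
write.csv(excl, file.path(RESULTS, "02_exclusions.csv"),
          row.names = FALSE, quote = FALSE)

cat("Kept", kept, "of", nrow(ds$pheno), "subjects.\n")
if (nrow(excl)) print(table(excl$sample, excl$reason))
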