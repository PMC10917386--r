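#!/usr/bin/env Rscript
# 05 — Transfer the negative consensus networks to independent samples.
#
# Refits each score's negative-network model on the full model sample,
# applies it unchanged to the validation patients (replication: expect
# r > 0) and to the healthy controls (specificity: expect a null
# result), and adjusts p values with BH-FDR within each sample family.

source("analysis/config.R")

prep <- prepare_analysis_set()
ph <- prep$pheno
model_rows <- ph$sample == "model"
cov_model <- covariate_matrix(ph[model_rows, ])

tab <- NULL
for (score in SCORES) {
  col <- paste0("score_", score)
  b <- ph[[col]][model_rows]
  fit <- loocv_cpm(prep$edges[model_rows, ], b, cov_model,
                   p_threshold = P_THRESHOLD, tails = "neg")
  tm <- transfer_model(prep$edges[model_rows, ], b, fit$consensus$neg)
  for (sm in c("validation", "control")) {
    rows <- ph$sample == sm & !is.na(ph[[col]])
    vr <- external_validate(tm, prep$edges[rows, ], ph[[col]][rows],
                            covariate_matrix(ph[rows, ]), sm)
    tab <- rbind(tab, data.frame(score = score, sample = sm, n = vr$n,
                                 df = vr$df, r = round(vr$r, 4),
                                 p = signif(vr$p, 4)))
  }
}
tab$p_fdr <- NA
for (sm in unique(tab$sample)) {
  fam <- tab$sample == sm
  tab$p_fdr[fam] <- signif(fdr_bh(tab$p[fam]), 4)
}
write.csv(tab, file.path(RESULTS, "05_validation.csv"),
          row.names = FALSE, quote = FALSE)

cat("Replication (validation patients) and specificity (controls):\n")
print(tab, row.names = FALSE)
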