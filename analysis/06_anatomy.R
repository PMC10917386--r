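#!/usr/bin/env Rscript
# 06 — Summarize the anatomy of the negative predictive networks.
#
# Reads the consensus masks written by 04, computes node degrees and the
# 6 x 6 within/between-network edge counts, and lists the highest-degree
# nodes — the plot-ready tables behind circle/glass-brain figures.

source("analysis/config.R")

atlas <- make_dataset()$atlas
for (score in SCORES) {
  mask_file <- file.path(RESULTS, paste0("04_consensus_", score, ".txt"))
  if (!file.exists(mask_file)) {
    stop("run analysis/04_cpm.R first (missing ", mask_file, ")")
  }
  mask <- read_edge_mask(mask_file)
  mask[mask == 1L] <- 0L   # negative network only
  sm <- summarize_network(mask, atlas)
  out <- file.path(RESULTS, paste0("06_anatomy_", score))
  write_network_summary(sm, atlas, out)
  top <- rank_nodes(sm, atlas, top_k = 5)
  cat(sprintf("\n%s: %d negative consensus edges; top nodes by degree:\n",
              score, sm$n_edges))
  print(top, row.names = FALSE)
  cat("network-pair counts written to", out, "\n")
}
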