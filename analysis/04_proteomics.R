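#!/usr/bin/env Rscript
# Label-free interaction-proteomics enrichment on the synthetic
# proteinGroups table: Perseus-style cleanup, 4-of-4 valid-value filter,
# downshifted imputation, two-sided t-test volcano, SILAC H/L ratio
# enrichment, and an iBAQ-style stoichiometry readout for the strongest
# hits. Recovery is scored against the planted interactor list.
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(txrecover))
msg <- function(...) message(sprintf(...))

res <- run_proteomics_pipeline("results/data/proteomics_config.yaml")

v <- res$volcano
truth <- readLines("results/data/proteomics_truth.txt")
hits <- v$protein[v$p_value < 0.05 & v$log2_fc > 0]
msg("proteins tested: %d; volcano hits (p < 0.05, enriched in UV): %d",
    nrow(v), length(hits))
msg("planted interactors recovered: %d / %d (sensitivity %.2f)",
    length(intersect(hits, truth)), length(truth),
    length(intersect(hits, truth)) / length(truth))
fp <- setdiff(hits, truth)
msg("false positives among %d background proteins: %d",
    nrow(v) - length(intersect(truth, v$protein)), length(fp))

if (!is.null(res$silac)) {
  n_enr <- sum(res$silac$enriched)
  msg("SILAC: %d proteins with >= 2-fold H/L enrichment (of %d)",
      n_enr, nrow(res$silac))
  msg("  planted overlap: %d / %d",
      length(intersect(res$silac$protein[res$silac$enriched], truth)),
      length(truth))
}
msg("outputs: results/proteomics/")
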