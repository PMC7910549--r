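#!/usr/bin/env Rscript
# Builds the synthetic study: a replicated ChIP cohort (mock + two UV
# doses + input), nascent-RNA tracks at 3 h post-UV, and a label-free
# proteomics matrix with planted UV-specific interactors. Everything is
# written as plain text under results/data/ together with YAML configs
# consumed by the downstream analysis scripts.

suppressPackageStartupMessages(library(txrecover))

seed <- 2026L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
msg <- function(...) message(sprintf(...))

## ChIP cohort: 40 genes, 2 mock + 2 UV replicates per dose + input ---------
sim <- simulate_catalog(40, c(4000, 20000), spacing = 4000, seed = seed)
write_catalog_bed(sim$catalog, file.path(data_dir, "genes.bed"))
write_chrom_sizes(sim$chrom_sizes, file.path(data_dir, "chrom.sizes"))
model <- occupancy_model()

# release fraction and lesion density both scale with dose
conds <- list(
  mock_1 = condition_spec("mock_1"),
  mock_2 = condition_spec("mock_2"),
  uv6_1 = condition_spec("uv6_1", release_fraction = 0.45,
                         damage_spacing = damage_spacing_for_dose(6)),
  uv6_2 = condition_spec("uv6_2", release_fraction = 0.45,
                         damage_spacing = damage_spacing_for_dose(6)),
  uv9_1 = condition_spec("uv9_1", release_fraction = 0.675,
                         damage_spacing = damage_spacing_for_dose(9)),
  uv9_2 = condition_spec("uv9_2", release_fraction = 0.675,
                         damage_spacing = damage_spacing_for_dose(9))
)
released <- sim$catalog$gene_id[1:20]  # half the cohort responds to UV
for (i in seq_along(conds)) {
  lib <- simulate_chip_library(sim$catalog, sim$chrom_sizes, model,
                               conds[[i]], depth = 1e5, seed = seed + i,
                               release_genes = released)
  write_fragment_bed(lib, file.path(data_dir,
                                    paste0(names(conds)[i], ".bed")))
  msg("ChIP library %s: %d fragments", names(conds)[i], nrow(lib$fragments))
}
input <- simulate_chip_library(
  sim$catalog, sim$chrom_sizes,
  occupancy_model(pause_height = 0, body_level = 0, tts_height = 0,
                  background = 1),
  condition_spec("input"), depth = 5e4, seed = seed + 20)
write_fragment_bed(input, file.path(data_dir, "input.bed"))
writeLines(as.character(sim$catalog$gene_id %in% released),
           file.path(data_dir, "released_truth.txt"))

chip_cfg <- list(
  annotation = file.path(data_dir, "genes.bed"),
  chrom_sizes = file.path(data_dir, "chrom.sizes"),
  samples = lapply(names(conds), function(nm)
    list(name = nm, fragments = file.path(data_dir, paste0(nm, ".bed")),
         condition = sub("_[0-9]$", "", nm),
         input = file.path(data_dir, "input.bed"))),
  outdir = "results/chip",
  params = list(min_len = 3000, max_len = 100000, flank = 2000,
                tr_preset = "RNAPII", span = c(-2000, 5000), bin_size = 50,
                mock_samples = c("mock_1", "mock_2"),
                comparisons = list(c("uv6_1", "mock_1"),
                                   c("uv6_2", "mock_2"),
                                   c("uv9_1", "mock_1"),
                                   c("uv9_2", "mock_2")),
                seed = seed)
)
yaml::write_yaml(chip_cfg, file.path(data_dir, "chip_config.yaml"))

## BrU-seq: 12 long genes, mock and 3 h post-UV ------------------------------
bsim <- simulate_catalog(12, c(30000, 45000), spacing = 12000,
                         seed = seed + 30)
write_catalog_bed(bsim$catalog, file.path(data_dir, "bru_genes.bed"))
write_chrom_sizes(bsim$chrom_sizes, file.path(data_dir, "bru_chrom.sizes"))
mock <- simulate_bru_track(bsim$catalog, bsim$chrom_sizes, 0,
                           condition_spec("mock"), depth = 5e5,
                           seed = seed + 31)
uv3h <- simulate_bru_track(bsim$catalog, bsim$chrom_sizes, 3,
                           condition_spec("uv", damage_spacing = 16000),
                           depth = 5e5, seed = seed + 32)
write_bedgraph(mock$track, file.path(data_dir, "bru_mock.bedGraph"))
write_bedgraph(uv3h$track, file.path(data_dir, "bru_uv3h.bedGraph"))
writeLines(c("condition\ttimepoint\tfraction",
             "mock\t0h\t1.0",
             sprintf("uv\t3h\t%.6f", uv3h$nascent_level)),
           file.path(data_dir, "bru_nascent_levels.tsv"))
msg("BrU 3 h genome-wide nascent fraction: %.3f", uv3h$nascent_level)

bru_cfg <- list(
  annotation = file.path(data_dir, "bru_genes.bed"),
  chrom_sizes = file.path(data_dir, "bru_chrom.sizes"),
  nascent_levels = file.path(data_dir, "bru_nascent_levels.tsv"),
  samples = list(
    list(name = "mock", coverage = file.path(data_dir, "bru_mock.bedGraph"),
         mapped_count = mock$mapped_count, condition = "mock",
         timepoint = "0h"),
    list(name = "uv3h", coverage = file.path(data_dir, "bru_uv3h.bedGraph"),
         mapped_count = uv3h$mapped_count, condition = "uv",
         timepoint = "3h")),
  outdir = "results/bruseq",
  params = list(span = c(-5000, 25000), bin_size = 500, min_rpkm = 0.05,
                tss_spacing = 10000, length_bounds = c(25000, 50000),
                threshold = 0.5, seed = seed)
)
yaml::write_yaml(bru_cfg, file.path(data_dir, "bruseq_config.yaml"))

## Proteomics: 400 proteins, 40 planted UV interactors -----------------------
sigma_matrix <- sqrt(2^2 + 0.5^2)
prot <- simulate_intensity_matrix(400, 40, 2 * sigma_matrix,
                                  seed = seed + 40)
lin <- 2^prot$matrix$intensities
lin[is.na(lin)] <- 0
df <- data.frame(`Protein IDs` = rownames(lin), check.names = FALSE)
for (s in colnames(lin)) df[[paste("LFQ intensity", s)]] <- lin[, s]
# H/L ratios echo the planted enrichment for the SILAC arm of the workflow
df[["Ratio H/L"]] <- withr::with_seed(seed + 41,
  round(ifelse(prot$truth, 2^(2 * sigma_matrix), 1) *
          2^rnorm(400, 0, 0.2), 4))
df$Reverse <- ""
df[["Potential contaminant"]] <- ""
df[["Only identified by site"]] <- ""
pg_path <- file.path(data_dir, "proteingroups_synthetic.tsv")
write.table(df, pg_path, sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(names(prot$truth)[prot$truth],
           file.path(data_dir, "proteomics_truth.txt"))
msg("proteomics matrix: %d x %d, %.1f%% missing", nrow(lin), ncol(lin),
    100 * mean(lin == 0))

prot_cfg <- list(
  proteingroups = pg_path,
  design = as.list(setNames(unname(prot$design), names(prot$design))),
  groups = c("uv", "mock"),
  outdir = "results/proteomics",
  params = list(min_valid = 4, shift = 1.8, width = 0.3,
                silac_threshold = 2, seed = seed)
)
yaml::write_yaml(prot_cfg, file.path(data_dir, "proteomics_config.yaml"))
msg("configs written under %s", data_dir)
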