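# Shared miniature ChIP study written to disk once per test file: 6 genes,
# one mock / one UV sample plus a shared input library.
build_chip_config <- function(root, seed = 101, depth = 3e4) {
  sim <- simulate_catalog(6, c(5000, 9000), spacing = 5000, seed = seed)
  model <- occupancy_model()
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  bed <- file.path(root, "genes.bed")
  write_catalog_bed(sim$catalog, bed)
  cs <- file.path(root, "chrom.sizes")
  write_chrom_sizes(sim$chrom_sizes, cs)
  conds <- list(mock = condition_spec("mock"),
                uv = condition_spec("uv", release_fraction = 0.6,
                                    damage_spacing = 16000))
  paths <- list()
  for (nm in names(conds)) {
    lib <- simulate_chip_library(sim$catalog, sim$chrom_sizes, model,
                                 conds[[nm]], depth, seed = seed + match(nm, names(conds)))
    paths[[nm]] <- file.path(root, paste0(nm, ".bed"))
    write_fragment_bed(lib, paths[[nm]])
  }
  input <- simulate_chip_library(sim$catalog, sim$chrom_sizes,
                                 occupancy_model(pause_height = 0,
                                                 body_level = 0,
                                                 tts_height = 0,
                                                 background = 1),
                                 condition_spec("input"), depth %/% 2,
                                 seed = seed + 10)
  inp <- file.path(root, "input.bed")
  write_fragment_bed(input, inp)
  list(
    annotation = bed, chrom_sizes = cs,
    samples = list(
      list(name = "mock", fragments = paths$mock, condition = "mock",
           input = inp),
      list(name = "uv", fragments = paths$uv, condition = "uv",
           input = inp)),
    outdir = file.path(root, "out"),
    params = list(min_len = 3000, max_len = 100000, flank = 2000,
                  tr_preset = "RNAPII", span = c(-2000, 4000),
                  bin_size = 100, seed = 1)
  )
}

test_that("the ChIP pipeline writes every advertised output with a manifest", {
  root <- withr::local_tempdir()
  cfg <- build_chip_config(root)
  res <- run_chip_pipeline(cfg)
  out <- cfg$outdir
  for (f in c("catalog_selected.bed", "traveling_ratios.tsv",
              "fraction_above_one.tsv", "shift_calls.tsv",
              "metaprofiles.tsv", "redistribution.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$stages$catalog$n_in, 6)
  expect_gt(manifest$stages$traveling_ratio$n_rows, 0)
  expect_true(all(c("ALL_SHIFT", "MIXED_SHIFT", "unclassifiable") %in%
                    names(manifest$stages$shift_classification)))
  # the UV condition releases polymerase: its mean normalized tr exceeds mock
  tab <- res$tr_table
  expect_gt(mean(tab$normalized_tr[tab$sample == "uv" & tab$finite]),
            mean(tab$normalized_tr[tab$sample == "mock" & tab$finite]))
})

test_that("the ChIP pipeline validates inputs before computing", {
  root <- withr::local_tempdir()
  cfg <- build_chip_config(root)
  cfg$samples[[2]]$fragments <- file.path(root, "absent.bed")
  expect_error(run_chip_pipeline(cfg), "missing input file")
  cfg2 <- build_chip_config(file.path(root, "b"))
  cfg2$samples <- cfg2$samples[2]  # no mock
  expect_error(run_chip_pipeline(cfg2), "no mock sample")
})

test_that("identical configs give byte-identical ChIP runs", {
  root <- withr::local_tempdir()
  cfg <- build_chip_config(root)
  cfg$outdir <- file.path(root, "run1")
  run_chip_pipeline(cfg)
  cfg$outdir <- file.path(root, "run2")
  run_chip_pipeline(cfg)
  f1 <- list.files(file.path(root, "run1"), full.names = TRUE)
  f2 <- file.path(root, "run2", basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("the BrU pipeline selects genes, scales profiles and summarizes", {
  root <- withr::local_tempdir()
  sim <- simulate_catalog(12, c(30000, 45000), spacing = 12000, seed = 201)
  bed <- file.path(root, "genes.bed"); write_catalog_bed(sim$catalog, bed)
  cs <- file.path(root, "chrom.sizes"); write_chrom_sizes(sim$chrom_sizes, cs)
  mock <- simulate_bru_track(sim$catalog, sim$chrom_sizes, 0,
                             condition_spec("mock"), depth = 3e5, seed = 202)
  uv <- simulate_bru_track(sim$catalog, sim$chrom_sizes, 3,
                           condition_spec("uv", damage_spacing = 16000),
                           depth = 3e5, seed = 203)
  p_mock <- file.path(root, "mock.bedGraph")
  write_bedgraph(mock$track, p_mock)
  p_uv <- file.path(root, "uv.bedGraph")
  write_bedgraph(uv$track, p_uv)
  lv <- file.path(root, "levels.tsv")
  writeLines(c("condition\ttimepoint\tfraction",
               "mock\t0h\t1.0",
               sprintf("uv\t3h\t%.4f", uv$nascent_level)), lv)
  cfg <- list(
    annotation = bed, chrom_sizes = cs, nascent_levels = lv,
    samples = list(
      list(name = "mock", coverage = p_mock,
           mapped_count = mock$mapped_count, condition = "mock",
           timepoint = "0h"),
      list(name = "uv3h", coverage = p_uv, mapped_count = uv$mapped_count,
           condition = "uv", timepoint = "3h")),
    outdir = file.path(root, "out"),
    params = list(span = c(-5000, 25000), bin_size = 500,
                  length_bounds = c(25000, 50000), min_rpkm = 0.05,
                  tss_spacing = 10000)
  )
  res <- run_bruseq_pipeline(cfg)
  expect_true(file.exists(file.path(cfg$outdir, "profiles_scaled.tsv")))
  expect_true(file.exists(file.path(cfg$outdir, "recovery_summaries.tsv")))
  expect_gt(nrow(res$catalog), 0)
  expect_true(all(res$summaries$recovery_front_bp >= 0))
  # missing nascent level for a timepoint is a startup error
  cfg$samples[[2]]$timepoint <- "8h"
  expect_error(run_bruseq_pipeline(cfg), "no nascent level")
})

test_that("the proteomics pipeline reruns deterministically; seeds only move imputed cells", {
  root <- withr::local_tempdir()
  sim <- simulate_intensity_matrix(300, 30, 4, seed = 301)
  lin <- 2^sim$matrix$intensities
  lin[is.na(lin)] <- 0
  df <- data.frame(`Protein IDs` = rownames(lin), check.names = FALSE)
  for (s in colnames(lin)) df[[paste("LFQ intensity", s)]] <- lin[, s]
  df$Reverse <- ""
  pg <- file.path(root, "proteinGroups.tsv")
  write.table(df, pg, sep = "\t", quote = FALSE, row.names = FALSE)
  design <- as.list(setNames(unname(sim$design), names(sim$design)))
  cfg <- list(proteingroups = pg, design = design,
              groups = c("uv", "mock"), outdir = file.path(root, "o1"),
              params = list(min_valid = 4, seed = 5))
  r1 <- run_proteomics_pipeline(cfg)
  cfg$outdir <- file.path(root, "o2")
  r2 <- run_proteomics_pipeline(cfg)
  expect_identical(r1$volcano, r2$volcano)
  # a different imputation seed changes p-values only through imputed cells
  cfg$outdir <- file.path(root, "o3")
  cfg$params$seed <- 6
  r3 <- run_proteomics_pipeline(cfg)
  expect_equal(r1$volcano$protein, r3$volcano$protein)
  complete_rows <- rowSums(is.na(
    sim$matrix$intensities[r1$volcano$protein, ])) == 0
  expect_equal(r1$volcano$p_value[complete_rows],
               r3$volcano$p_value[complete_rows])
  expect_false(identical(r1$volcano$p_value, r3$volcano$p_value))
})
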