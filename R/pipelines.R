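#' Configuration-driven pipelines
#'
#' Three end-to-end drivers tie the modules into reproducible runs, each
#' taking a YAML config (or the equivalent list) and writing its tables
#' plus a machine-readable manifest — parameters, row counts, output
#' checksums, seed — into the output directory. Reruns with an identical
#' config are byte-identical: nothing in the outputs depends on time or
#' session state.
#'
#' @name pipelines
NULL

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

check_files_exist <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(outdir, stages, params, seed) {
  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    seed = seed,
    parameters = params,
    stages = stages,
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) list(md5 = unname(sums[f])))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the ChIP-seq repositioning pipeline
#'
#' Stages: load and filter the gene catalog; pile up, depth-normalize and
#' input-subtract each sample; rank the top-bound genes on the designated
#' ranking sample; traveling-ratio table with mock normalization and
#' fraction-above-1 summaries; All/Mixed-Shift classification; AUC
#' metaprofiles and UV-minus-mock redistribution per comparison.
#'
#' @param config YAML path or list. Required fields: `annotation`,
#'   `chrom_sizes`, `samples` (list of `name`, `fragments`, `condition`,
#'   optional `mapped_count`, optional `input` fragment path), `outdir`.
#'   Optional `params`: `min_len`, `max_len`, `flank`, `n_top`,
#'   `tr_preset`, `span`, `bin_size`, `rank_sample`, `mock_samples`,
#'   `comparisons` (list of `[uv, mock]` pairs), `seed`.
#' @return (invisibly) list with the main in-memory results
#' @export
run_chip_pipeline <- function(config) {
  cfg <- read_run_config(config)
  p <- cfg$params %||% list()
  min_len <- p$min_len %||% 3000
  max_len <- p$max_len %||% 100000
  flank <- p$flank %||% 2000
  n_top <- p$n_top %||% NULL
  preset <- p$tr_preset %||% "RNAPII"
  span <- unlist(p$span %||% c(-2000, 5000))
  bin_size <- p$bin_size %||% 50
  seed <- p$seed %||% 1L

  sample_names <- vapply(cfg$samples, `[[`, "", "name")
  frag_paths <- vapply(cfg$samples, `[[`, "", "fragments")
  input_paths <- vapply(cfg$samples, function(s) s$input %||% "none", "")
  check_files_exist(c(cfg$annotation, cfg$chrom_sizes, frag_paths,
                      input_paths[input_paths != "none"]))
  conditions <- vapply(cfg$samples, `[[`, "", "condition")
  mock_samples <- unlist(p$mock_samples %||% sample_names[conditions == "mock"])
  if (!length(mock_samples)) stop("no mock sample in config")

  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  chrom_sizes <- read_chrom_sizes(cfg$chrom_sizes)
  catalog <- load_tss_table(cfg$annotation)
  selected <- select_nonoverlapping(catalog, min_len, max_len, flank)

  tracks <- list()
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    fr <- read_fragment_bed(s$fragments, s$mapped_count %||% NULL)
    tr <- normalize_per_10M(pileup(fr, chrom_sizes), fr$mapped_count)
    if (input_paths[i] != "none") {
      inp <- read_fragment_bed(input_paths[i])
      inp_tr <- normalize_per_10M(pileup(inp, chrom_sizes), inp$mapped_count)
      tr <- subtract_input(tr, inp_tr)
    }
    tracks[[s$name]] <- tr
  }

  rank_sample <- p$rank_sample %||% mock_samples[1]
  top <- if (!is.null(n_top) && n_top < nrow(selected)) {
    rank_top_bound(selected, tracks[[rank_sample]], n = n_top)
  } else selected
  write_catalog_bed(top, file.path(cfg$outdir, "catalog_selected.bed"))

  windows <- tr_windows(preset)
  tr_tab <- traveling_ratio_table(tracks, top, windows)
  tr_tab <- normalize_tr(tr_tab, mock_samples)
  write_tsv(as.data.frame(tr_tab), file.path(cfg$outdir, "traveling_ratios.tsv"))

  frac <- do.call(rbind, lapply(sample_names, function(s) {
    f <- fraction_above_one(tr_tab, s)
    data.frame(sample = s, fraction_above_one = f$fraction,
               n_above = f$n_above, n_finite = f$n_finite)
  }))
  write_tsv(frac, file.path(cfg$outdir, "fraction_above_one.tsv"))

  comparisons <- p$comparisons %||% {
    uv <- sample_names[conditions != "mock"]
    lapply(uv, function(u) c(u, mock_samples[1]))
  }
  calls <- classify_shift(tr_tab, comparisons)
  write_tsv(as.data.frame(calls), file.path(cfg$outdir, "shift_calls.tsv"))

  metas <- lapply(sample_names, function(s) {
    meta_profile(profile_matrix(tracks[[s]], top, span = span,
                                bin_size = bin_size),
                 stat = "mean", normalize = "AUC",
                 bin_size = bin_size, span = span, label = s)
  })
  names(metas) <- sample_names
  write_meta_profile_tsv(metas, file.path(cfg$outdir, "metaprofiles.tsv"))
  redist <- lapply(comparisons, function(cmp) {
    redistribution(metas[[cmp[[1]]]], metas[[cmp[[2]]]])
  })
  names(redist) <- vapply(comparisons, function(cmp)
    paste0(cmp[[1]], "_minus_", cmp[[2]]), "")
  write_meta_profile_tsv(redist, file.path(cfg$outdir, "redistribution.tsv"))

  stages <- list(
    catalog = list(n_in = nrow(catalog), n_selected = nrow(selected),
                   n_analyzed = nrow(top)),
    traveling_ratio = list(n_rows = nrow(tr_tab)),
    shift_classification = as.list(shift_class_counts(calls)),
    metaprofiles = list(n_profiles = length(metas), n_bins = length(metas[[1]]$bins))
  )
  write_manifest(cfg$outdir, stages,
                 list(min_len = min_len, max_len = max_len, flank = flank,
                      n_top = n_top, tr_preset = preset, span = span,
                      bin_size = bin_size, mock_samples = mock_samples),
                 seed)
  invisible(list(catalog = top, tracks = tracks, tr_table = tr_tab,
                 fraction_above_one = frac, shift_calls = calls,
                 metaprofiles = metas, redistribution = redist))
}

#' Run the BrU-seq recovery pipeline
#'
#' Stages: expression/length/spacing gene selection on the mock sample;
#' 500-bp bin RPKM matrices; median metagene profiles with upstream zero
#' baseline; absolute scaling to 5-EU nascent levels; recovery-front and
#' decay-length summaries per UV timepoint.
#'
#' @param config YAML path or list. Required: `annotation`, `chrom_sizes`,
#'   `samples` (list of `name`, `coverage` bedGraph, `mapped_count`,
#'   `condition`, `timepoint`), `nascent_levels` TSV, `outdir`. Optional
#'   `params`: `span`, `bin_size`, `min_rpkm`, `tss_spacing`,
#'   `length_bounds`, `threshold`, `mock_sample`, `seed`.
#' @return (invisibly) list with matrices, profiles and summary fits
#' @export
run_bruseq_pipeline <- function(config) {
  cfg <- read_run_config(config)
  p <- cfg$params %||% list()
  span <- unlist(p$span %||% c(-5000, 50000))
  bin_size <- p$bin_size %||% 500
  min_rpkm <- p$min_rpkm %||% 0.05
  tss_spacing <- p$tss_spacing %||% 10000
  length_bounds <- unlist(p$length_bounds %||% c(25000, 50000))
  threshold <- p$threshold %||% 0.5
  seed <- p$seed %||% 1L

  sample_names <- vapply(cfg$samples, `[[`, "", "name")
  cov_paths <- vapply(cfg$samples, `[[`, "", "coverage")
  check_files_exist(c(cfg$annotation, cfg$chrom_sizes, cov_paths,
                      cfg$nascent_levels))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  chrom_sizes <- read_chrom_sizes(cfg$chrom_sizes)
  catalog <- load_tss_table(cfg$annotation)
  levels <- read_nascent_levels(cfg$nascent_levels)

  mock_sample <- p$mock_sample %||%
    sample_names[vapply(cfg$samples, `[[`, "", "condition") == "mock"][1]
  if (is.na(mock_sample)) stop("no mock sample in config")

  tracks <- list()
  mapped <- stats::setNames(numeric(length(cfg$samples)), sample_names)
  for (s in cfg$samples) {
    tracks[[s$name]] <- read_bedgraph(s$coverage, chrom_sizes)
    mapped[s$name] <- s$mapped_count
  }

  rpkm <- gene_rpkm(tracks[[mock_sample]], catalog, mapped[mock_sample])
  selected <- select_expressed_by_length(catalog, rpkm, min_rpkm,
                                         tss_spacing, length_bounds)
  if (!nrow(selected)) stop("gene selection left no genes")
  write_catalog_bed(selected, file.path(cfg$outdir, "catalog_selected.bed"))

  profiles <- list()
  for (s in cfg$samples) {
    bm <- bin_rpkm_matrix(tracks[[s$name]], selected, span, bin_size,
                          mapped[s$name])
    write_tsv(data.frame(gene_id = rownames(bm), as.data.frame(unclass(bm))),
              file.path(cfg$outdir, sprintf("bin_rpkm_%s.tsv", s$name)))
    prof <- median_profile_zero_baseline(bm, label = s$name)
    lv <- levels[levels$condition == s$condition &
                   levels$timepoint == s$timepoint, "fraction"]
    if (!length(lv)) {
      stop(sprintf("no nascent level for condition '%s' timepoint '%s'",
                   s$condition, s$timepoint))
    }
    profiles[[s$name]] <- scale_absolute(prof, lv[1])
  }
  write_meta_profile_tsv(profiles, file.path(cfg$outdir, "profiles_scaled.tsv"))

  uv_samples <- setdiff(sample_names, mock_sample)
  summaries <- do.call(rbind, lapply(uv_samples, function(s) {
    front <- recovery_front(profiles[[s]], profiles[[mock_sample]], threshold)
    # lesion-limited decay only shows beyond the recovered front
    fit <- tryCatch(fit_decay_length(profiles[[s]], profiles[[mock_sample]],
                                     fit_range = c(front + bin_size, span[2])),
                    error = function(e) list(L = NA_real_, slope = NA_real_,
                                             r_squared = NA_real_, n_bins = 0))
    data.frame(sample = s, recovery_front_bp = front, decay_length_bp = fit$L,
               decay_r_squared = fit$r_squared, n_fit_bins = fit$n_bins)
  }))
  if (!is.null(summaries)) {
    write_tsv(summaries, file.path(cfg$outdir, "recovery_summaries.tsv"))
  }

  write_manifest(cfg$outdir,
                 list(selection = list(n_in = nrow(catalog),
                                       n_selected = nrow(selected)),
                      profiles = list(n_samples = length(profiles))),
                 list(span = span, bin_size = bin_size, min_rpkm = min_rpkm,
                      tss_spacing = tss_spacing,
                      length_bounds = length_bounds, threshold = threshold),
                 seed)
  invisible(list(catalog = selected, profiles = profiles,
                 summaries = summaries))
}

#' Run the label-free proteomics enrichment pipeline
#'
#' Stages: read a proteinGroups table; drop flagged proteins and log2
#' transform; minimum-valid filter per group; downshifted-normal
#' imputation; two-sided t-test volcano; SILAC ratio enrichment when H/L
#' ratios are present.
#'
#' @param config YAML path or list. Required: `proteingroups` TSV,
#'   `design` (named map sample -> group), `groups` (`[uv, mock]` pair),
#'   `outdir`. Optional `params`: `min_valid` (default 4), `shift` (1.8),
#'   `width` (0.3), `silac_threshold` (2), `seed`.
#' @return (invisibly) list with the volcano table and (optionally) the
#'   SILAC enrichment table
#' @export
run_proteomics_pipeline <- function(config) {
  cfg <- read_run_config(config)
  p <- cfg$params %||% list()
  min_valid <- p$min_valid %||% 4
  shift <- p$shift %||% 1.8
  width <- p$width %||% 0.3
  silac_threshold <- p$silac_threshold %||% 2
  seed <- p$seed %||% 1L
  check_files_exist(cfg$proteingroups)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  raw <- read_proteingroups(cfg$proteingroups)
  design <- group_design(unlist(cfg$design))
  m <- clean_and_log2(raw)
  m <- filter_min_valid(m, design, min_valid)
  m <- impute_downshift(m, shift, width, seed)
  volcano <- group_ttest_volcano(m, design, unlist(cfg$groups))
  write_tsv(volcano, file.path(cfg$outdir, "volcano.tsv"))

  silac <- NULL
  ratios <- attr(raw, "ratio_hl")
  if (!is.null(ratios)) {
    ratios <- ratios[!is.na(ratios)]
    if (length(ratios)) {
      silac <- silac_enrichment(ratios, silac_threshold)
      write_tsv(silac, file.path(cfg$outdir, "silac_enrichment.tsv"))
    }
  }

  write_manifest(cfg$outdir,
                 list(cleanup = list(n_raw = nrow(raw$intensities),
                                     n_tested = nrow(m$intensities)),
                      silac = list(n_ratios = length(ratios %||% numeric(0)),
                                   n_enriched = sum(silac$enriched %||% 0))),
                 list(min_valid = min_valid, shift = shift, width = width,
                      silac_threshold = silac_threshold),
                 seed)
  invisible(list(volcano = volcano, silac = silac, matrix = m))
}
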