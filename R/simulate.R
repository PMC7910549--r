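#' Synthetic pausing / release / elongation data
#'
#' Generators that emulate the signal structure the analysis assumes, so
#' every pipeline stage can be exercised end-to-end without external data:
#'
#' * ChIP occupancy: a Gaussian pause peak at the TSS, uniform gene-body
#'   occupancy attenuated exponentially by lesion density, a Gaussian peak
#'   downstream of the TTS, and flat background. UV moves a fraction `f` of
#'   the pause mass into a short release zone just downstream of the TSS;
#'   dose scales lesion density (spacing `L` is inversely proportional to
#'   dose, anchored at 16 kb for the 7 J/m2-equivalent condition).
#'   CSB-knockout-like and PAF1-depleted-like genotypes forbid release
#'   (`f = 0`); a global scale factor models overall occupancy loss.
#' * Nascent transcription: full signal up to a recovery front moving out
#'   from the promoter, exponential lesion-limited decay beyond it.
#' * Proteomics: log2-normal intensity matrices with planted group
#'   enrichment and intensity-dependent missingness.
#'
#' All draws are seeded and reproducible: the same inputs give the same
#' bytes.
#'
#' @name synthetic_data
NULL

#' ChIP occupancy model parameters
#'
#' Units are relative intensity (expected fragments per bp, up to the
#' common scale set by sequencing depth).
#'
#' @param pause_height peak intensity of the TSS pause site
#' @param pause_width Gaussian s.d. of the pause peak, bp
#' @param body_level uniform gene-body intensity
#' @param tts_height,tts_width Gaussian peak downstream of the TTS
#' @param background genome-wide flat intensity
#' @return an `occupancy_model`
#' @export
occupancy_model <- function(pause_height = 15, pause_width = 100,
                            body_level = 1, tts_height = 3, tts_width = 500,
                            background = 0.1) {
  m <- list(pause_height = pause_height, pause_width = pause_width,
            body_level = body_level, tts_height = tts_height,
            tts_width = tts_width, background = background)
  if (any(unlist(m) < 0)) stop("occupancy model parameters must be >= 0")
  structure(m, class = "occupancy_model")
}

#' Experimental-condition specification
#'
#' @param label condition name
#' @param release_fraction share `f` of pause occupancy moved into the
#'   release zone (0 = mock); forced to 0 for genotypes that cannot release
#' @param release_zone zone length downstream of the TSS, bp (2 kb for
#'   RNAPII-like, 1 kb for PAF1-like release)
#' @param damage_spacing mean lesion spacing `L`, bp (`Inf` for mock;
#'   16,000 at the 7 J/m2-equivalent dose, scaling as 1/dose)
#' @param global_scale multiplicative occupancy attenuation
#' @param genotype `"WT"`, `"CSB_KO"` or `"PAF1_depleted"`
#' @return a `condition_spec`
#' @export
condition_spec <- function(label, release_fraction = 0, release_zone = 2000,
                           damage_spacing = Inf, global_scale = 1,
                           genotype = c("WT", "CSB_KO", "PAF1_depleted")) {
  genotype <- match.arg(genotype)
  stopifnot(release_fraction >= 0, release_fraction <= 1,
            release_zone > 0, damage_spacing > 0, global_scale >= 0)
  if (genotype != "WT") release_fraction <- 0
  structure(list(label = label, release_fraction = release_fraction,
                 release_zone = release_zone,
                 damage_spacing = damage_spacing,
                 global_scale = global_scale, genotype = genotype),
            class = "condition_spec")
}

#' Lesion spacing for a UV dose
#'
#' Anchored at one lesion per 16 kb at 7 J/m2 and inversely proportional
#' to dose.
#'
#' @param dose_jm2 UV dose, J/m2 (0 = no damage)
#' @return spacing in bp (`Inf` at dose 0)
#' @export
damage_spacing_for_dose <- function(dose_jm2) {
  if (dose_jm2 <= 0) return(Inf)
  16000 * 7 / dose_jm2
}

#' Simulate a gene catalog on one synthetic chromosome
#'
#' Genes are laid end to end with a fixed inter-gene gap, alternating
#' strands; lengths are drawn log-uniformly within `length_range`.
#'
#' @param n_genes number of genes
#' @param length_range `c(lo, hi)` bp; lengths are log-uniform in this range
#' @param spacing gap between consecutive genes, bp
#' @param seed integer seed
#' @param chrom chromosome name
#' @return list with `catalog` (a `gene_catalog`) and `chrom_sizes`
#' @export
simulate_catalog <- function(n_genes, length_range = c(3000, 100000),
                             spacing = 5000, seed = 1L, chrom = "chrS") {
  stopifnot(spacing >= 0, n_genes >= 1)
  lens <- withr::with_seed(seed,
    round(exp(stats::runif(n_genes, log(length_range[1]),
                           log(length_range[2])))))
  starts <- spacing + c(0, cumsum(lens + spacing))[seq_len(n_genes)]
  df <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = chrom,
    start = starts,
    end = starts + lens,
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE
  )
  chrom_sizes <- stats::setNames(df$end[n_genes] + spacing, chrom)
  list(catalog = new_gene_catalog(df, provenance = list(
         simulated = list(n_genes = n_genes, length_range = length_range,
                          spacing = spacing, seed = seed))),
       chrom_sizes = chrom_sizes)
}

# Expected occupancy intensity lambda(x) over a whole chromosome for one
# condition. gene_scales multiplies the gene-specific components (pause,
# release, body, TTS) per gene; release_genes limits release to a subset.
chip_intensity <- function(catalog, chrom_sizes, model, cond,
                           gene_scales = NULL, release_genes = NULL) {
  if (is.null(gene_scales)) gene_scales <- rep(1, nrow(catalog))
  lam <- lapply(chrom_sizes, function(len) rep(model$background, as.integer(len)))
  names(lam) <- names(chrom_sizes)
  pause_mass <- model$pause_height * model$pause_width * sqrt(2 * pi)
  for (i in seq_len(nrow(catalog))) {
    g <- catalog[i, ]
    len <- g$end - g$start
    f <- cond$release_fraction
    if (!is.null(release_genes) && !(g$gene_id %in% release_genes)) f <- 0
    zone <- min(cond$release_zone, len)
    if (zone < cond$release_zone) {
      warning(sprintf("release zone truncated to gene length for %s", g$gene_id))
    }
    pad <- ceiling(4 * model$pause_width + 4 * model$tts_width + zone)
    chr_len <- as.integer(chrom_sizes[[g$chrom]])
    lo <- max(0, g$start - pad)
    hi <- min(chr_len, g$end + pad)
    pos <- lo:(hi - 1)
    x <- if (g$strand == "+") pos - g$start else (g$end - 1) - pos
    tau <- zone / 3
    rel_norm <- tau * (1 - exp(-zone / tau))
    body <- model$body_level * (x > 0 & x < len) *
      exp(-pmax(x, 0) / cond$damage_spacing)
    contrib <- (1 - f) * model$pause_height *
      exp(-x^2 / (2 * model$pause_width^2)) +
      f * pause_mass * (x > 0 & x <= zone) * exp(-pmax(x, 0) / tau) / rel_norm +
      body +
      model$tts_height * exp(-(x - len)^2 / (2 * model$tts_width^2))
    lam[[g$chrom]][pos + 1] <- lam[[g$chrom]][pos + 1] +
      gene_scales[i] * contrib
  }
  lapply(lam, function(v) cond$global_scale * v)
}

#' Simulate a ChIP fragment library
#'
#' Fragment count is Poisson(`depth`); fragment midpoints are drawn in
#' proportion to the expected occupancy intensity, so windowed counts are
#' Poisson with mean proportional to the windowed intensity. Fragments have
#' fixed length and are clipped to the chromosome.
#'
#' @param catalog a `gene_catalog` (from [simulate_catalog()])
#' @param chrom_sizes named chromosome lengths
#' @param model an [occupancy_model()]
#' @param cond a [condition_spec()]
#' @param depth expected number of fragments
#' @param fragment_len fixed fragment length, bp
#' @param seed integer seed
#' @param gene_scales optional per-gene binding-strength multipliers
#' @param release_genes optional subset of gene_ids allowed to release
#'   (others behave as mock in this sample)
#' @return a `fragment_set`
#' @export
simulate_chip_library <- function(catalog, chrom_sizes, model, cond, depth,
                                  fragment_len = 200, seed = 1L,
                                  gene_scales = NULL, release_genes = NULL) {
  stopifnot(depth > 0, fragment_len >= 1)
  lam <- chip_intensity(catalog, chrom_sizes, model, cond, gene_scales,
                        release_genes)
  frags <- withr::with_seed(seed, {
    n_chr <- vapply(lam, sum, 0)
    n_tot <- stats::rpois(1, depth)
    n_per <- if (n_tot > 0) {
      as.vector(stats::rmultinom(1, n_tot, n_chr / sum(n_chr)))
    } else integer(length(lam))
    do.call(rbind, lapply(seq_along(lam), function(k) {
      if (n_per[k] == 0) return(NULL)
      chr_len <- length(lam[[k]])
      mid <- sample.int(chr_len, n_per[k], replace = TRUE,
                        prob = lam[[k]]) - 1L
      start <- pmin(pmax(mid - fragment_len %/% 2, 0L),
                    chr_len - fragment_len)
      data.frame(chrom = names(lam)[k], start = start,
                 end = start + fragment_len, stringsAsFactors = FALSE)
    }))
  })
  if (is.null(frags)) {
    frags <- data.frame(chrom = character(), start = numeric(),
                        end = numeric())
  }
  frags <- frags[order(frags$chrom, frags$start, frags$end), , drop = FALSE]
  rownames(frags) <- NULL
  fragment_set(frags, mapped_count = max(nrow(frags), 1))
}

#' Simulate a replicated ChIP cohort
#'
#' One catalog plus mock and UV replicate libraries piled up and
#' depth-normalized, ready for traveling-ratio analysis. A configurable
#' share of genes is UV-responsive (released); the rest stay paused in
#' every sample, giving per-gene truth labels for classifier benchmarks.
#' `release_fraction = 0` with `damage_spacing = Inf` produces a null
#' cohort of fully exchangeable replicates; with a finite spacing the UV
#' libraries keep the lesion-density body attenuation even though nothing
#' releases.
#'
#' @param n_genes,length_range,spacing catalog layout (see
#'   [simulate_catalog()])
#' @param depth expected fragments per library
#' @param n_mock,n_uv replicate counts
#' @param release_fraction pause-release share `f` in UV libraries
#' @param released_share share of genes that respond to UV
#' @param damage_spacing lesion spacing in UV libraries, bp
#' @param model an [occupancy_model()]
#' @param seed integer seed (per-library seeds are derived from it)
#' @return list: `catalog`, `chrom_sizes`, `tracks` (named `per10M`
#'   coverage tracks `mock_i` / `uv_i`), `released` (gene_ids of
#'   responsive genes), `comparisons` (replicate-paired UV-vs-mock list
#'   usable with [classify_shift()])
#' @export
simulate_chip_cohort <- function(n_genes = 150,
                                 length_range = c(4000, 20000),
                                 spacing = 4000, depth = 1e5,
                                 n_mock = 4, n_uv = 4,
                                 release_fraction = 0.6,
                                 released_share = 0.5,
                                 damage_spacing = 16000,
                                 model = occupancy_model(), seed = 1L) {
  seed <- as.integer(seed %% 1000000L)  # keep derived per-library seeds < 2^31
  sim <- simulate_catalog(n_genes, length_range, spacing, seed = seed)
  n_rel <- round(released_share * n_genes)
  released <- if (release_fraction > 0) sim$catalog$gene_id[seq_len(n_rel)]
              else character(0)
  conds <- c(
    stats::setNames(lapply(seq_len(n_mock), function(i)
      condition_spec(sprintf("mock_%d", i))),
      sprintf("mock_%d", seq_len(n_mock))),
    stats::setNames(lapply(seq_len(n_uv), function(i)
      condition_spec(sprintf("uv_%d", i), release_fraction = release_fraction,
                     damage_spacing = damage_spacing)),
      sprintf("uv_%d", seq_len(n_uv)))
  )
  tracks <- lapply(seq_along(conds), function(i) {
    lib <- simulate_chip_library(sim$catalog, sim$chrom_sizes, model,
                                 conds[[i]], depth,
                                 seed = seed * 1000L + i,
                                 release_genes = if (length(released)) released)
    normalize_per_10M(pileup(lib, sim$chrom_sizes), lib$mapped_count)
  })
  names(tracks) <- names(conds)
  comparisons <- lapply(seq_len(min(n_mock, n_uv)), function(i)
    c(sprintf("uv_%d", i), sprintf("mock_%d", i)))
  list(catalog = sim$catalog, chrom_sizes = sim$chrom_sizes,
       tracks = tracks, released = released, comparisons = comparisons)
}

#' Simulate a nascent-transcription (BrU-like) coverage track
#'
#' Expected read rate over a gene body at distance `x` from the TSS is
#' `rate * recovery(x, t)` with `recovery = 1` for `x < v * t` (the wave
#' front has passed) and `exp(-x / L)` beyond it; mock (`L = Inf`) is
#' uniform. The PAF1-depleted genotype retains promoter-proximal signal but
#' decays over the body at all times (no processive recovery). Per-base
#' counts are independent Poisson draws.
#'
#' @param catalog a `gene_catalog`
#' @param chrom_sizes named chromosome lengths
#' @param time_h hours since irradiation
#' @param cond a [condition_spec()] (`damage_spacing` = lesion spacing)
#' @param elongation_speed recovery-front speed, bp/h
#' @param depth expected total reads in the mock-equivalent library
#' @param seed integer seed
#' @param pp_width promoter-proximal width retained under PAF1 depletion, bp
#' @return list: `track` (raw per-base read counts), `nascent_level`
#'   (expected genome-wide signal fraction vs mock), `mapped_count`
#' @export
simulate_bru_track <- function(catalog, chrom_sizes, time_h, cond,
                               elongation_speed = 4000, depth = 1e6,
                               seed = 1L, pp_width = 500) {
  stopifnot(elongation_speed > 0, depth > 0)
  body_bases <- sum(gene_length(catalog))
  rate <- depth / body_bases
  lam <- lapply(chrom_sizes, function(len) numeric(as.integer(len)))
  names(lam) <- names(chrom_sizes)
  mock_total <- 0
  front <- elongation_speed * time_h
  for (i in seq_len(nrow(catalog))) {
    g <- catalog[i, ]
    len <- g$end - g$start
    x <- 0:(len - 1)
    recov <- if (cond$genotype == "PAF1_depleted") {
      ifelse(x < pp_width, 1, exp(-x / cond$damage_spacing))
    } else {
      ifelse(x < front, 1, exp(-x / cond$damage_spacing))
    }
    v <- rate * recov
    pos <- if (g$strand == "+") g$start + x else (g$end - 1) - x
    lam[[g$chrom]][pos + 1] <- lam[[g$chrom]][pos + 1] + v
    mock_total <- mock_total + rate * len
  }
  counts <- withr::with_seed(seed,
    lapply(lam, function(v) as.numeric(stats::rpois(length(v), v))))
  track <- new_coverage_track(counts, "raw")
  list(track = track,
       nascent_level = sum(unlist(lapply(lam, sum))) / mock_total,
       mapped_count = sum(unlist(counts)))
}

#' Simulate a proteomics intensity matrix with planted enrichment
#'
#' Per-protein baselines are normal on the log2 scale; enriched proteins
#' gain `effect_log2` in the UV group. Missingness is
#' intensity-dependent: `P(missing) = plogis((midpoint - x) / scale)`, so
#' weak intensities drop out preferentially (set `missing_model = NULL`
#' for a complete matrix).
#'
#' @param n_proteins,n_enriched matrix size and number of planted proteins
#' @param effect_log2 planted UV-group shift, log2 units
#' @param group_sizes named vector, e.g. `c(mock = 4, uv = 4)`
#' @param missing_model list with `midpoint` and `scale` (log2 units), or
#'   `NULL`
#' @param seed integer seed
#' @param baseline_mean,baseline_sd,rep_sd log2 intensity distribution
#' @return list: `matrix` (log2 `intensity_matrix` with NAs), `design`
#'   (a [group_design()]), `truth` (logical: planted enrichment)
#' @export
simulate_intensity_matrix <- function(n_proteins, n_enriched = 0,
                                      effect_log2 = 0,
                                      group_sizes = c(mock = 4, uv = 4),
                                      missing_model = list(midpoint = 19,
                                                           scale = 1),
                                      seed = 1L,
                                      baseline_mean = 23, baseline_sd = 2,
                                      rep_sd = 0.5) {
  stopifnot(n_enriched <= n_proteins, length(group_sizes) == 2)
  samples <- unlist(lapply(names(group_sizes), function(gp)
    sprintf("%s_%d", gp, seq_len(group_sizes[[gp]]))))
  grp <- rep(names(group_sizes), group_sizes)
  names(grp) <- samples
  uv_group <- names(group_sizes)[2]
  out <- withr::with_seed(seed, {
    base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    m <- base + matrix(stats::rnorm(n_proteins * length(samples), 0, rep_sd),
                       n_proteins, length(samples))
    truth <- c(rep(TRUE, n_enriched), rep(FALSE, n_proteins - n_enriched))
    m[truth, grp == uv_group] <- m[truth, grp == uv_group] + effect_log2
    if (!is.null(missing_model)) {
      p_miss <- stats::plogis((missing_model$midpoint - m) /
                                missing_model$scale)
      m[stats::runif(length(m)) < p_miss] <- NA
    }
    list(m = m, truth = truth)
  })
  dimnames(out$m) <- list(sprintf("P%05d", seq_len(n_proteins)), samples)
  list(matrix = intensity_matrix(out$m, state = "log2"),
       design = group_design(grp),
       truth = stats::setNames(out$truth, rownames(out$m)))
}
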