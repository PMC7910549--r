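#' Nascent-RNA (BrU-seq) recovery profiles
#'
#' Bromouridine pulse-labeling marks RNA made during a short window, so
#' read density along a gene maps where polymerases are transcribing.
#' After UV, elongating polymerases stall at lesions: signal decays
#' exponentially with distance into the gene at a rate set by the lesion
#' density (about one cyclobutane pyrimidine dimer per 16 kb at 7 J/m2),
#' and recovery proceeds as a wave from the promoter outward. This module
#' builds 500-bp bin RPKM matrices, median metagene profiles with an
#' upstream zero baseline, absolute scaling to 5-EU-measured nascent
#' levels, and two summary fits: the exponential decay length and the
#' recovery-front position.
#'
#' @name bruseq
NULL

#' Bin-level RPKM matrix over a catalog
#'
#' Reads per bin are summed from a raw per-base read-count track
#' (strand-oriented bins from `span[1]` upstream of the TSS), then
#' converted to RPKM: `reads / (bin_kb * mapped_millions)`.
#'
#' @param coverage `coverage_track` in state `raw` holding per-base read
#'   counts
#' @param catalog a `gene_catalog`
#' @param span `c(from_off, to_off)` bp relative to TSS (default -5 kb to
#'   +50 kb)
#' @param bin_size bin width, bp (default 500)
#' @param mapped_count uniquely-mapped reads in the library
#' @return `bin_matrix`: genes-by-bins RPKM matrix with attributes
#'   `bin_size`, `span`, `mapped_count`
#' @export
bin_rpkm_matrix <- function(coverage, catalog, span = c(-5000, 50000),
                            bin_size = 500, mapped_count) {
  if (mapped_count <= 0) stop("mapped_count must be positive")
  m <- profile_matrix(coverage, catalog, anchor = "TSS", span = span,
                      bin_size = bin_size)
  # profile_matrix returns mean per-base counts; reads per bin = mean * width
  reads <- m * bin_size
  rpkm <- reads / ((bin_size / 1000) * (mapped_count / 1e6))
  structure(rpkm, bin_size = bin_size, span = span,
            mapped_count = mapped_count, class = c("bin_matrix", "matrix"))
}

#' Per-gene RPKM from a raw read-count track
#'
#' @param coverage `coverage_track` in state `raw`
#' @param catalog a `gene_catalog`
#' @param mapped_count uniquely-mapped reads in the library
#' @return data frame: `gene_id`, `rpkm`
#' @export
gene_rpkm <- function(coverage, catalog, mapped_count) {
  if (mapped_count <= 0) stop("mapped_count must be positive")
  reads <- vapply(seq_len(nrow(catalog)), function(i) {
    g <- catalog[i, ]
    v <- coverage$values[[g$chrom]]
    sum(v[(g$start + 1):g$end])
  }, numeric(1))
  len_kb <- gene_length(catalog) / 1000
  data.frame(gene_id = catalog$gene_id,
             rpkm = reads / (len_kb * mapped_count / 1e6),
             stringsAsFactors = FALSE)
}

#' Median metagene profile with upstream zero baseline
#'
#' Per-bin median RPKM across genes, then the mean of the upstream
#' (`span[1]`..TSS) bins is subtracted from every bin so the pre-gene
#' baseline sits at zero. Negative bins are retained: they represent
#' sub-baseline signal, and clipping would bias downstream decay fits.
#'
#' @param matrix a `bin_matrix` whose span includes upstream bins
#' @param label condition label for the resulting profile
#' @return a `meta_profile` (stat = median)
#' @export
median_profile_zero_baseline <- function(matrix, label = "") {
  if (!nrow(matrix)) stop("empty bin matrix")
  span <- attr(matrix, "span")
  bin_size <- attr(matrix, "bin_size")
  med <- apply(matrix, 2, stats::median)
  off <- seq(span[1], span[2] - bin_size, by = bin_size)
  upstream <- which(off < 0)
  if (!length(upstream)) stop("span has no upstream bins for the baseline")
  bins <- med - mean(med[upstream])
  new_meta_profile(bins, nrow(matrix), bin_size, span, "TSS",
                   normalization = "none", stat = "median", label = label)
}

#' Read 5-EU nascent-level table
#'
#' TSV with columns `condition`, `timepoint`, `fraction`: nascent
#' transcription relative to the matched control (e.g. 0.62 means 62% of
#' control RNA synthesis).
#'
#' @param path TSV path
#' @return data frame
#' @export
read_nascent_levels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "timepoint", "fraction")
  if (!all(need %in% names(df))) {
    stop("nascent-level TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$fraction < 0)) stop("nascent fraction must be >= 0")
  df
}

#' Scale a profile by an absolute nascent-transcription fraction
#'
#' Multiplies every bin by the 5-EU-measured fraction, converting the
#' relative read distribution into absolute nascent-transcription units.
#'
#' @param profile a `meta_profile`
#' @param fraction nascent level relative to control (>= 0)
#' @return `meta_profile` with `normalization = "global-scaled"`
#' @export
scale_absolute <- function(profile, fraction) {
  stopifnot(fraction >= 0)
  out <- profile
  out$bins <- profile$bins * fraction
  out$normalization <- "global-scaled"
  out
}

#' Recovery-front distance
#'
#' The largest distance `d` downstream of the TSS such that the
#' timepoint/mock bin ratio stays at or above `threshold` for every bin in
#' `(0, d]`; 0 when the first gene-body bin already fails.
#'
#' @param profile_t,profile_mock `meta_profile`s on identical bins; mock
#'   must be positive beyond the TSS
#' @param threshold recovery fraction defining the front (default 0.5)
#' @return distance in bp
#' @export
recovery_front <- function(profile_t, profile_mock, threshold = 0.5) {
  if (!identical(profile_t$span, profile_mock$span) ||
      profile_t$bin_size != profile_mock$bin_size) {
    stop("profiles must share binning")
  }
  off <- bin_offsets(profile_t)
  body <- which(off >= 0)
  if (any(profile_mock$bins[body] <= 0)) {
    stop("mock profile must be positive downstream of the TSS")
  }
  ok <- profile_t$bins[body] / profile_mock$bins[body] >= threshold
  first_fail <- which(!ok)[1]
  n_ok <- if (is.na(first_fail)) length(ok) else first_fail - 1L
  n_ok * profile_t$bin_size
}

#' Fit the exponential decay length of UV attenuation
#'
#' Over gene-body bins, log(UV/mock) is approximately linear in distance
#' with slope `-1/L`, `L` the mean spacing between transcription-blocking
#' lesions. Ordinary least squares on bins where both profiles are
#' positive.
#'
#' @param profile_uv,profile_mock `meta_profile`s on identical bins
#' @param fit_range `c(lo, hi)` bp range of bin offsets to fit (default the
#'   full gene-body span)
#' @return list with `L` (bp), `slope` (1/bp), `r_squared`, `n_bins`
#' @export
fit_decay_length <- function(profile_uv, profile_mock, fit_range = NULL) {
  if (!identical(profile_uv$span, profile_mock$span) ||
      profile_uv$bin_size != profile_mock$bin_size) {
    stop("profiles must share binning")
  }
  off <- bin_offsets(profile_uv) + profile_uv$bin_size / 2
  use <- off > 0 & profile_uv$bins > 0 & profile_mock$bins > 0
  if (!is.null(fit_range)) use <- use & off >= fit_range[1] & off <= fit_range[2]
  if (sum(use) < 3) stop("fewer than 3 usable bins for the decay fit")
  y <- log(profile_uv$bins[use] / profile_mock$bins[use])
  fit <- stats::lm(y ~ off[use])
  slope <- unname(stats::coef(fit)[2])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(L = -1 / slope, slope = slope, r_squared = r2, n_bins = sum(use))
}
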