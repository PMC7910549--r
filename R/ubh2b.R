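#' Ub-H2B gene-body profiling
#'
#' H2B monoubiquitylation tracks co-transcriptional elongation, so its
#' gene-body ChIP profile reports how far polymerases travel. Profiles are
#' background-subtracted against the signal just upstream of the TSS
#' (default 200 bp upstream) and then rescaled so their area matches a
#' global Ub-H2B level measured independently by microscopy — ChIP
#' internally normalizes away global losses, so the imaging scalar restores
#' the absolute scale.
#'
#' @name ubh2b
NULL

#' Subtract the upstream-baseline bin from a metaprofile
#'
#' The value of the bin containing `-baseline_offset` bp is subtracted from
#' every bin; negatives are clipped to 0.
#'
#' @param profile a `meta_profile` whose span covers the baseline position
#' @param baseline_offset distance upstream of the TSS, bp (positive number)
#' @return baseline-subtracted `meta_profile`
#' @export
baseline_subtract_upstream <- function(profile, baseline_offset = 200) {
  pos <- -abs(baseline_offset)
  off <- bin_offsets(profile)
  idx <- which(off <= pos & pos < off + profile$bin_size)
  if (!length(idx)) {
    stop(sprintf("profile span [%d,%d) excludes baseline at %d bp",
                 profile$span[1], profile$span[2], pos))
  }
  bins <- pmax(profile$bins - profile$bins[idx], 0)
  out <- profile
  out$bins <- bins
  out
}

#' Read imaging-derived global levels
#'
#' Two-column TSV (`condition`, `fraction`): each condition's global level
#' relative to the designated reference condition (reference = 1).
#'
#' @param path TSV path
#' @return named numeric vector of fractions
#' @export
read_global_levels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("condition", "fraction") %in% names(df))) {
    stop("global-level TSV needs columns: condition, fraction")
  }
  if (any(df$fraction < 0)) stop("global-level fraction must be >= 0")
  stats::setNames(df$fraction, df$condition)
}

#' Rescale a metaprofile to a global level
#'
#' Multiplies the profile so its integral `sum(bins * bin_size)` equals
#' `fraction`, tying the ChIP shape to an absolute, externally measured
#' amount.
#'
#' @param profile a `meta_profile` with positive integral
#' @param fraction global level for this condition (unitless, reference = 1)
#' @return `meta_profile` with `normalization = "global-scaled"`
#' @export
scale_to_global <- function(profile, fraction) {
  stopifnot(fraction >= 0)
  auc <- sum(profile$bins * profile$bin_size)
  if (auc <= 0) stop("cannot scale a profile with zero integral")
  out <- profile
  out$bins <- profile$bins * (fraction / auc)
  out$normalization <- "global-scaled"
  out
}
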