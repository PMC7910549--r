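#' Label-free interaction-proteomics workflow
#'
#' Perseus-style analysis of MaxQuant-quantified pull-downs: flag-based
#' cleanup and log2 transform, a minimum-valid-values filter per group,
#' downshifted-normal imputation of missing values (missing-not-at-random
#' intensities sit below the detection limit, so draws come from a
#' distribution shifted `1.8` whole-matrix standard deviations below the
#' observed mean with `0.3` s.d. width), two-sided Student's t-test
#' volcanoes, SILAC H/L ratio enrichment, and iBAQ-based stoichiometry.
#'
#' @name proteomics
NULL

#' Construct an intensity matrix
#'
#' @param intensities proteins-by-samples numeric matrix; `NA` (or 0 in
#'   linear state) marks a missing quantification
#' @param flags data frame with logical columns `contaminant`, `reverse`,
#'   `site_only` (one row per protein); defaults to all-FALSE
#' @param ibaq optional proteins-by-samples iBAQ matrix
#' @param state `"linear"` or `"log2"`
#' @return an `intensity_matrix`
#' @export
intensity_matrix <- function(intensities, flags = NULL, ibaq = NULL,
                             state = "linear") {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  if (state == "linear" && any(intensities < 0, na.rm = TRUE)) {
    stop("linear intensities must be >= 0")
  }
  if (is.null(flags)) {
    flags <- data.frame(contaminant = logical(nrow(intensities)),
                        reverse = logical(nrow(intensities)),
                        site_only = logical(nrow(intensities)))
  }
  structure(list(intensities = intensities, flags = flags, ibaq = ibaq,
                 state = state),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix [%s]: %d proteins x %d samples, %.1f%% missing\n",
              x$state, nrow(x$intensities), ncol(x$intensities),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Sample-to-group design
#'
#' @param groups named character vector: `names` are sample names (matching
#'   intensity columns), values are group labels
#' @return a `group_design`
#' @export
group_design <- function(groups) {
  stopifnot(!is.null(names(groups)), all(nzchar(names(groups))))
  if (length(unique(groups)) < 2) stop("a design needs at least 2 groups")
  structure(groups, class = "group_design")
}

#' Remove flagged proteins and log2-transform
#'
#' Drops contaminants, reverse-database hits and proteins identified only
#' by a modification site, then log2-transforms the remaining intensities.
#' Zeros (MaxQuant's non-quantification marker) become missing.
#'
#' @param matrix an `intensity_matrix` in linear state
#' @return `intensity_matrix` in log2 state
#' @export
clean_and_log2 <- function(matrix) {
  if (matrix$state != "linear") stop("clean_and_log2 expects a linear matrix")
  keep <- !(matrix$flags$contaminant | matrix$flags$reverse |
              matrix$flags$site_only)
  m <- matrix$intensities[keep, , drop = FALSE]
  m[!is.na(m) & m == 0] <- NA
  m <- log2(m)
  ib <- if (!is.null(matrix$ibaq)) matrix$ibaq[keep, , drop = FALSE]
  intensity_matrix(m, matrix$flags[keep, , drop = FALSE], ib, state = "log2")
}

#' Keep proteins quantified in at least `min_valid` replicates of a group
#'
#' @param matrix an `intensity_matrix`
#' @param design a [group_design()]
#' @param min_valid required non-missing values in at least one group
#' @return filtered `intensity_matrix`
#' @export
filter_min_valid <- function(matrix, design, min_valid) {
  samples <- colnames(matrix$intensities)
  stopifnot(all(samples %in% names(design)))
  grp <- split(samples, design[samples])
  if (min_valid > min(lengths(grp))) {
    stop("min_valid exceeds the smallest group size")
  }
  ok_by_group <- vapply(grp, function(s) {
    rowSums(!is.na(matrix$intensities[, s, drop = FALSE])) >= min_valid
  }, logical(nrow(matrix$intensities)))
  keep <- apply(as.matrix(ok_by_group), 1, any)
  ib <- if (!is.null(matrix$ibaq)) matrix$ibaq[keep, , drop = FALSE]
  intensity_matrix(matrix$intensities[keep, , drop = FALSE],
                   matrix$flags[keep, , drop = FALSE], ib,
                   state = matrix$state)
}

#' Impute missing values from a downshifted normal
#'
#' Each missing log2 intensity is replaced by a draw from
#' `Normal(mu - shift * sigma, (width * sigma)^2)`, where `mu` and `sigma`
#' are the mean and s.d. of *all* observed values in the matrix.
#'
#' @param matrix an `intensity_matrix` in log2 state with >= 2 observed
#'   values
#' @param shift downshift in whole-matrix s.d. units (default 1.8)
#' @param width imputation s.d. in whole-matrix s.d. units (default 0.3)
#' @param seed integer seed; identical seeds give identical imputations
#' @return complete `intensity_matrix`
#' @export
impute_downshift <- function(matrix, shift = 1.8, width = 0.3, seed = 1L) {
  if (matrix$state != "log2") stop("impute_downshift expects a log2 matrix")
  obs <- matrix$intensities[!is.na(matrix$intensities)]
  if (length(obs) < 2) stop("need >= 2 observed values to impute")
  mu <- mean(obs)
  sigma <- stats::sd(obs)
  n_miss <- sum(is.na(matrix$intensities))
  out <- matrix
  if (n_miss > 0) {
    draws <- withr::with_seed(seed,
      stats::rnorm(n_miss, mean = mu - shift * sigma, sd = width * sigma))
    out$intensities[is.na(out$intensities)] <- draws
  }
  out
}

#' Two-group volcano: log2 fold-change and two-sided t-test
#'
#' Per protein: fold-change = mean(a) - mean(b) on the log2 scale; p-value
#' from a two-sample Student's (equal-variance) t-test, two-sided. A
#' Benjamini-Hochberg adjusted column is included as an optional extra;
#' the primary readout is the raw volcano.
#'
#' @param matrix a complete (post-imputation) log2 `intensity_matrix`
#' @param design a [group_design()]
#' @param groups `c(a, b)` group labels to compare (fold-change is a minus
#'   b)
#' @return data frame: `protein`, `log2_fc`, `p_value`, `neg_log10_p`,
#'   `p_adj_bh`
#' @export
group_ttest_volcano <- function(matrix, design, groups) {
  if (any(is.na(matrix$intensities))) {
    stop("matrix still has missing values; impute first")
  }
  samples <- colnames(matrix$intensities)
  a <- samples[design[samples] == groups[1]]
  b <- samples[design[samples] == groups[2]]
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 samples")
  ma <- matrix$intensities[, a, drop = FALSE]
  mb <- matrix$intensities[, b, drop = FALSE]
  fc <- rowMeans(ma) - rowMeans(mb)
  p <- vapply(seq_len(nrow(ma)), function(i) {
    if (stats::sd(c(ma[i, ], mb[i, ])) == 0) return(1)
    stats::t.test(ma[i, ], mb[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  data.frame(protein = rownames(matrix$intensities),
             log2_fc = unname(fc), p_value = p,
             neg_log10_p = -log10(p),
             p_adj_bh = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' SILAC ratio enrichment
#'
#' Flags proteins whose heavy/light ratio (heavy = UV, light = mock) meets
#' the fold threshold, inclusively ("at least `threshold`-fold").
#'
#' @param ratios named numeric vector of H/L ratios (> 0)
#' @param threshold fold threshold (default 2)
#' @return data frame: `protein`, `ratio_hl`, `log2_ratio`, `enriched`
#' @export
silac_enrichment <- function(ratios, threshold = 2) {
  if (any(ratios <= 0, na.rm = TRUE)) stop("H/L ratios must be positive")
  data.frame(protein = names(ratios), ratio_hl = unname(ratios),
             log2_ratio = log2(unname(ratios)),
             enriched = unname(ratios) >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' iBAQ stoichiometry relative to a bait
#'
#' The bound fraction of a prey is its iBAQ divided by the bait's iBAQ in
#' the same condition (iBAQ approximates molar amount); the fold-change is
#' the UV-to-mock ratio of bound fractions.
#'
#' @param ibaq proteins-by-conditions iBAQ matrix (rownames = protein)
#' @param bait bait protein name
#' @param prey character vector of prey protein names
#' @param conditions `c(uv, mock)` column names
#' @return data frame: `prey`, `fraction_uv`, `fraction_mock`,
#'   `fold_change`
#' @export
ibaq_stoichiometry <- function(ibaq, bait, prey, conditions) {
  stopifnot(bait %in% rownames(ibaq), all(prey %in% rownames(ibaq)),
            all(conditions %in% colnames(ibaq)))
  b <- ibaq[bait, conditions]
  if (any(b <= 0)) stop("bait iBAQ must be positive in both conditions")
  f_uv <- ibaq[prey, conditions[1]] / b[[1]]
  f_mock <- ibaq[prey, conditions[2]] / b[[2]]
  data.frame(prey = prey, fraction_uv = unname(f_uv),
             fraction_mock = unname(f_mock),
             fold_change = unname(f_uv / f_mock),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Expects tab-separated columns `Protein IDs`, `LFQ intensity <sample>`,
#' optional `iBAQ <sample>`, `Ratio H/L`, and the `+`-marked flag columns
#' `Reverse`, `Potential contaminant`, `Only identified by site`.
#'
#' @param path TSV path
#' @return an `intensity_matrix` in linear state, with H/L ratios (if
#'   present) in `attr(, "ratio_hl")`
#' @export
read_proteingroups <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Protein IDs" %in% names(df)) stop("missing column: Protein IDs")
  lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (!length(lfq_cols)) stop("no 'LFQ intensity <sample>' columns found")
  m <- as.matrix(df[, lfq_cols, drop = FALSE])
  rownames(m) <- df[["Protein IDs"]]
  colnames(m) <- sub("^LFQ intensity ", "", lfq_cols)
  flag <- function(col) {
    if (col %in% names(df)) {
      v <- df[[col]]
      !is.na(v) & v == "+"
    } else logical(nrow(df))
  }
  flags <- data.frame(contaminant = flag("Potential contaminant"),
                      reverse = flag("Reverse"),
                      site_only = flag("Only identified by site"))
  ibaq_cols <- grep("^iBAQ ", names(df), value = TRUE)
  ibaq <- NULL
  if (length(ibaq_cols)) {
    ibaq <- as.matrix(df[, ibaq_cols, drop = FALSE])
    rownames(ibaq) <- df[["Protein IDs"]]
    colnames(ibaq) <- sub("^iBAQ ", "", ibaq_cols)
  }
  out <- intensity_matrix(m, flags, ibaq, state = "linear")
  if ("Ratio H/L" %in% names(df)) {
    attr(out, "ratio_hl") <- stats::setNames(df[["Ratio H/L"]],
                                             df[["Protein IDs"]])
  }
  out
}
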