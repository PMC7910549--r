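#' Anchored profiles and metaprofiles
#'
#' An `anchored_profile` is one gene's binned, strand-oriented density
#' around an anchor (TSS or TTS). A `meta_profile` is the per-bin mean or
#' median over many genes, optionally normalized to unit area under the
#' curve (AUC) so that conditions with different overall read density can
#' be compared shape-to-shape.
#'
#' @name profiles
NULL

new_anchored_profile <- function(gene_id, anchor, bins, bin_size, span) {
  structure(list(gene_id = gene_id, anchor = anchor, bins = bins,
                 bin_size = bin_size, span = span),
            class = "anchored_profile")
}

new_meta_profile <- function(bins, n_genes, bin_size, span, anchor,
                             normalization = "none", stat = "mean",
                             label = "") {
  structure(list(bins = bins, n_genes = n_genes, bin_size = bin_size,
                 span = span, anchor = anchor, normalization = normalization,
                 stat = stat, label = label),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile '%s': %d bins of %d bp over [%d,%d), %s of %d genes, normalization=%s\n",
              x$label, length(x$bins), x$bin_size, x$span[1], x$span[2],
              x$stat, x$n_genes, x$normalization))
  invisible(x)
}

#' Bin offsets of a profile
#'
#' @param profile an `anchored_profile` or `meta_profile`
#' @return numeric vector of bin start offsets (bp relative to the anchor)
#' @export
bin_offsets <- function(profile) {
  seq(profile$span[1], profile$span[2] - profile$bin_size,
      by = profile$bin_size)
}

#' Binned strand-oriented profile around a gene anchor
#'
#' Bin `b` is the mean per-base density over
#' `[from_off + b*bin_size, from_off + (b+1)*bin_size)` in transcription
#' direction relative to the anchor.
#'
#' @param track a `coverage_track`
#' @param gene single-row `gene_catalog`
#' @param anchor `"TSS"` or `"TTS"`
#' @param span `c(from_off, to_off)` in bp; must be a multiple of `bin_size`
#' @param bin_size bin width, bp
#' @return an `anchored_profile`
#' @export
anchored_profile <- function(track, gene, anchor = c("TSS", "TTS"),
                             span = c(-2000, 5000), bin_size = 50) {
  anchor <- match.arg(anchor)
  width <- span[2] - span[1]
  if (width %% bin_size != 0) stop("span must be a multiple of bin_size")
  n_bins <- width %/% bin_size
  a0 <- if (anchor == "TSS") {
    if (gene$strand == "+") gene$start else gene$end - 1
  } else {
    if (gene$strand == "+") gene$end - 1 else gene$start
  }
  v <- track$values[[gene$chrom]]
  if (is.null(v)) stop("coverage track missing chromosome: ", gene$chrom)
  # fast path: whole span in bounds -> one slice, reshape
  if (gene$strand == "+") {
    gs <- a0 + span[1]; ge <- a0 + span[2]
    if (gs >= 0 && ge <= length(v)) {
      m <- matrix(v[(gs + 1):ge], nrow = bin_size)
      return(new_anchored_profile(gene$gene_id, anchor, colMeans(m),
                                  bin_size, span))
    }
  } else {
    gs <- a0 - span[2] + 1; ge <- a0 - span[1] + 1
    if (gs >= 0 && ge <= length(v)) {
      m <- matrix(rev(v[(gs + 1):ge]), nrow = bin_size)
      return(new_anchored_profile(gene$gene_id, anchor, colMeans(m),
                                  bin_size, span))
    }
  }
  # slow path with per-bin clipping at chromosome edges; window_density is
  # reused against a 1-bp pseudo-gene whose TSS sits at the anchor
  pseudo <- gene
  pseudo$start <- a0
  pseudo$end <- a0 + 1
  bins <- vapply(seq_len(n_bins) - 1L, function(b) {
    lo <- span[1] + b * bin_size
    window_density(track, pseudo, lo, lo + bin_size)
  }, numeric(1))
  new_anchored_profile(gene$gene_id, anchor, bins, bin_size, span)
}

#' Profile matrix over a catalog
#'
#' Builds the genes-by-bins matrix behind a TSS heatmap, rows in catalog
#' order.
#'
#' @inheritParams anchored_profile
#' @param catalog a `gene_catalog`
#' @return numeric matrix, `rownames = gene_id`
#' @export
profile_matrix <- function(track, catalog, anchor = "TSS",
                           span = c(-2000, 5000), bin_size = 50) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    anchored_profile(track, catalog[i, , drop = FALSE], anchor, span,
                     bin_size)$bins
  })
  m <- do.call(rbind, rows)
  rownames(m) <- catalog$gene_id
  m
}

#' Average anchored profiles into a metaprofile
#'
#' @param profiles list of `anchored_profile`s sharing anchor, span and
#'   bin size, or a genes-by-bins matrix from [profile_matrix()]
#' @param stat `"mean"` or `"median"` across genes, per bin
#' @param normalize `"none"` or `"AUC"` (divide by the integral
#'   `sum(bins * bin_size)` so the profile integrates to 1)
#' @param bin_size,span,anchor required when `profiles` is a matrix
#' @param label condition label carried on the result
#' @return a `meta_profile`
#' @export
meta_profile <- function(profiles, stat = c("mean", "median"),
                         normalize = c("none", "AUC"),
                         bin_size = NULL, span = NULL, anchor = "TSS",
                         label = "") {
  stat <- match.arg(stat)
  normalize <- match.arg(normalize)
  if (is.matrix(profiles)) {
    m <- profiles
    stopifnot(!is.null(bin_size), !is.null(span))
  } else {
    if (!length(profiles)) stop("empty profile collection")
    key <- function(p) paste(p$anchor, p$span[1], p$span[2], p$bin_size)
    if (length(unique(vapply(profiles, key, ""))) != 1) {
      stop("profiles mix anchors, spans or bin sizes")
    }
    bin_size <- profiles[[1]]$bin_size
    span <- profiles[[1]]$span
    anchor <- profiles[[1]]$anchor
    m <- do.call(rbind, lapply(profiles, `[[`, "bins"))
  }
  bins <- if (stat == "mean") colMeans(m) else apply(m, 2, stats::median)
  if (normalize == "AUC") {
    auc <- sum(bins * bin_size)
    if (auc <= 0) stop("AUC normalization undefined: profile integrates to 0")
    bins <- bins / auc
  }
  new_meta_profile(bins, nrow(m), bin_size, span, anchor,
                   normalization = if (normalize == "AUC") "AUC" else "none",
                   stat = stat, label = label)
}

#' UV-minus-mock redistribution profile
#'
#' Per-bin signed difference between two metaprofiles on identical bins.
#' With AUC-normalized inputs the difference integrates to zero, isolating
#' where signal moved rather than how much there is.
#'
#' @param uv,mock `meta_profile`s with identical bins and normalization
#' @return a `meta_profile` with `normalization = "difference"`; bins may be
#'   negative
#' @export
redistribution <- function(uv, mock) {
  if (!identical(uv$span, mock$span) || uv$bin_size != mock$bin_size ||
      length(uv$bins) != length(mock$bins)) {
    stop("redistribution requires identical binning")
  }
  if (!identical(uv$normalization, mock$normalization)) {
    stop("redistribution requires matching normalization (AUC recommended)")
  }
  new_meta_profile(uv$bins - mock$bins, min(uv$n_genes, mock$n_genes),
                   uv$bin_size, uv$span, uv$anchor,
                   normalization = "difference", stat = uv$stat,
                   label = sprintf("%s - %s", uv$label, mock$label))
}

#' Length-scaled metagene profile
#'
#' Fixed-width flank bins on both sides plus a gene body rescaled to a fixed
#' number of equal-fraction bins, so genes of different lengths align in
#' fractional coordinates. Each body bin is the exact mean of the per-base
#' density over its (generally non-integer) span.
#'
#' @param track a `coverage_track`
#' @param gene single-row `gene_catalog` with length >= `body_bins`
#' @param flank flank width each side, bp (multiple of `bin_size`)
#' @param body_bins number of equal-fraction body bins
#' @param bin_size flank bin width, bp
#' @return an `anchored_profile` with `span` expressed in bin units
#'   (`flank/bin_size` bins, then `body_bins`, then `flank/bin_size`)
#' @export
metagene_scaled <- function(track, gene, flank = 2000, body_bins = 100,
                            bin_size = 50) {
  len <- gene$end - gene$start
  if (len < body_bins) stop("gene shorter than body_bins")
  if (flank %% bin_size != 0) stop("flank must be a multiple of bin_size")
  v <- track$values[[gene$chrom]]
  if (is.null(v)) stop("coverage track missing chromosome: ", gene$chrom)
  # oriented per-base vector over [-flank, len + flank)
  if (gene$strand == "+") {
    gs <- gene$start - flank; ge <- gene$end + flank
    if (gs < 0 || ge > length(v)) stop("flank outside chromosome for ", gene$gene_id)
    ori <- v[(gs + 1):ge]
  } else {
    gs <- gene$start - flank; ge <- gene$end + flank
    if (gs < 0 || ge > length(v)) stop("flank outside chromosome for ", gene$gene_id)
    ori <- rev(v[(gs + 1):ge])
  }
  nf <- flank %/% bin_size
  up <- colMeans(matrix(ori[seq_len(flank)], nrow = bin_size))
  down <- colMeans(matrix(ori[(flank + len + 1):(flank + len + flank)],
                          nrow = bin_size))
  body <- ori[(flank + 1):(flank + len)]
  # exact fractional-span means via the cumulative integral of the step fn
  cum <- c(0, cumsum(body))
  S <- function(x) {
    f <- floor(x)
    cum[f + 1] + (x - f) * body[pmin(f + 1, len)]
  }
  edges <- len * (0:body_bins) / body_bins
  body_means <- (S(edges[-1]) - S(edges[-(body_bins + 1)])) / diff(edges)
  new_anchored_profile(gene$gene_id, "TSS", c(up, body_means, down),
                       bin_size, c(-flank, flank + bin_size * body_bins + flank))
}

#' Write a metaprofile (or several) as TSV
#'
#' @param profiles a `meta_profile` or named list of them (shared binning)
#' @param path output path; columns are `offset` then one per profile
#' @return `path`, invisibly
#' @export
write_meta_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "meta_profile")) profiles <- list(profile = profiles)
  off <- bin_offsets(profiles[[1]])
  df <- data.frame(offset = off)
  for (nm in names(profiles)) df[[nm]] <- profiles[[nm]]$bins
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
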