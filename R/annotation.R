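#' Gene catalogs: loading and selection
#'
#' A gene catalog is a data frame of oriented gene intervals — one row per
#' gene with columns `gene_id`, `chrom`, `start`, `end`, `strand` — carrying
#' a `provenance` attribute that records every filter applied to it.
#' Coordinates follow the BED convention: 0-based, half-open `[start, end)`.
#' The TSS of a plus-strand gene is `start`; of a minus-strand gene, `end - 1`.
#'
#' @name gene_catalog
NULL

new_gene_catalog <- function(df, provenance = list()) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$strand <- as.character(df$strand)
  if (any(df$end <= df$start)) {
    stop("gene catalog: every gene must satisfy end > start")
  }
  if (anyDuplicated(df$gene_id)) {
    stop("gene catalog: duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene catalog: strand must be '+' or '-'")
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("gene_catalog", "data.frame"))
}

#' TSS / TTS / length accessors
#'
#' @param catalog a `gene_catalog`
#' @return numeric vector, one value per gene (0-based coordinates)
#' @export
tss <- function(catalog) {
  ifelse(catalog$strand == "+", catalog$start, catalog$end - 1)
}

#' @rdname tss
#' @export
tts <- function(catalog) {
  ifelse(catalog$strand == "+", catalog$end - 1, catalog$start)
}

#' @rdname tss
#' @export
gene_length <- function(catalog) {
  catalog$end - catalog$start
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("provenance:", paste(names(prov), collapse = " -> "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Catalog provenance
#'
#' @param catalog a `gene_catalog`
#' @return named list of filter records, in application order
#' @export
catalog_provenance <- function(catalog) {
  attr(catalog, "provenance") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a TSS table as a gene catalog
#'
#' Reads oriented gene intervals from BED6 (`chrom start end name score
#' strand`) or a headered TSV with columns `chrom`, `start`, `end`, `strand`,
#' `gene_id`. Rows with a strand other than `+`/`-` are a parse error: an
#' unoriented gene has no TSS and cannot enter any downstream computation.
#'
#' @param path file path
#' @param format `"BED6"` or `"TSS-TSV"` (default guessed from extension:
#'   `.bed` is BED6, anything else TSS-TSV)
#' @return a `gene_catalog`
#' @export
load_tss_table <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED6" else "TSS-TSV"
  }
  format <- match.arg(format, c("BED6", "TSS-TSV"))
  if (format == "BED6") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "[ \t]+")
    bad <- which(vapply(fields, length, 1L) < 6L)
    if (length(bad)) {
      stop(sprintf("BED6 parse error at line %d: expected 6 columns", bad[1]))
    }
    df <- data.frame(
      chrom = vapply(fields, `[[`, "", 1L),
      start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
      end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
      gene_id = vapply(fields, `[[`, "", 4L),
      strand = vapply(fields, `[[`, "", 6L),
      stringsAsFactors = FALSE
    )
    bad <- which(is.na(df$start) | is.na(df$end))
    if (length(bad)) {
      stop(sprintf("BED6 parse error at line %d: non-numeric coordinate", bad[1]))
    }
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "gene_id")
    if (!all(need %in% names(df))) {
      stop("TSS-TSV must have header columns: ", paste(need, collapse = ", "))
    }
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: strand '%s' is not '+' or '-'",
                 bad[1] + (format == "TSS-TSV"), df$strand[bad[1]]))
  }
  new_gene_catalog(df, provenance = list(source = list(path = path, format = format)))
}

#' Select non-overlapping genes by length and spacing
#'
#' Retains genes whose annotated span is within `[min_len, max_len]` and
#' whose interval, expanded by `flank` on both sides, intersects no *other*
#' gene in the input catalog. The spacing test runs against the full input —
#' a gene that fails the length filter still disqualifies a close neighbour,
#' since its reads contaminate the neighbour's profile regardless of its own
#' length.
#'
#' @param catalog a `gene_catalog`
#' @param min_len,max_len inclusive length bounds in bp (`max_len = Inf` for
#'   unbounded)
#' @param flank required clearance to any other gene, bp
#' @return filtered `gene_catalog`; parameters are appended to provenance
#' @export
select_nonoverlapping <- function(catalog, min_len = 3000, max_len = 100000,
                                  flank = 2000) {
  stopifnot(min_len >= 0, flank >= 0)
  if (nrow(catalog) == 0) {
    return(new_gene_catalog(as.data.frame(catalog),
                            provenance = c(catalog_provenance(catalog),
                                           list(nonoverlap = list(min_len = min_len,
                                                                  max_len = max_len,
                                                                  flank = flank)))))
  }
  len_ok <- gene_length(catalog) >= min_len & gene_length(catalog) <= max_len
  iso <- vapply(seq_len(nrow(catalog)), function(i) {
    same <- which(catalog$chrom == catalog$chrom[i])
    same <- setdiff(same, i)
    if (!length(same)) return(TRUE)
    # expanded [start - flank, end + flank) must miss every other interval
    all(catalog$start[same] >= catalog$end[i] + flank |
          catalog$end[same] <= catalog$start[i] - flank)
  }, logical(1))
  keep <- len_ok & iso
  new_gene_catalog(as.data.frame(catalog)[keep, , drop = FALSE],
                   provenance = c(catalog_provenance(catalog),
                                  list(nonoverlap = list(min_len = min_len,
                                                         max_len = max_len,
                                                         flank = flank,
                                                         n_in = nrow(catalog),
                                                         n_out = sum(keep)))))
}

#' Select expressed genes by length class and TSS spacing
#'
#' Nascent-RNA gene selection: keep genes with expression of at least
#' `min_rpkm`, length within `(lo, hi]`, and a TSS at least `tss_spacing`
#' away from the TSS of every other candidate passing the expression and
#' length filters. Genes absent from the expression table count as
#' unexpressed (RPKM 0).
#'
#' @param catalog a `gene_catalog`
#' @param rpkm named numeric vector (names = gene_id) or data frame with
#'   columns `gene_id`, `rpkm`
#' @param min_rpkm minimum expression, RPKM
#' @param tss_spacing minimum TSS-to-TSS distance, bp
#' @param length_bounds `(lo, hi]` length bounds in bp
#' @return filtered `gene_catalog`
#' @export
select_expressed_by_length <- function(catalog, rpkm, min_rpkm = 0.05,
                                       tss_spacing = 10000,
                                       length_bounds = c(25000, 50000)) {
  if (is.data.frame(rpkm)) {
    rpkm <- stats::setNames(rpkm$rpkm, rpkm$gene_id)
  }
  if (any(rpkm < 0)) stop("negative RPKM value")
  expr <- rpkm[catalog$gene_id]
  expr[is.na(expr)] <- 0
  len <- gene_length(catalog)
  cand <- expr >= min_rpkm & len > length_bounds[1] & len <= length_bounds[2]
  pos <- tss(catalog)
  keep <- cand
  for (i in which(cand)) {
    others <- which(cand & catalog$chrom == catalog$chrom[i])
    others <- setdiff(others, i)
    if (length(others) && any(abs(pos[others] - pos[i]) < tss_spacing)) {
      keep[i] <- FALSE
    }
  }
  new_gene_catalog(as.data.frame(catalog)[keep, , drop = FALSE],
                   provenance = c(catalog_provenance(catalog),
                                  list(expressed = list(min_rpkm = min_rpkm,
                                                        tss_spacing = tss_spacing,
                                                        length_bounds = length_bounds,
                                                        n_out = sum(keep)))))
}

#' Rank genes by TSS-window binding and keep the top n
#'
#' Ranks genes by mean per-bp density in a strand-oriented window around the
#' TSS (default the symmetric 1-kb neighbourhood) and returns the `n` most
#' strongly bound, in rank order. Ties break on lexicographic `gene_id` so
#' the ranking is deterministic.
#'
#' @param catalog a `gene_catalog`
#' @param track a `coverage_track` (typically input-subtracted)
#' @param window `c(from_off, to_off)` in bp relative to the TSS
#' @param n number of genes to keep
#' @return `gene_catalog` of the top `n` genes, ordered by descending
#'   density; scores stored in provenance
#' @export
rank_top_bound <- function(catalog, track, window = c(-1000, 1000), n) {
  stopifnot(window[1] < window[2], n <= nrow(catalog))
  missing_chr <- setdiff(unique(catalog$chrom), names(track$values))
  if (length(missing_chr)) {
    stop("coverage track missing chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  }
  dens <- vapply(seq_len(nrow(catalog)), function(i) {
    window_density(track, catalog[i, , drop = FALSE], window[1], window[2])
  }, numeric(1))
  ord <- order(-dens, catalog$gene_id)
  top <- ord[seq_len(n)]
  new_gene_catalog(as.data.frame(catalog)[top, , drop = FALSE],
                   provenance = c(catalog_provenance(catalog),
                                  list(rank_top_bound = list(
                                    window = window, n = n,
                                    scores = stats::setNames(dens[top],
                                                             catalog$gene_id[top])))))
}

#' Write a catalog as BED6 with a JSON provenance sidecar
#'
#' @param catalog a `gene_catalog`
#' @param path output BED path; provenance goes to `<path>.json`
#' @return `path`, invisibly
#' @export
write_catalog_bed <- function(catalog, path) {
  df <- data.frame(catalog$chrom, format(catalog$start, scientific = FALSE, trim = TRUE),
                   format(catalog$end, scientific = FALSE, trim = TRUE),
                   catalog$gene_id, 0L, catalog$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(catalog_provenance(catalog), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
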