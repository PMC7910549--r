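#' Fragment sets and coverage tracks
#'
#' A `fragment_set` holds deduplicated sequencing fragments as 0-based
#' half-open intervals plus the library's total mapped-fragment count (which
#' may exceed the number of intervals when fragments outside the modelled
#' region were dropped). A `coverage_track` holds one dense per-base depth
#' vector per chromosome and a normalization state that only moves forward:
#' `raw` -> `per10M` (fragments-per-base per 10 million mapped) ->
#' `input_subtracted`.
#'
#' @name coverage_track
NULL

#' @param fragments data frame with columns `chrom`, `start`, `end`
#' @param mapped_count total mapped fragments in the library
#' @rdname coverage_track
#' @export
fragment_set <- function(fragments, mapped_count = nrow(fragments)) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$end <= fragments$start)) {
    stop("fragment_set: every fragment must satisfy end > start")
  }
  if (mapped_count < nrow(fragments)) {
    stop("fragment_set: mapped_count below number of fragments")
  }
  structure(list(fragments = fragments, mapped_count = mapped_count),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments, %s mapped\n",
              nrow(x$fragments), format(x$mapped_count, big.mark = ",")))
  invisible(x)
}

new_coverage_track <- function(values, state) {
  stopifnot(is.list(values), !is.null(names(values)))
  structure(list(values = values, state = state), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track [%s]: %s\n", x$state,
              paste(sprintf("%s (%d bp)", names(x$values),
                            lengths(x$values)), collapse = ", ")))
  invisible(x)
}

#' Accumulate fragments into per-base raw depth
#'
#' `depth(x)` is the number of fragments whose interval covers base `x`.
#' Implemented as a difference-array cumulative sum, linear in genome size.
#'
#' @param fragments a `fragment_set`
#' @param chrom_sizes named numeric vector of chromosome lengths (bp)
#' @return `coverage_track` in state `raw`
#' @export
pileup <- function(fragments, chrom_sizes) {
  fr <- fragments$fragments
  missing_chr <- setdiff(unique(fr$chrom), names(chrom_sizes))
  if (length(missing_chr)) {
    stop("fragments on chromosome(s) absent from chrom_sizes: ",
         paste(missing_chr, collapse = ", "))
  }
  values <- lapply(names(chrom_sizes), function(chr) {
    len <- as.integer(chrom_sizes[[chr]])
    f <- fr[fr$chrom == chr, , drop = FALSE]
    if (nrow(f) && (any(f$start < 0) || any(f$end > len))) {
      bad <- which(f$start < 0 | f$end > len)[1]
      stop(sprintf("fragment [%d,%d) outside %s (length %d)",
                   f$start[bad], f$end[bad], chr, len))
    }
    if (!nrow(f)) return(numeric(len))
    delta <- tabulate(f$start + 1L, nbins = len + 1L) -
      tabulate(f$end + 1L, nbins = len + 1L)
    cumsum(delta)[seq_len(len)]
  })
  names(values) <- names(chrom_sizes)
  new_coverage_track(values, "raw")
}

#' Normalize raw depth to 10 million mapped fragments
#'
#' @param track `coverage_track` in state `raw`
#' @param mapped_count library size used for the scaling factor
#' @return `coverage_track` in state `per10M`
#' @export
normalize_per_10M <- function(track, mapped_count) {
  if (track$state != "raw") stop("normalize_per_10M expects a raw track")
  if (mapped_count <= 0) stop("mapped_count must be positive")
  new_coverage_track(lapply(track$values, function(v) v * (1e7 / mapped_count)),
                     "per10M")
}

#' Subtract an input (control) track, clipping negatives to zero
#'
#' Background correction for ChIP signal: per-base sample minus input, with
#' negative differences set to 0 so no impossible negative read density
#' enters downstream ratios.
#'
#' @param sample,input `coverage_track`s in state `per10M` with identical
#'   chromosome extents
#' @return `coverage_track` in state `input_subtracted`
#' @export
subtract_input <- function(sample, input) {
  if (sample$state != "per10M" || input$state != "per10M") {
    stop("subtract_input expects two per10M tracks")
  }
  if (!identical(lengths(sample$values), lengths(input$values))) {
    stop("chromosome extents differ between sample and input")
  }
  out <- Map(function(s, i) pmax(s - i, 0), sample$values, input$values)
  new_coverage_track(out, "input_subtracted")
}

# Strand-oriented genomic window of [from_off, to_off) around a gene's TSS.
# On the minus strand, offset k maps to genomic base tss - k, so the window
# reverses: [tss - to + 1, tss - from + 1).
oriented_window <- function(gene, from_off, to_off) {
  t0 <- if (gene$strand == "+") gene$start else gene$end - 1
  if (gene$strand == "+") {
    c(t0 + from_off, t0 + to_off)
  } else {
    c(t0 - to_off + 1, t0 - from_off + 1)
  }
}

#' Mean per-base density over a strand-oriented TSS window
#'
#' Offsets are in transcription direction: on a minus-strand gene a positive
#' offset runs toward smaller genomic coordinates. Windows extending past a
#' chromosome edge are clipped (with a warning) and the mean uses the
#' clipped width; a window entirely off-chromosome is an error.
#'
#' @param track a `coverage_track`
#' @param gene single-row `gene_catalog` (or any one-row data frame with the
#'   catalog columns)
#' @param from_off,to_off window `[from_off, to_off)` in bp relative to TSS
#' @return mean per-base value (same units as the track)
#' @export
window_density <- function(track, gene, from_off, to_off) {
  stopifnot(from_off < to_off)
  chr <- gene$chrom
  v <- track$values[[chr]]
  if (is.null(v)) stop("coverage track missing chromosome: ", chr)
  w <- oriented_window(gene, from_off, to_off)
  gs <- w[1]; ge <- w[2]
  cs <- max(gs, 0); ce <- min(ge, length(v))
  if (ce <= cs) {
    stop(sprintf("window [%d,%d) for gene %s lies outside %s",
                 gs, ge, gene$gene_id, chr))
  }
  if (cs > gs || ce < ge) {
    warning(sprintf("window [%d,%d) for gene %s clipped to [%d,%d)",
                    gs, ge, gene$gene_id, cs, ce))
  }
  sum(v[(cs + 1):ce]) / (ce - cs)
}

#' Read / write fragment BED and bedGraph
#'
#' Plain 0-based half-open text formats: fragment BED is 3+ columns
#' (`chrom start end`), bedGraph is 4 columns (`chrom start end value`) with
#' zero runs omitted.
#'
#' @param path file path
#' @param mapped_count library size to attach (default: number of intervals)
#' @return `read_fragment_bed`: a `fragment_set`; `read_bedgraph`: a
#'   `coverage_track`; writers return `path` invisibly
#' @export
read_fragment_bed <- function(path, mapped_count = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  fragment_set(df[, 1:3], mapped_count %||% nrow(df))
}

#' @param fragments a `fragment_set`
#' @rdname read_fragment_bed
#' @export
write_fragment_bed <- function(fragments, path) {
  fr <- fragments$fragments
  utils::write.table(
    data.frame(fr$chrom,
               format(fr$start, scientific = FALSE, trim = TRUE),
               format(fr$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param track a `coverage_track`
#' @param state normalization state to attach on read
#' @rdname read_fragment_bed
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chr, starts[keep], ends[keep],
                         format(r$values[keep], scientific = FALSE, trim = TRUE)),
                 con)
    }
  }
  invisible(path)
}

#' @param chrom_sizes named numeric vector of chromosome lengths
#' @rdname read_fragment_bed
#' @export
read_bedgraph <- function(path, chrom_sizes, state = "raw") {
  values <- lapply(chrom_sizes, function(len) numeric(as.integer(len)))
  names(values) <- names(chrom_sizes)
  if (file.size(path) > 0) {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    missing_chr <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(missing_chr)) {
      stop("bedGraph chromosome(s) absent from chrom_sizes: ",
           paste(missing_chr, collapse = ", "))
    }
    for (i in seq_len(nrow(df))) {
      values[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- df$value[i]
    }
  }
  new_coverage_track(values, state)
}

#' @rdname read_fragment_bed
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  stats::setNames(df$size, df$chrom)
}

#' @rdname read_fragment_bed
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(names(chrom_sizes),
               format(chrom_sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
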