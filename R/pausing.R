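#' Traveling ratios and shift classification
#'
#' The traveling ratio (pausing index) of a gene is the mean per-bp signal
#' density in an early gene-body window divided by the density in the
#' promoter-proximal window. A higher ratio means more polymerase released
#' from the pause site into the body. Two window presets are used:
#'
#' * `RNAPII`: promoter (-750, +250), body (+250, +3000) relative to TSS
#' * `PAF1`:   promoter (-750, 0),   body (0, +1000)
#'
#' Ratios are normalized so the unirradiated (mock) cohort averages 1, and
#' genes whose UV/mock ratio exceeds 1 in every replicate comparison are
#' classified `ALL_SHIFT` (uniform UV-induced release), the rest
#' `MIXED_SHIFT`. Genes with zero promoter density have no finite ratio and
#' are excluded from all distributions and classifications.
#'
#' @name pausing
NULL

#' Traveling-ratio window presets
#'
#' @param preset `"RNAPII"`, `"PAF1"`, or `"custom"`
#' @param promoter,body `c(from_off, to_off)` bp windows relative to TSS
#'   (required for `"custom"`, ignored otherwise)
#' @return a `tr_windows` list with elements `promoter`, `body`, `label`
#' @export
tr_windows <- function(preset = c("RNAPII", "PAF1", "custom"),
                       promoter = NULL, body = NULL) {
  preset <- match.arg(preset)
  w <- switch(preset,
    RNAPII = list(promoter = c(-750, 250), body = c(250, 3000)),
    PAF1 = list(promoter = c(-750, 0), body = c(0, 1000)),
    custom = {
      stopifnot(!is.null(promoter), !is.null(body))
      list(promoter = promoter, body = body)
    })
  stopifnot(w$promoter[1] < w$promoter[2], w$body[1] < w$body[2])
  w$label <- preset
  structure(w, class = "tr_windows")
}

#' Traveling ratio of one gene
#'
#' @param track a `coverage_track` (`per10M` or `input_subtracted`)
#' @param gene single-row `gene_catalog`
#' @param windows a [tr_windows()] preset
#' @return list with `promoter_density`, `body_density`, `tr` (NA when the
#'   promoter density is 0), `finite`
#' @export
traveling_ratio <- function(track, gene, windows = tr_windows("RNAPII")) {
  p <- window_density(track, gene, windows$promoter[1], windows$promoter[2])
  b <- window_density(track, gene, windows$body[1], windows$body[2])
  finite <- p > 0
  list(promoter_density = p, body_density = b,
       tr = if (finite) b / p else NA_real_, finite = finite)
}

#' Traveling-ratio table across samples
#'
#' @param tracks named list of `coverage_track`s, one per sample
#' @param catalog a `gene_catalog`
#' @param windows a [tr_windows()] preset
#' @return data frame in long format: `gene_id`, `sample`,
#'   `promoter_density`, `body_density`, `tr`, `finite`; class
#'   `tr_table`
#' @export
traveling_ratio_table <- function(tracks, catalog,
                                  windows = tr_windows("RNAPII")) {
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  rows <- lapply(names(tracks), function(s) {
    res <- lapply(seq_len(nrow(catalog)), function(i) {
      traveling_ratio(tracks[[s]], catalog[i, , drop = FALSE], windows)
    })
    data.frame(gene_id = catalog$gene_id, sample = s,
               promoter_density = vapply(res, `[[`, 0, "promoter_density"),
               body_density = vapply(res, `[[`, 0, "body_density"),
               tr = vapply(res, `[[`, 0, "tr"),
               finite = vapply(res, `[[`, TRUE, "finite"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "windows") <- windows
  class(out) <- c("tr_table", "data.frame")
  out
}

#' Normalize traveling ratios to the mock average
#'
#' Divides every gene's ratio by the mean finite ratio over the mock
#' (unirradiated) samples, so the mock cohort averages 1 by construction
#' and UV samples read directly as fold-release.
#'
#' @param table a `tr_table`
#' @param mock_samples character vector of mock sample names
#' @return the table with a `normalized_tr` column; the mock mean is stored
#'   in `attr(, "mock_mean_tr")`
#' @export
normalize_tr <- function(table, mock_samples) {
  stopifnot(length(mock_samples) > 0)
  missing_s <- setdiff(mock_samples, unique(table$sample))
  if (length(missing_s)) stop("unknown mock sample(s): ",
                              paste(missing_s, collapse = ", "))
  mock <- table[table$sample %in% mock_samples & table$finite, ]
  if (!nrow(mock)) stop("no finite mock traveling ratio to normalize against")
  mu <- mean(mock$tr)
  table$normalized_tr <- table$tr / mu
  attr(table, "mock_mean_tr") <- mu
  table
}

#' Fraction of genes with normalized traveling ratio above 1
#'
#' Strictly greater than 1, among genes with a finite ratio in the sample.
#'
#' @param table a `tr_table` after [normalize_tr()]
#' @param sample sample name
#' @return list with `fraction`, `n_above`, `n_finite`
#' @export
fraction_above_one <- function(table, sample) {
  if (is.null(table$normalized_tr)) stop("run normalize_tr first")
  x <- table[table$sample == sample & table$finite, "normalized_tr"]
  list(fraction = mean(x > 1), n_above = sum(x > 1), n_finite = length(x))
}

#' Classify genes as All-Shift or Mixed-Shift across replicate comparisons
#'
#' For each (UV sample, mock reference) comparison a gene scores `TRUE` when
#' its UV/mock traveling-ratio increase is strict (`tr_UV / tr_mock > 1`).
#' `ALL_SHIFT` genes shift in every comparison; all other classifiable
#' genes are `MIXED_SHIFT`. A gene is classifiable only when both members
#' of every comparison have a finite ratio; the rest are reported with
#' `class = NA` in an unclassifiable bucket.
#'
#' @param table a `tr_table`
#' @param uv_comparisons list of `c(uv_sample, mock_reference)` pairs (or
#'   2-element lists)
#' @return data frame: `gene_id`, one logical column per comparison,
#'   `n_shifted`, `classifiable`, `class`
#' @export
classify_shift <- function(table, uv_comparisons) {
  if (!length(uv_comparisons)) stop("empty comparison list")
  genes <- unique(table$gene_id)
  tr_of <- function(s) {
    sub <- table[table$sample == s, ]
    stats::setNames(ifelse(sub$finite, sub$tr, NA_real_), sub$gene_id)[genes]
  }
  comp_cols <- lapply(uv_comparisons, function(cmp) {
    uv <- tr_of(cmp[[1]]); mock <- tr_of(cmp[[2]])
    uv / mock > 1
  })
  names(comp_cols) <- vapply(uv_comparisons, function(cmp)
    paste0(cmp[[1]], "_vs_", cmp[[2]]), "")
  m <- do.call(cbind, comp_cols)
  classifiable <- !apply(is.na(m), 1, any)
  n_shifted <- rowSums(m)
  cls <- ifelse(!classifiable, NA_character_,
                ifelse(n_shifted == length(uv_comparisons),
                       "ALL_SHIFT", "MIXED_SHIFT"))
  out <- data.frame(gene_id = genes, m, n_shifted = n_shifted,
                    classifiable = classifiable, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("shift_calls", "data.frame")
  out
}

#' Tabulate shift classes
#'
#' @param calls a `shift_calls` data frame
#' @return named counts: `ALL_SHIFT`, `MIXED_SHIFT`, `unclassifiable`
#' @export
shift_class_counts <- function(calls) {
  c(ALL_SHIFT = sum(calls$class == "ALL_SHIFT", na.rm = TRUE),
    MIXED_SHIFT = sum(calls$class == "MIXED_SHIFT", na.rm = TRUE),
    unclassifiable = sum(!calls$classifiable))
}
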