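# Brute-force oracles and shared fixtures. Every oracle recomputes its
# quantity by direct per-base enumeration, independent of the package's
# cumulative-sum / slicing implementations.

# per-base depth by membership counting
oracle_depth <- function(fragments, chrom_sizes) {
  out <- lapply(names(chrom_sizes), function(chr) {
    len <- as.integer(chrom_sizes[[chr]])
    f <- fragments[fragments$chrom == chr, , drop = FALSE]
    vapply(0:(len - 1), function(x) {
      sum(f$start <= x & x < f$end)
    }, numeric(1))
  })
  names(out) <- names(chrom_sizes)
  out
}

# genomic 0-based positions of strand-oriented offsets [from, to) rel. TSS
oracle_positions <- function(gene, from, to) {
  t0 <- if (gene$strand == "+") gene$start else gene$end - 1
  k <- from:(to - 1)
  if (gene$strand == "+") t0 + k else t0 - k
}

oracle_window_mean <- function(values, gene, from, to) {
  pos <- oracle_positions(gene, from, to)
  mean(values[[gene$chrom]][pos + 1])
}

oracle_bins <- function(values, gene, span, bin_size) {
  n <- (span[2] - span[1]) %/% bin_size
  vapply(seq_len(n) - 1L, function(b) {
    oracle_window_mean(values, gene, span[1] + b * bin_size,
                       span[1] + (b + 1) * bin_size)
  }, numeric(1))
}

# ~20 genes / ~1e3 fragments oracle fixture on one small chromosome
make_oracle_fixture <- function(seed = 42) {
  n <- 20
  lens <- rep(c(6000, 9000, 12000), length.out = n)
  starts <- 8000 + c(0, cumsum(lens + 8000))[seq_len(n)]
  catalog <- txrecover:::new_gene_catalog(data.frame(
    gene_id = sprintf("FX%02d", seq_len(n)),
    chrom = "chrF", start = starts, end = starts + lens,
    strand = rep(c("+", "-"), length.out = n),
    stringsAsFactors = FALSE))
  chrom_sizes <- c(chrF = starts[n] + lens[n] + 8000)
  frags <- withr::with_seed(seed, {
    s <- sort(sample.int(chrom_sizes[[1]] - 200, 1000, replace = TRUE)) - 1L
    data.frame(chrom = "chrF", start = s, end = s + 150L,
               stringsAsFactors = FALSE)
  })
  list(catalog = catalog, chrom_sizes = chrom_sizes,
       fragments = fragment_set(frags, mapped_count = 1000))
}

# flat track of constant value c over given chromosome sizes
flat_track <- function(chrom_sizes, value = 1, state = "per10M") {
  txrecover:::new_coverage_track(
    lapply(chrom_sizes, function(len) rep(value, as.integer(len))), state)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "txrecover", mustWork = TRUE)
}
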