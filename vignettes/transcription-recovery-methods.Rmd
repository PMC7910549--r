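---
title: "Quantifying UV-induced RNAPII repositioning and transcription recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying UV-induced RNAPII repositioning and transcription recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Bulky UV lesions in transcribed strands stall elongating RNA polymerase II
(RNAPII). Cells respond by accumulating RNAPII — together with the
pause-release factor PAF1C — at promoter-proximal pause sites, and restart
transcription as a wave that moves from the promoter toward the gene end
while transcription-coupled repair clears lesions. `txrecover` implements
the downstream quantification of this response from three data types:

* **ChIP-seq fragment coverage** of RNAPII, PAF1 or Ub-H2B, used to
  measure where polymerase sits relative to each gene's transcription
  start site (TSS);
* **BrU-seq nascent-RNA coverage**, used to measure how far transcription
  has recovered along gene bodies at each timepoint;
* **pull-down proteomics intensity matrices**, used to identify
  UV-specific protein interactions.

A seeded synthetic-data generator reproduces the signal structure these
analyses assume, so the whole pipeline is testable end to end without any
sequencing download.

## Traveling ratios and shift classification

For a gene $g$ and sample $s$, with mean per-bp input-subtracted coverage
$d_{\mathrm{prom}}$ over a promoter-proximal window and $d_{\mathrm{body}}$
over an early gene-body window (both strand-oriented relative to the TSS),
the traveling ratio is

$$\mathrm{TR}(g, s) = \frac{d_{\mathrm{body}}(g, s)}{d_{\mathrm{prom}}(g, s)}.$$

Two presets are provided: RNAPII uses promoter $(-750, +250)$ and body
$(+250, +3000)$; PAF1 uses promoter $(-750, 0)$ and body $(0, +1000)$ (bp
relative to the TSS). Genes with zero promoter density have no finite
ratio and are excluded from every distribution and classification.
Normalized ratios divide by the mean finite ratio of the unirradiated
cohort, so the mock average is 1 by construction and UV samples read
directly as fold-release. We compute the ratio on per-bp *densities*
rather than raw window sums: the two conventions differ by the constant
ratio of window widths, which cancels exactly under mock normalization
(asserted to $10^{-12}$ relative in the tests), and densities make the
flat-coverage identity $\mathrm{TR} = 1$ hold.

A gene is **All-Shift** when $\mathrm{TR}_{UV}/\mathrm{TR}_{mock} > 1$
(strict, no margin — the only threshold the underlying analysis defines)
in *every* replicate comparison, and **Mixed-Shift** otherwise. When
sample metadata pairs replicates, each UV sample is compared to its
matched mock; unpaired designs fall back to a pooled mock reference.
Replicate-matched pairing keeps the comparisons independent, which is
what makes the null All-Shift rate equal $0.5^k$ for $k$ comparisons — a
calibration property the acceptance suite verifies. Genes non-finite in
any required sample are reported in an explicit "unclassifiable" bucket.

## Coverage, profiles and normalization

Coverage is full-fragment per-base depth (not 5′-end tags or midpoints),
normalized to 10 million mapped fragments. Input control subtraction is
per-base with negatives clipped to zero, since a negative read density is
not physically meaningful; clipping is idempotent. Windows are half-open
in offset space; a window that runs off a chromosome edge is clipped with
a warning and the clipped width is used as the divisor, so edge genes
do not crash a genome-wide run — a fully out-of-bounds window is an error.

Metaprofiles average per-gene anchored profiles (default TSS span
$-2$ kb to $+5$ kb, 50-bp bins — fine enough to resolve a 1–2 kb shift)
and can be normalized to unit area under the curve (AUC), which compares
profile *shapes* across conditions with different overall read density.
AUC normalization is applied to the averaged profile, not per gene.
Redistribution profiles subtract mock from UV; with AUC inputs they
integrate to zero by construction, isolating where signal moved.
Length-scaled metagene profiles use exact fractional-span means over the
per-base step function, so bodies of different lengths align without
rounding bias.

The top-bound gene ranking uses the mean input-subtracted density in a
symmetric $\pm 1$ kb TSS window of the unirradiated sample. The window is
a documented default — the underlying analysis ranks on unirradiated
signal without stating a window — and ties break on lexicographic gene id
so the ranking is deterministic.

## Ub-H2B gene-body profiles

H2B monoubiquitylation is deposited co-transcriptionally, so its
gene-body profile tracks elongation. Profiles are background-subtracted
using the single bin containing the point 200 bp upstream of the TSS (the
minimal reading of a point-wise background), negatives clipped, and then
rescaled so the profile integral equals an imaging-derived global level
(reference condition = 1). ChIP-seq normalizes away global losses; the
imaging scalar restores them. The packaged
`ubh2b_global_levels.tsv` carries the fractions used in the worked
example (wild type 0.63, repair-deficient 0.38 at 8 h after 9 J/m²).

## BrU-seq recovery profiles

Reads are counted in strand-oriented 500-bp bins from 5 kb upstream of
the TSS and converted to RPKM
($\mathrm{reads} / (\mathrm{bin~kb} \times \mathrm{mapped~millions})$).
The per-bin *median* across genes (robust to a few highly expressed
outliers) is baseline-zeroed by subtracting the mean of the upstream
bins. Negative post-baseline bins are retained — the baseline is a
display convention and clipping would bias the decay fit. Profiles are
then multiplied by the 5-EU-measured nascent-transcription fraction
(e.g. 0.62 = 62% of control synthesis), converting the library-relative
RPKM distribution into absolute nascent-transcription units; this step is
what makes UV/mock bin ratios meaningful.

Two summaries are computed. The **recovery front** is the largest
distance $d$ such that the UV/mock ratio stays at or above a threshold
(default 0.5) in every bin of $(0, d]$. The **decay length** $L$ comes
from an ordinary least-squares fit of $\log(\mathrm{UV}/\mathrm{mock})$
against distance over bins beyond the front, where elongation is limited
by the lesion density: the expected slope is $-1/L$, with
$L \approx 16$ kb at the 7 J/m²-equivalent lesion density (one
cyclobutane pyrimidine dimer per 16 kb).

## Proteomics enrichment

The label-free workflow mirrors the standard Perseus sequence:
contaminant / reverse / identified-by-site removal and log2 transform
(zeros become missing); keep proteins quantified in at least
`min_valid` (default 4) of the replicates of at least one group; impute
missing values from $\mathcal N(\mu - 1.8\sigma, (0.3\sigma)^2)$ where
$\mu, \sigma$ are the mean and s.d. of *all* observed log2 values in the
matrix (whole-matrix statistics; a per-column option exists but is off by
default); then a two-sided two-sample Student's (equal-variance) t-test
per protein — no moderation, no multiple-testing correction in the
primary readout, matching the conventional volcano; a Benjamini–Hochberg
column is emitted as a clearly optional extra. SILAC enrichment flags
proteins at an inclusive $\geq 2$-fold H/L ratio. iBAQ stoichiometry
divides prey iBAQ by bait iBAQ per condition and reports the UV/mock
fold-change of that bound fraction.

## What the synthetic generator emulates — and what it does not

ChIP occupancy per gene is a Gaussian pause peak at the TSS
(height 15, s.d. 100 bp), uniform gene-body occupancy (1 per bp of
pause-height units) attenuated by $e^{-x/L}$, a Gaussian TTS peak
(height 3, s.d. 500 bp) and flat background (0.1). UV moves a fraction
$f$ of the pause mass into a release zone just downstream of the TSS
(2 kb for RNAPII-like, 1 kb for PAF1-like release) with an exponential
shape within the zone (decay constant zone/3) — the zone lengths follow
the observed repositioning ranges, the shape is a modeling choice.
Lesion spacing is anchored at $L = 16$ kb for 7 J/m² and scales as
$1/\mathrm{dose}$; where a release fraction per dose is needed the
generator uses $f = \min(0.9,\, 0.075 \times \mathrm{dose})$ (0.45 at
6 J/m², 0.675 at 9 J/m²), a choice made once to give a clearly
dose-ordered response. Repair-deficient and PAF1-depleted genotypes force
$f = 0$; global occupancy loss is a multiplicative scale. Fragment counts
are Poisson with fixed 200-bp fragments whose *midpoints* are drawn
proportional to the intensity, so the coverage peak sits at the pause
summit. Nascent-transcription tracks put full signal behind a recovery
front moving at an effective 4 kb/h (a repair-limited wave speed, far
below the instantaneous elongation rate) and $e^{-x/L}$ beyond it.
Proteomics matrices are log2-normal (protein baseline s.d. 2, replicate
s.d. 0.5) with planted UV-group shifts and logistic intensity-dependent
missingness.

The generator makes no claim of mechanistic fidelity: real data add
mappability and GC structure, overlapping transcription units, isoform
heterogeneity, burst kinetics, batch effects and correlated replicate
noise, none of which are modelled. Passing tests therefore demonstrate
that the *computations* are correct and calibrated under the assumed
signal structure, not that the biological conclusions transfer to any
particular dataset.

## Numerical and benchmark choices

* Coordinates are 0-based half-open (BED) throughout; the TSS of a
  minus-strand gene is `end - 1`, and all windows and bins run in
  transcription direction.
* Gene length bounds (3–100 kb) are inclusive; the non-overlap test runs
  against the *full* input catalog before length filtering, because a
  short neighbour still contaminates a profile.
* Per-10M scaling uses fragment totals (tag-vs-fragment totals are not
  distinguished upstream of this package).
* Benchmark problem sizes were chosen to make every stochastic check
  decisively powered while keeping the whole suite fast: ChIP cohorts of
  150 genes (4–20 kb) at $10^5$–$2\times10^5$ fragments per library with
  4 + 4 replicates; BrU cohorts of 30 genes (60–90 kb) at $10^6$ reads;
  proteomics null calibration at $10^4$ proteins and imputation moments
  at $10^5$ draws. Null calibration bands are $\pm 3$ binomial standard
  errors.
* In the planted-volcano benchmark the effect size is specified in
  whole-matrix s.d. units ($\Delta = 2\sigma_{\mathrm{matrix}}$, with
  $\sigma_{\mathrm{matrix}} = \sqrt{2^2 + 0.5^2} \approx 2.06$),
  the same $\sigma$ the imputation moments are stated in. Against the
  replicate noise this is a strong, clearly detectable enrichment, which
  is what the benchmark is meant to verify — recovery of planted truth,
  not marginal power.
* The demo 5-EU nascent levels shipped in `nascent_levels.tsv` are
  synthetic illustration values except the PAF1-depleted 3-h fraction
  (0.62), which anchors the absolute-scaling convention.

## Known limitations

* Dense per-base coverage vectors are simple and exact but memory-bound
  for full mammalian genomes (~3 Gb doubles per track); the design
  targets simulated chromosomes and region-restricted analyses.
* The per-replicate shift criterion (strict ratio > 1, no pseudocount)
  is the minimal reading of the underlying convention; published
  All/Mixed-Shift gene counts from deep-sequencing data are sensitive to
  this under-specified choice and are not reproduced at desk scale.
* `recovery_front` assumes a monotone mock-positive body profile; very
  noisy profiles can truncate the front at the first noisy bin. Median
  profiles over ≥ 20 genes are recommended.
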