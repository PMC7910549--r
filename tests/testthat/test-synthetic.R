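test_that("simulated catalogs respect spacing, strand alternation, determinism", {
  sim <- simulate_catalog(10, c(4000, 20000), spacing = 5000, seed = 11)
  cat <- sim$catalog
  expect_equal(nrow(cat), 10)
  gaps <- cat$start[-1] - cat$end[-10]
  expect_true(all(gaps >= 5000))
  expect_equal(cat$strand, rep(c("+", "-"), 5))
  expect_true(all(cat$end <= sim$chrom_sizes[[1]]))
  sim2 <- simulate_catalog(10, c(4000, 20000), spacing = 5000, seed = 11)
  expect_identical(sim, sim2)
  # lengths are log-uniform within the requested range
  big <- simulate_catalog(1000, c(3000, 100000), seed = 12)$catalog
  lens <- gene_length(big)
  expect_true(all(lens >= 3000 & lens <= 100000))
  ks <- suppressWarnings(
    ks.test(log(lens), "punif", log(3000), log(100000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("mock ChIP libraries peak at the pause site", {
  sim <- simulate_catalog(20, c(6000, 12000), spacing = 6000, seed = 21)
  model <- occupancy_model()
  mock <- condition_spec("mock")
  lib <- simulate_chip_library(sim$catalog, sim$chrom_sizes, model, mock,
                               depth = 2e5, seed = 22)
  track <- pileup(lib, sim$chrom_sizes)
  # pooled TSS profile mode within one pause-width of the TSS
  m <- profile_matrix(track, sim$catalog, span = c(-1000, 1000), bin_size = 25)
  pooled <- colMeans(m)
  peak_off <- seq(-1000, 975, 25)[which.max(pooled)] + 12.5
  expect_lt(abs(peak_off), model$pause_width)
})

test_that("full release empties the pause and fills the release zone", {
  sim <- simulate_catalog(10, c(8000, 12000), spacing = 6000, seed = 31)
  model <- occupancy_model(background = 0)
  lam_mock <- txrecover:::chip_intensity(sim$catalog, sim$chrom_sizes, model,
                                         condition_spec("mock"))
  lam_rel <- txrecover:::chip_intensity(sim$catalog, sim$chrom_sizes, model,
                                        condition_spec("uv", release_fraction = 1))
  g <- sim$catalog[1, ]
  # at the pause summit the f=1 intensity drops to release+body only
  summit <- g$start  # + strand, TSS
  pause_part <- lam_mock[[1]][summit + 1] - lam_rel[[1]][summit + 1]
  expect_gt(pause_part / lam_mock[[1]][summit + 1], 0.8)
  # total intensity over the gene is conserved up to the pause tail beyond
  # the zone (release moves mass, it does not create or destroy it)
  rng <- (g$start - 2000):(g$end + 2000)
  expect_equal(sum(lam_rel[[1]][rng]), sum(lam_mock[[1]][rng]),
               tolerance = 0.05)
})

test_that("doubling depth doubles the expected fragment count", {
  sim <- simulate_catalog(10, c(5000, 9000), spacing = 5000, seed = 41)
  model <- occupancy_model()
  mock <- condition_spec("mock")
  n1 <- vapply(1:5, function(s)
    nrow(simulate_chip_library(sim$catalog, sim$chrom_sizes, model, mock,
                               depth = 2e4, seed = s)$fragments), numeric(1))
  n2 <- vapply(1:5, function(s)
    nrow(simulate_chip_library(sim$catalog, sim$chrom_sizes, model, mock,
                               depth = 4e4, seed = 100 + s)$fragments),
    numeric(1))
  # Poisson means 2e4 and 4e4: compare averages within 3 s.e.
  se <- sqrt(mean(n2) / 5 + 4 * mean(n1) / 5)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * se)
})

test_that("windowed fragment counts match the intensity integral", {
  sim <- simulate_catalog(12, c(6000, 10000), spacing = 6000, seed = 51)
  model <- occupancy_model()
  cond <- condition_spec("uv", release_fraction = 0.6,
                         damage_spacing = 16000)
  depth <- 1e5
  lam <- txrecover:::chip_intensity(sim$catalog, sim$chrom_sizes, model, cond)
  lib <- simulate_chip_library(sim$catalog, sim$chrom_sizes, model, cond,
                               depth = depth, seed = 52)
  lam_tot <- sum(lam[[1]])
  fr <- lib$fragments
  mid <- fr$start + 100  # fixed 200-bp fragments -> midpoint = start + 100
  for (i in c(1, 4, 9)) {
    g <- sim$catalog[i, ]
    w <- txrecover:::oriented_window(g, -750, 250)
    expected <- depth * sum(lam[[1]][(w[1] + 1):w[2]]) / lam_tot
    observed <- sum(mid >= w[1] & mid < w[2])
    expect_lt(abs(observed - expected), 3 * sqrt(expected))
  }
})

test_that("genotypes forbid release and same seed gives identical bytes", {
  expect_equal(condition_spec("ko", release_fraction = 0.7,
                              genotype = "CSB_KO")$release_fraction, 0)
  expect_equal(condition_spec("aid", release_fraction = 0.7,
                              genotype = "PAF1_depleted")$release_fraction, 0)
  expect_equal(damage_spacing_for_dose(7), 16000)
  expect_equal(damage_spacing_for_dose(14), 8000)
  expect_equal(damage_spacing_for_dose(0), Inf)
  sim <- simulate_catalog(5, c(5000, 8000), spacing = 5000, seed = 61)
  model <- occupancy_model()
  a <- simulate_chip_library(sim$catalog, sim$chrom_sizes, model,
                             condition_spec("mock"), 1e4, seed = 62)
  b <- simulate_chip_library(sim$catalog, sim$chrom_sizes, model,
                             condition_spec("mock"), 1e4, seed = 62)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fragment_bed(a, f1); write_fragment_bed(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("BrU tracks recover as a wave and report the nascent fraction", {
  sim <- simulate_catalog(15, c(30000, 40000), spacing = 5000, seed = 71)
  mock <- condition_spec("mock")
  uv <- condition_spec("uv3h", damage_spacing = 16000)
  m <- simulate_bru_track(sim$catalog, sim$chrom_sizes, 0, mock,
                          depth = 5e5, seed = 72)
  u0 <- simulate_bru_track(sim$catalog, sim$chrom_sizes, 0, uv,
                           depth = 5e5, seed = 73)
  u3 <- simulate_bru_track(sim$catalog, sim$chrom_sizes, 3, uv,
                           depth = 5e5, seed = 74)
  expect_equal(m$nascent_level, 1)
  expect_lt(u0$nascent_level, u3$nascent_level)
  # t -> infinity approaches mock
  ult <- simulate_bru_track(sim$catalog, sim$chrom_sizes, 1000, uv,
                            depth = 5e5, seed = 75)
  expect_equal(ult$nascent_level, 1)
  # t = 0 decays from the TSS; signal at 30 kb is far below the TSS-side
  g <- sim$catalog[1, ]
  v <- u0$track$values[[1]]
  near <- mean(v[(g$start + 1):(g$start + 2000)])
  far <- mean(v[(g$start + 24000 + 1):(g$start + 28000)])
  expect_lt(far, near * 0.4)
})

test_that("PAF1-depleted BrU keeps the promoter but not the body", {
  sim <- simulate_catalog(10, c(30000, 40000), spacing = 5000, seed = 81)
  aid <- condition_spec("aid", damage_spacing = 16000,
                        genotype = "PAF1_depleted")
  late <- simulate_bru_track(sim$catalog, sim$chrom_sizes, 24, aid,
                             depth = 5e5, seed = 82)
  g <- sim$catalog[1, ]
  v <- late$track$values[[1]]
  pp <- mean(v[(g$start + 1):(g$start + 500)])
  body <- mean(v[(g$start + 20000 + 1):(g$start + 30000)])
  expect_lt(body, pp * 0.5)  # no recovery wave without PAF1
})

test_that("planted proteomics matrices are reproducible with labelled truth", {
  s1 <- simulate_intensity_matrix(500, 50, 2, seed = 91)
  s2 <- simulate_intensity_matrix(500, 50, 2, seed = 91)
  expect_identical(s1$matrix$intensities, s2$matrix$intensities)
  expect_equal(sum(s1$truth), 50)
  # missingness disabled -> complete matrix
  full <- simulate_intensity_matrix(100, 0, 0, missing_model = NULL, seed = 92)
  expect_false(anyNA(full$matrix$intensities))
  # missingness is intensity-dependent: missing cells sit lower
  miss <- s1$matrix$intensities
  comp <- simulate_intensity_matrix(500, 50, 2, missing_model = NULL,
                                    seed = 91)$matrix$intensities
  expect_gt(mean(comp[!is.na(miss)]), mean(comp[is.na(miss)]))
})
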