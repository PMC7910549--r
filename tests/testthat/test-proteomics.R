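mk_linear <- function(m, flags = NULL, ibaq = NULL) {
  intensity_matrix(m, flags, ibaq, state = "linear")
}

test_that("cleanup drops flagged proteins, log2-transforms, zeros go missing", {
  m <- matrix(c(8, 4, 0, 16, 2, 32), nrow = 3,
              dimnames = list(c("keep", "rev", "cont"), c("s1", "s2")))
  flags <- data.frame(contaminant = c(FALSE, FALSE, TRUE),
                      reverse = c(FALSE, TRUE, FALSE),
                      site_only = FALSE)
  out <- clean_and_log2(mk_linear(m, flags))
  expect_equal(rownames(out$intensities), "keep")
  expect_equal(out$intensities["keep", "s1"], 3)      # log2(8)
  expect_equal(out$intensities["keep", "s2"], 4)      # log2(16)
  zero <- clean_and_log2(mk_linear(matrix(c(0, 8), 1,
                                          dimnames = list("p", c("a", "b")))))
  expect_true(is.na(zero$intensities["p", "a"]))
})

test_that("min-valid filter keeps proteins complete in at least one group", {
  design <- group_design(c(m1 = "mock", m2 = "mock", m3 = "mock", m4 = "mock",
                           u1 = "uv", u2 = "uv", u3 = "uv", u4 = "uv"))
  m <- matrix(NA_real_, 3, 8,
              dimnames = list(c("full_mock", "partial", "full_uv"),
                              names(design)))
  m["full_mock", 1:4] <- 20          # 4/4 mock, 0/4 uv -> kept
  m["partial", c(1:3, 5:7)] <- 20    # 3/4 in both -> removed at min_valid 4
  m["full_uv", 5:8] <- 20
  im <- intensity_matrix(m, state = "log2")
  out <- filter_min_valid(im, design, 4)
  expect_setequal(rownames(out$intensities), c("full_mock", "full_uv"))
  # monotone in min_valid; 0 is the identity
  out0 <- filter_min_valid(im, design, 0)
  expect_equal(nrow(out0$intensities), 3)
  out3 <- filter_min_valid(im, design, 3)
  expect_true(all(rownames(out$intensities) %in% rownames(out3$intensities)))
  expect_error(filter_min_valid(im, design, 5), "smallest group")
})

test_that("downshift imputation draws from Normal(mu - 1.8 sd, (0.3 sd)^2)", {
  set.seed(1)
  obs <- rnorm(5000, 20, 2)
  m <- matrix(c(obs, rep(NA_real_, 5000)), ncol = 10,
              dimnames = list(sprintf("p%04d", 1:1000), sprintf("s%02d", 1:10)))
  im <- intensity_matrix(m, state = "log2")
  out <- impute_downshift(im, seed = 7)
  expect_false(anyNA(out$intensities))
  mu <- mean(obs); sigma <- sd(obs)
  imp <- out$intensities[is.na(m)]
  expect_lt(abs(mean(imp) - (mu - 1.8 * sigma)), 0.05 * sigma)
  expect_lt(abs(sd(imp) / (0.3 * sigma) - 1), 0.05)
  # observed values are untouched; same seed reproduces exactly
  expect_equal(out$intensities[!is.na(m)], m[!is.na(m)])
  out2 <- impute_downshift(im, seed = 7)
  expect_identical(out$intensities, out2$intensities)
  out3 <- impute_downshift(im, seed = 8)
  expect_false(identical(out$intensities, out3$intensities))
  empty <- intensity_matrix(matrix(NA_real_, 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))),
                            state = "log2")
  expect_error(impute_downshift(empty), "observed values")
})

test_that("volcano fold-changes and p-values match closed-form t-tests", {
  design <- group_design(c(a1 = "uv", a2 = "uv", b1 = "mock", b2 = "mock"))
  m <- rbind(toy = c(5, 6, 1, 2), null = c(3, 4, 3, 4))
  colnames(m) <- names(design)
  im <- intensity_matrix(m, state = "log2")
  v <- group_ttest_volcano(im, design, c("uv", "mock"))
  expect_equal(v$log2_fc[v$protein == "toy"], 4)
  # closed form: t = 4 / (s_p * sqrt(1/2 + 1/2)), s_p = 1/sqrt(2), df = 2
  tstat <- 4 / sqrt(0.5 * (1 / 2 + 1 / 2))
  expect_equal(v$p_value[v$protein == "toy"],
               2 * pt(-abs(tstat), df = 2))
  expect_equal(v$log2_fc[v$protein == "null"], 0)
  expect_equal(v$p_value[v$protein == "null"], 1)
  # swapping the groups negates fold-change, p unchanged
  v2 <- group_ttest_volcano(im, design, c("mock", "uv"))
  expect_equal(v2$log2_fc, -v$log2_fc)
  expect_equal(v2$p_value, v$p_value)
})

test_that("SILAC enrichment threshold is inclusive at 2-fold", {
  r <- c(hit = 2.0, near = 1.99, strong = 8, weak = 0.5)
  out <- silac_enrichment(r, 2)
  expect_true(out$enriched[out$protein == "hit"])
  expect_false(out$enriched[out$protein == "near"])
  # label swap inverts ratios in log space
  swapped <- silac_enrichment(1 / r, 2)
  expect_equal(swapped$log2_ratio, -out$log2_ratio)
  expect_error(silac_enrichment(c(a = -1)), "positive")
})

test_that("iBAQ stoichiometry gives bound fractions and fold-changes", {
  ib <- rbind(CSB = c(uv = 10, mock = 10),
              PAF1 = c(uv = 6, mock = 0.6),
              RPB1 = c(uv = 0.2, mock = 0.02))
  st <- ibaq_stoichiometry(ib, "CSB", c("PAF1", "RPB1"), c("uv", "mock"))
  expect_equal(st$fraction_uv[st$prey == "PAF1"], 0.6)
  expect_equal(st$fold_change[st$prey == "PAF1"], 10)
  same <- ibaq_stoichiometry(ib, "CSB", "PAF1", c("uv", "uv"))
  expect_equal(same$fold_change, 1)
  bad <- rbind(CSB = c(uv = 0, mock = 1), P = c(uv = 1, mock = 1))
  expect_error(ibaq_stoichiometry(bad, "CSB", "P", c("uv", "mock")),
               "positive")
})

test_that("proteinGroups round-trip drives the full label-free workflow", {
  sim <- simulate_intensity_matrix(200, 20, 4, seed = 3)
  # write a MaxQuant-style table: linear intensities, flags, H/L ratios
  lin <- 2^sim$matrix$intensities
  lin[is.na(lin)] <- 0
  df <- data.frame(`Protein IDs` = rownames(lin), check.names = FALSE)
  for (s in colnames(lin)) df[[paste("LFQ intensity", s)]] <- lin[, s]
  df[["iBAQ uv_1"]] <- seq_len(nrow(lin))
  df[["Ratio H/L"]] <- ifelse(sim$truth, 4, 1)
  df$Reverse <- ifelse(seq_len(nrow(lin)) <= 2, "+", "")
  df[["Potential contaminant"]] <- ""
  df[["Only identified by site"]] <- ""
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pg <- read_proteingroups(path)
  expect_equal(dim(pg$intensities), c(200, 8))
  expect_equal(sum(pg$flags$reverse), 2)
  expect_equal(unname(attr(pg, "ratio_hl")[3]), 4)
  cleaned <- clean_and_log2(pg)
  expect_equal(nrow(cleaned$intensities), 198)
  obs <- sim$matrix$intensities[-(1:2), ]
  expect_equal(unname(cleaned$intensities[!is.na(obs)]),
               unname(obs[!is.na(obs)]))
})
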