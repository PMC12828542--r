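test_that("low-count filtering keeps the boundary and is idempotent", {
  m <- matrix(c(0, 0, 3, 6, 5, 5, 20, 30), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  kept <- filter_low_count(m)
  # row sums 0, 9, 10, 50: the sum-10 gene is kept ("< 10 removed")
  expect_equal(rownames(kept), c("g3", "g4"))
  expect_identical(filter_low_count(kept), kept)
  expect_identical(filter_low_count(m, min_total = 0), m)
  zero <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(filter_low_count(zero), "threshold")
})

test_that("size factors behave like median-of-ratios", {
  m <- matrix(c(10, 10, 20, 100, 100, 200, 50, 50, 100,
                7, 7, 14, 300, 300, 600), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), c("s1", "s2", "s3")))
  sf <- size_factors(m)
  # identical columns 1-2: equal factors; column 3 doubled
  expect_equal(sf[["s1"]], sf[["s2"]])
  expect_equal(sf[["s3"]] / sf[["s1"]], 2)
  tr <- normalize_transform(m, sf)
  expect_equal(tr[, "s1"], tr[, "s3"])
  # independent implementation agreement on rough data
  skip_if_not_installed("DESeq2")
  set.seed(3)
  big <- matrix(rnbinom(200 * 6, mu = 100, size = 5), 200, 6,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  expect_equal(size_factors(big),
               DESeq2::estimateSizeFactorsForMatrix(big),
               tolerance = 1e-8)
})

test_that("the stabilised transform is monotone within a sample", {
  m <- matrix(c(1, 5, 9, 30, 2, 4, 100, 7), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  tr <- normalize_transform(m, sf = c(1, 1))
  expect_true(all(diff(tr[order(m[, 1]), 1]) >= 0))
  expect_error(size_factors(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:1000) {
    p <- round(runif(6), 3)
    expect_equal(bh_adjust(p), bf_bh(p))
  }
})

test_that("PCA outlier flagging catches gross displacement and spares nulls", {
  sim <- small_run()$sim
  expr <- normalize_transform(filter_low_count(sim$counts))
  out0 <- pca_outliers(expr, sim$samples)
  expect_s3_class(out0, "data.frame")
  expect_identical(pca_outliers(expr, sim$samples, k_sd = Inf)$outlier,
                   rep(FALSE, nrow(sim$samples)))
  # displace one sample by 10x the data scale
  expr2 <- expr
  expr2[, 3] <- expr2[, 3] + 10 * stats::sd(expr)
  out <- pca_outliers(expr2, sim$samples)
  expect_true(out$outlier[3])
  # homogeneous cells rarely flag anything
  flags <- vapply(1:40, function(s) {
    set.seed(s)
    e <- matrix(rnorm(200 * 12), 200, 12,
                dimnames = list(NULL, paste0("s", 1:12)))
    sm <- data.frame(sample_id = paste0("s", 1:12),
                     metabolic_state = rep(c("lean", "DIO"), each = 6),
                     temperature = rep(c(30, 8, 30, 8), each = 3))
    sum(pca_outliers(e, sm)$outlier)
  }, 0)
  expect_gte(mean(flags == 0), 0.95)
})

test_that("interaction coefficient equals the difference of cold responses", {
  run <- small_run()
  d <- run$res$degs
  wide <- split(d, d$contrast)
  delta <- wide$COLD_DIO$log2FC - wide$COLD_lean$log2FC
  expect_equal(wide$DeltaCOLD$log2FC, delta, tolerance = 1e-8)
})

test_that("a planted equal cold effect leaves the interaction centred at zero", {
  ann <- generate_annotation(n_genes = 500, n_chroms = 3, seed = 31)
  d <- design_spec(n_per_cell = 50, seed = 31)
  tr <- plant_truth(ann, frac_dmeg = 0, frac_deg_only = 0, n_low_count = 0,
                    seed = 31)
  # equal cold effect in both states => interaction 0
  tr$genes$lfc_COLD_lean <- 1.2
  tr$genes$lfc_COLD_DIO <- 1.2
  cnt <- generate_counts(ann, d, tr)
  res <- fit_contrasts(cnt$counts, cnt$samples)
  inter <- res$log2FC[res$contrast == "DeltaCOLD"]
  expect_lt(abs(mean(inter, na.rm = TRUE)), 0.1)
})

test_that("a strong planted cold effect is recovered at small n", {
  ann <- generate_annotation(n_genes = 200, n_chroms = 2, seed = 13)
  d <- design_spec(n_per_cell = 7, seed = 13)
  tr <- plant_truth(ann, frac_dmeg = 0, frac_deg_only = 0, n_low_count = 0,
                    seed = 13)
  set.seed(13)
  planted <- sample(seq_len(200), 50)
  tr$genes$lfc_COLD_lean[planted] <- 2
  cnt <- generate_counts(ann, d, tr)
  res <- fit_contrasts(cnt$counts, cnt$samples)
  cl <- res[res$contrast == "COLD_lean", ]
  expect_gte(mean(cl$fdr[planted] < 0.05, na.rm = TRUE), 0.9)
})

test_that("fold changes agree with an independent NB engine", {
  skip_if_not_installed("DESeq2")
  sim <- small_run()$sim
  counts <- filter_low_count(sim$counts)
  res <- fit_contrasts(counts, sim$samples)
  suppressMessages({
    cd <- data.frame(state = factor(sim$samples$metabolic_state,
                                    levels = c("lean", "DIO")),
                     temp = factor(sim$samples$temperature,
                                   levels = c(30, 8)))
    dds <- DESeq2::DESeqDataSetFromMatrix(counts, cd, ~ state * temp)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds, name = "temp_8_vs_30")
  })
  ours <- res[res$contrast == "COLD_lean", ]
  ok <- !is.na(ours$log2FC) & !is.na(dres$log2FoldChange)
  expect_gt(stats::cor(ours$log2FC[ok], dres$log2FoldChange[ok]), 0.98)
})
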