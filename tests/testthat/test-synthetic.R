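test_that("generators are bit-identical under the same seed", {
  a1 <- generate_annotation(n_genes = 30, n_chroms = 2, seed = 9)
  a2 <- generate_annotation(n_genes = 30, n_chroms = 2, seed = 9)
  expect_identical(a1, a2)
  d <- design_spec(n_per_cell = 3, seed = 9)
  tr <- plant_truth(a1, frac_dmeg = 0.2, frac_deg_only = 0.1,
                    n_low_count = 2, seed = 9)
  c1 <- generate_counts(a1, d, tr)
  c2 <- generate_counts(a1, d, tr)
  expect_identical(c1$counts, c2$counts)
  m1 <- generate_methylation(a1, d, tr, n_background_cpgs = 50, expr = c1)
  m2 <- generate_methylation(a1, d, tr, n_background_cpgs = 50, expr = c1)
  expect_identical(m1$meth, m2$meth)
  expect_identical(m1$cov, m2$cov)
})

test_that("generated genes do not overlap within a chromosome", {
  ann <- generate_annotation(n_genes = 50, n_chroms = 2, seed = 4)
  expect_equal(nrow(ann), 50L)
  expect_setequal(unique(ann$strand), c("+", "-"))
  for (cc in unique(ann$chrom)) {
    d <- ann[ann$chrom == cc, ]
    if (nrow(d) < 2) next
    d <- d[order(d$start), ]
    # brute-force pairwise interval overlap scan
    for (i in seq_len(nrow(d) - 1)) {
      for (j in (i + 1):nrow(d)) {
        expect_true(d$end[i] < d$start[j] || d$end[j] < d$start[i])
      }
    }
  }
})

test_that("a gene near the origin forces promoter clipping", {
  ann <- generate_annotation(n_genes = 10, n_chroms = 1, seed = 2)
  first <- ann[ann$chrom == "chr1", ][1, ]
  expect_true(first$start < 1500 && first$strand == "+")
  w <- promoter_window(first$start, "+",
                       chrom_length = attr(ann, "chrom_lengths")[["chr1"]])
  expect_equal(w[1], 1L)
})

test_that("infeasible packing errors with the required length", {
  expect_error(
    generate_annotation(n_genes = 100, n_chroms = 1, seed = 1,
                        chrom_length = 10000, frac_chrx = 0),
    "need at least")
})

test_that("low-count genes stay under the filter threshold", {
  sim <- small_run()$sim
  low <- sim$truth$genes$gene_id[sim$truth$genes$is_low_count]
  expect_true(all(rowSums(sim$counts[low, , drop = FALSE]) < 10))
})

test_that("methylated counts never exceed coverage and betas are valid", {
  cpgs <- small_run()$sim$cpgs
  expect_true(all(cpgs$meth >= 0))
  expect_true(all(cpgs$meth <= cpgs$cov))
})

test_that("null genes show no systematic temperature fold change at large n", {
  ann <- generate_annotation(n_genes = 60, n_chroms = 2, seed = 21)
  d <- design_spec(n_per_cell = 50, seed = 21)
  tr <- plant_truth(ann, frac_dmeg = 0, frac_deg_only = 0, n_low_count = 0,
                    seed = 21)
  cnt <- generate_counts(ann, d, tr)
  cold <- cnt$samples$temperature == 8
  lfc <- log2(rowMeans(cnt$counts[, cold]) + 1) -
    log2(rowMeans(cnt$counts[, !cold]) + 1)
  expect_true(all(abs(lfc) < 0.2))
})

test_that("planted sites reach the target correlation at large n", {
  ann <- generate_annotation(n_genes = 40, n_chroms = 2, seed = 8)
  d <- design_spec(n_per_cell = 50, seed = 8)
  tr <- plant_truth(ann, frac_dmeg = 0.5, frac_deg_only = 0,
                    n_low_count = 0, seed = 8)
  cnt <- generate_counts(ann, d, tr)
  cpgs <- generate_methylation(ann, d, tr, n_background_cpgs = 20,
                               expr = cnt, seed = 99)
  expr <- normalize_transform(filter_low_count(cnt$counts))
  m <- beta_to_m(beta_values(cpgs))
  key <- paste(cpgs$sites$chrom, cpgs$sites$pos)
  dmp <- tr$dmps
  shared <- dmp[dmp$gene_id %in%
                  tr$genes$gene_id[tr$genes$profile == "shared"], ]
  rs <- vapply(seq_len(nrow(shared)), function(i) {
    si <- match(paste(shared$chrom[i], shared$pos[i]), key)
    stats::cor(expr[shared$gene_id[i], ], m[si, ])
  }, 0)
  expect_true(mean(sign(rs) == shared$corr_sign) > 0.95)
  expect_true(stats::median(abs(rs)) > 0.5)
})

test_that("background sites stay uncorrelated with expression at n_per_cell=7", {
  run <- small_run()
  sim <- run$sim
  expr <- run$res$expr
  m <- beta_to_m(beta_values(sim$cpgs))
  key <- paste(sim$cpgs$sites$chrom, sim$cpgs$sites$pos)
  bg_rows <- which(!key %in% paste(sim$truth$dmps$chrom,
                                   sim$truth$dmps$pos))
  set.seed(1)
  bg_rows <- sample(bg_rows, 200)
  genes <- sample(rownames(expr), 200, replace = TRUE)
  rs <- vapply(seq_along(bg_rows), function(i) {
    y <- m[bg_rows[i], ]
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) return(0)
    stats::cor(expr[genes[i], ok], y[ok])
  }, 0)
  expect_gt(mean(abs(rs) < 0.5), 0.9)
})

test_that("planting validates DMP positions against the annotation", {
  ann <- generate_annotation(n_genes = 10, n_chroms = 1, seed = 3)
  d <- design_spec(n_per_cell = 2, seed = 3)
  tr <- plant_truth(ann, frac_dmeg = 0.3, frac_deg_only = 0,
                    n_low_count = 0, seed = 3)
  tr$dmps$pos[1] <- attr(ann, "chrom_lengths")[["chr1"]] - 5L
  expect_error(generate_methylation(ann, d, tr, n_background_cpgs = 10),
               "outside its gene/promoter")
})
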