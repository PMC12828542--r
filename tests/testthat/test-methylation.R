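test_that("beta to M transform hits its anchor points", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8, epsilon = 0), 2)
  expect_equal(beta_to_m(1, epsilon = 0.01), log2(101))
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  b <- seq(0, 1, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
  # epsilon-symmetric antisymmetry
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))
})

test_that("masking flags low coverage, SNPs, sex chromosomes and outliers", {
  set.seed(2)
  k <- 8
  sm <- data.frame(sample_id = paste0("s", 1:k),
                   metabolic_state = rep(c("lean", "DIO"), each = 4),
                   temperature = rep(c(30, 8, 30, 8), each = 2))
  cov <- matrix(30L, 12, k)
  cov[2, 1] <- 3L            # low coverage in one sample at site 2
  meth <- pmin(matrix(10L, 12, k), cov)
  cpgs <- toy_cpg_set(meth, cov, chrom = c("chrX", rep("chr1", 11)),
                      sample_ids = sm$sample_id)
  out <- mask_sites(cpgs, sm, min_cov = 5, snp_positions =
                      data.frame(chrom = "chr1", pos = 300L))
  expect_equal(out$mask[1, ], setNames(rep("sex_chromosome", k),
                                       sm$sample_id))
  expect_true(out$dropped[1])
  expect_equal(unname(out$mask[2, 1]), "low_coverage")
  # one of two samples masked in its cell: the site is dropped outright
  expect_true(out$dropped[2])
  expect_true(all(out$mask[3, ] == "snp"))   # pos 300 is the SNP
  expect_true(out$dropped[3])
  # uniform coverage elsewhere stays unmasked at quantile 0.999
  expect_true(all(out$mask[4:12, ] == ""))
  expect_false(any(out$dropped[4:12]))
})

test_that("high-coverage outliers are masked at the per-sample quantile", {
  set.seed(7)
  k <- 8
  sm <- data.frame(sample_id = paste0("s", 1:k),
                   metabolic_state = rep(c("lean", "DIO"), each = 4),
                   temperature = rep(c(30, 8, 30, 8), each = 2))
  cov <- matrix(rpois(2000 * k, 30), 2000, k)
  cov[1, ] <- 10000L
  cpgs <- toy_cpg_set(pmin(matrix(5L, 2000, k), cov), cov,
                      pos = seq_len(2000) * 10L, sample_ids = sm$sample_id)
  out <- mask_sites(cpgs, sm, high_cov_quantile = 0.99)
  expect_true(all(out$mask[1, ] == "high_coverage_outlier"))
})

test_that("Welch test on M-values matches t.test site by site", {
  set.seed(9)
  k <- 14
  sm <- data.frame(sample_id = paste0("s", 1:k),
                   metabolic_state = "lean",
                   temperature = rep(c(8, 30), each = 7))
  cov <- matrix(rpois(60 * k, 30) + 1L, 60, k)
  meth <- matrix(rbinom(60 * k, cov, 0.4), 60, k)
  cpgs <- toy_cpg_set(meth, cov, sample_ids = sm$sample_id)
  dmps <- test_dmps(cpgs, sm, "COLD_lean")
  m <- beta_to_m(beta_values(cpgs))
  for (i in sample(nrow(m), 25)) {
    tt <- t.test(m[i, sm$temperature == 8], m[i, sm$temperature == 30])
    expect_equal(dmps$p[dmps$site_idx == i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("interaction p-values match lm() on M-values", {
  run <- small_run()
  sim <- run$sim
  masked <- mask_sites(sim$cpgs, sim$samples)
  dmps <- test_dmps(masked, sim$samples, "DeltaCOLD")
  m <- beta_to_m(beta_values(masked))
  st <- factor(sim$samples$metabolic_state, levels = c("lean", "DIO"))
  tp <- factor(sim$samples$temperature, levels = c(30, 8))
  set.seed(4)
  for (i in sample(dmps$site_idx, 20)) {
    y <- m[i, ]
    fit <- summary(stats::lm(y ~ st * tp))
    expect_equal(dmps$p[dmps$site_idx == i],
                 fit$coefficients["stDIO:tp8", 4], tolerance = 1e-9)
  }
})

test_that("group-mean fold change follows the epsilon-offset ratio", {
  k <- 6
  sm <- data.frame(sample_id = paste0("s", 1:k),
                   metabolic_state = "lean",
                   temperature = rep(c(8, 30), each = 3))
  cov <- matrix(10L, 2, k)
  meth <- rbind(c(8L, 8L, 8L, 2L, 2L, 2L),   # 0.8 cold vs 0.2 warm
                c(5L, 5L, 5L, 5L, 5L, 5L))   # identical means
  cpgs <- toy_cpg_set(meth, cov, sample_ids = sm$sample_id)
  dmps <- test_dmps(cpgs, sm, "COLD_lean")
  expect_equal(dmps$log2FC[1], log2(0.81 / 0.21), tolerance = 1e-12)
  expect_equal(dmps$log2FC[2], 0)
  expect_false(dmps$retained[2])
  # constant within both groups: degenerate, p = 1
  expect_true(dmps$degenerate[1])
  expect_equal(dmps$p[1], 1)
  expect_false(dmps$retained[1])
})

test_that("null CpGs rarely pass the joint DMP threshold", {
  set.seed(12)
  k <- 28
  sm <- data.frame(sample_id = paste0("s", 1:k),
                   metabolic_state = rep(c("lean", "DIO"), each = 14),
                   temperature = rep(c(30, 8, 30, 8), each = 7))
  cov <- matrix(rpois(1000 * k, 30) + 1L, 1000, k)
  p_site <- runif(1000, 0.1, 0.9)
  meth <- matrix(rbinom(1000 * k, cov, rep(p_site, k)), 1000, k)
  cpgs <- toy_cpg_set(meth, cov, pos = seq_len(1000) * 50L,
                      sample_ids = sm$sample_id)
  dmps <- test_dmps(cpgs, sm, "COLD_lean")
  expect_lt(mean(dmps$retained), 0.05)
  # the joint gate is stricter than the p-gate alone
  expect_lt(mean(dmps$retained), mean(dmps$p < 0.05))
})

test_that("DMR aggregation combines member p-values by Fisher's method", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                    end = 5000L, strand = "+", stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(2000L, 2500L, 99000L))
  asn <- assign_sites_to_regions(sites, ann, c(chr1 = 100000L))
  dmps <- data.frame(chrom = sites$chrom, pos = sites$pos,
                     site_idx = 1:3, contrast = "COLD_lean",
                     log2FC = c(1.5, -1.2, 2), p = c(0.01, 0.04, 0.001),
                     degenerate = FALSE, retained = TRUE,
                     stringsAsFactors = FALSE)
  dmrs <- call_dmrs(dmps, asn)
  expect_equal(nrow(dmrs), 1L)   # far site contributes to no region
  expect_equal(dmrs$n_dmps, 2L)
  expect_equal(dmrs$region_p,
               pchisq(-2 * (log(0.01) + log(0.04)), df = 4,
                      lower.tail = FALSE))
  # single-member region keeps its own p
  one <- call_dmrs(dmps[1, ], asn)
  expect_equal(one$region_p, 0.01)
})

test_that("every DMR member satisfies the DMP thresholds", {
  run <- small_run()
  for (ct in names(run$res$dmrs)) {
    dmrs <- run$res$dmrs[[ct]]
    dmps <- run$res$dmps[[ct]]
    members <- unlist(dmrs$member_idx)
    rows <- dmps[match(members, dmps$site_idx), ]
    expect_true(all(abs(rows$log2FC) > 1))
    expect_true(all(rows$p < 0.05))
  }
})
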