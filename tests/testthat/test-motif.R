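jaspar_fixture <- function() {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TESTA",
    "A  [ 10  0  0 10 ]",
    "C  [  0 10  0  0 ]",
    "G  [  0  0 10  0 ]",
    "T  [  0  0  0  0 ]",
    ">MA0002.1 TESTB",
    "A 1 1 8",
    "C 1 8 1",
    "G 8 1 1",
    "T 0 0 0"), f)
  f
}

test_that("JASPAR parsing yields normalised probability matrices", {
  pwms <- read_jaspar(jaspar_fixture())
  expect_named(pwms, c("MA0001.1", "MA0002.1"))
  expect_equal(dim(pwms$MA0001.1), c(4L, 4L))
  expect_equal(unname(colSums(pwms$MA0001.1)), rep(1, 4))
  expect_equal(rownames(pwms$MA0002.1), c("A", "C", "G", "T"))
  # consensus base dominates each column
  expect_equal(unname(apply(pwms$MA0001.1, 2, which.max)), c(1, 2, 3, 1))
})

test_that("PWM scanning counts consensus and reverse-complement hits", {
  pwm <- pwm_from_counts(rbind(A = c(100, 0, 0), C = c(0, 100, 0),
                               G = c(0, 0, 100), T = c(0, 0, 0)),
                         pseudocount = 0.01)
  # one embedded consensus ACG
  expect_equal(scan_pwm("TTTTACGATTTT", pwm, 0.9), 1L)
  # reverse complement CGT -> hit on the minus strand
  expect_equal(scan_pwm("TTTTCGTTTTT", pwm, 0.9), 1L)
  expect_equal(scan_pwm("TTTTTTTTTT", pwm, 0.9), 0L)
  expect_error(scan_pwm("ACGTQ", pwm), "letters")
})

test_that("scanning equals the brute-force scorer on random sequences", {
  set.seed(31)
  pwms <- read_jaspar(jaspar_fixture())
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 41, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    pwm <- pwms[[1 + i %% 2]]
    expect_identical(scan_pwm(s, pwm, 0.8),
                     as.integer(bf_scan_pwm(s, pwm, 0.8)))
  }
})

test_that("windows are centred, clipped and flagged", {
  genome <- c(chr1 = paste(rep("ACGT", 100), collapse = ""))
  w <- extract_windows(data.frame(chrom = "chr1", pos = 100L), genome)
  expect_equal(nchar(w$sequence), 41L)
  expect_equal(w$start, 80L); expect_equal(w$end, 120L)
  expect_false(w$clipped)
  wc <- extract_windows(data.frame(chrom = "chr1", pos = 10L), genome)
  expect_equal(nchar(wc$sequence), 30L)  # [1, 30]
  expect_true(wc$clipped)
  expect_error(extract_windows(data.frame(chrom = "chr9", pos = 5L),
                               genome), "unknown chromosome")
})

test_that("background sampling is seeded and covers promoters uniformly", {
  ann <- generate_annotation(n_genes = 10, n_chroms = 1, seed = 6,
                             frac_chrx = 0)
  genome <- generate_genome(attr(ann, "chrom_lengths"), seed = 6)
  b1 <- sample_background(ann, genome, 41, 500, seed = 3)
  b2 <- sample_background(ann, genome, 41, 500, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(nchar(b1) == 41))
  expect_error(sample_background(ann, genome, 10000, 10, seed = 1),
               "promoter")
  # uniformity over promoters: chi-squared on the sampled promoter index
  big <- sample_background(ann, genome, 41, 5000, seed = 11)
  counts <- tabulate(attr(big, "promoter_idx"), nbins = 10)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("rate comparison flags planted over-representation and spares nulls", {
  set.seed(41)
  bg <- rpois(500, 1)
  null_fg <- rpois(50, 1)
  te <- test_enrichment(null_fg, bg)
  expect_true(te$p > 0.05)
  rich <- rpois(50, 5)
  te2 <- test_enrichment(rich, bg)
  expect_equal(te2$direction, "over")
  expect_lt(te2$p, 0.01)
  # degenerate background: exact Poisson fallback
  te3 <- test_enrichment(c(3L, 4L), rep(1L, 200))
  expect_equal(te3$method, "poisson_exact")
  expect_error(test_enrichment(integer(), bg), "foreground")
  expect_error(test_enrichment(1L, rpois(50, 1)), "background")
})

test_that("enrichment p-values are roughly uniform under the null", {
  set.seed(51)
  ps <- replicate(300, {
    lambda <- runif(1, 0.2, 3)
    test_enrichment(rpois(40, lambda), rpois(400, lambda))$p
  })
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.10)
})

test_that("motif_enrichment detects a planted consensus cluster", {
  set.seed(61)
  pwm <- pwm_from_counts(rbind(A = c(50, 0, 0, 0, 0, 50),
                               C = c(0, 50, 0, 0, 50, 0),
                               G = c(0, 0, 50, 50, 0, 0),
                               T = c(0, 0, 0, 0, 0, 0)), 0.01)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  bg <- replicate(300, rand_seq(41))
  fg <- vapply(1:50, function(i) {
    s <- rand_seq(41)
    # plant the consensus ACGGCA at a fixed offset in most windows
    if (i <= 40) substr(s, 10, 15) <- "ACGGCA"
    s
  }, "")
  out <- motif_enrichment(fg, bg, list(planted = pwm))
  expect_equal(out$direction, "over")
  expect_lt(out$fdr, 0.01)
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeom_contrast(3, 5, 4, 10), 66 / 252)
  expect_equal(hypergeom_contrast(0, 5, 4, 10), 1)
  expect_equal(hypergeom_contrast(5, 5, 5, 5), 1)
  expect_error(hypergeom_contrast(6, 5, 4, 10), "inconsistent")
  set.seed(71)
  for (i in 1:1000) {
    N <- sample(5:20, 1)
    m <- sample(0:N, 1)
    k <- sample(1:N, 1)
    q <- sample(0:min(k, m), 1)
    expect_equal(hypergeom_contrast(q, k, m, N),
                 bf_hyper(q, m, N - m, k), tolerance = 1e-12)
  }
})
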