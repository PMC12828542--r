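# Independent brute-force oracles used to validate the package's
# implementations. Each is written from the definition, not from the
# code path it checks.

# Benjamini-Hochberg step-up, from the definition.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Pearson r and two-sided t-test p, from the definition.
bf_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# Site-to-region assignment by scanning every (site, region) pair.
bf_assign <- function(sites, annotation, chrom_lengths,
                      upstream = 1500, downstream = 500) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(annotation))) {
      if (sites$chrom[i] != annotation$chrom[j]) next
      p <- sites$pos[i]
      if (p >= annotation$start[j] && p <= annotation$end[j])
        rows[[length(rows) + 1L]] <- data.frame(
          site_idx = i, gene_id = annotation$gene_id[j], context = "body")
      tss <- if (annotation$strand[j] == "+") annotation$start[j] else
        annotation$end[j]
      cl <- unname(chrom_lengths[annotation$chrom[j]])
      w <- if (annotation$strand[j] == "+")
        c(tss - upstream, tss + downstream) else
          c(tss - downstream, tss + upstream)
      w[1] <- max(1, w[1]); if (!is.na(cl)) w[2] <- min(cl, w[2])
      if (p >= w[1] && p <= w[2])
        rows[[length(rows) + 1L]] <- data.frame(
          site_idx = i, gene_id = annotation$gene_id[j],
          context = "promoter")
    }
  }
  if (!length(rows)) return(data.frame(site_idx = integer(),
                                       gene_id = character(),
                                       context = character()))
  out <- do.call(rbind, rows)
  out[order(out$site_idx, out$gene_id, out$context), ]
}

# PWM match counting by scoring every offset on both strands with
# explicit loops.
bf_scan_pwm <- function(sequence, pwm, min_score_frac = 0.80) {
  lo <- log2(pwm / 0.25)
  thr <- min_score_frac * sum(apply(lo, 2, max))
  score_one <- function(chars) {
    L <- ncol(pwm); n <- length(chars); hits <- 0L
    if (n < L) return(0L)
    for (off in 1:(n - L + 1)) {
      s <- 0
      for (j in 1:L) {
        b <- chars[off + j - 1]
        s <- s + if (b == "N") 0 else lo[b, j]
      }
      if (s >= thr) hits <- hits + 1L
    }
    hits
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_one(chars) + score_one(rev(unname(comp[chars])))
}

# Upper-tail hypergeometric by exhaustive enumeration of the pmf.
bf_hyper <- function(q, m, n_white_comp, k) {
  sum(vapply(q:min(k, m), function(x)
    choose(m, x) * choose(n_white_comp, k - x), 0)) /
    choose(m + n_white_comp, k)
}

# Shared small synthetic dataset + pipeline run, built once per test run.
.fixture_env <- new.env(parent = emptyenv())
small_run <- function() {
  if (is.null(.fixture_env$run)) {
    sim <- simulate_dataset(seed = 42, n_genes = 400,
                            n_background_cpgs = 400, n_low_count = 10)
    res <- run_pipeline(sim$counts, sim$cpgs, sim$annotation, sim$samples)
    .fixture_env$run <- list(sim = sim, res = res)
  }
  .fixture_env$run
}

toy_cpg_set <- function(meth, cov, chrom = "chr1",
                        pos = seq_len(nrow(meth)) * 100L,
                        sample_ids = colnames(meth)) {
  sites <- data.frame(chrom = chrom, pos = pos, strand = "+",
                      stringsAsFactors = FALSE)
  colnames(meth) <- sample_ids; colnames(cov) <- sample_ids
  methexpr:::new_cpg_set(sites, meth, cov)
}
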