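#' Mask unreliable CpG calls
#'
#' Applies the usual RRBS reliability masks per sample and site:
#' coverage below `min_cov` (low_coverage), coverage above the per-sample
#' `high_cov_quantile` quantile (high_coverage_outlier), known SNP
#' positions (snp, applied to all samples) and sex chromosomes
#' (sex_chromosome). A site is additionally dropped outright when fewer
#' than two unmasked samples remain in any design cell.
#'
#' @param cpgs a `cpg_set`.
#' @param samples sample sheet matching the columns of `cpgs`.
#' @param min_cov minimum read coverage for a usable call.
#' @param high_cov_quantile per-sample coverage quantile above which calls
#'   are treated as outliers (computed over covered sites).
#' @param snp_positions optional data frame (`chrom`, `pos`) of positions
#'   to drop entirely.
#' @param exclude_sex_chroms mask sites on `sex_chroms`.
#' @param sex_chroms sex-chromosome name set.
#' @return the `cpg_set` with `mask` and `dropped` filled in.
#' @export
mask_sites <- function(cpgs, samples, min_cov = 5, high_cov_quantile = 0.999,
                       snp_positions = NULL, exclude_sex_chroms = TRUE,
                       sex_chroms = SEX_CHROMS) {
  mask <- matrix("", nrow(cpgs$cov), ncol(cpgs$cov),
                 dimnames = dimnames(cpgs$cov))
  for (j in seq_len(ncol(cpgs$cov))) {
    covj <- cpgs$cov[, j]
    hi <- stats::quantile(covj[covj > 0], high_cov_quantile, names = FALSE,
                          type = 7)
    mask[covj > hi, j] <- "high_coverage_outlier"
    mask[covj < min_cov, j] <- "low_coverage"
  }
  if (exclude_sex_chroms) {
    sx <- cpgs$sites$chrom %in% sex_chroms
    mask[sx, ] <- "sex_chromosome"
  }
  if (!is.null(snp_positions) && nrow(snp_positions)) {
    hit <- paste(cpgs$sites$chrom, cpgs$sites$pos) %in%
      paste(snp_positions$chrom, snp_positions$pos)
    mask[hit, ] <- "snp"
  }
  cpgs$mask <- mask
  cell <- design_cells(samples)
  ok <- mask == ""
  min_ok <- rep(Inf, nrow(ok))
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    min_ok <- pmin(min_ok, rowSums(ok[, idx, drop = FALSE]))
  }
  cpgs$dropped <- min_ok < 2
  cpgs
}

#' Beta to M-value transform
#'
#' `M = log2((beta + epsilon) / (1 - beta + epsilon))`: the logit-scale
#' methylation value, offset by `epsilon` so boundary betas stay finite.
#' Strictly increasing in beta with `M(0.5) = 0`.
#'
#' @param beta methylation fractions in `[0, 1]` (NA passed through).
#' @param epsilon boundary offset.
#' @export
beta_to_m <- function(beta, epsilon = 0.01) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop2("beta values must lie in [0, 1]")
  log2((beta + epsilon) / (1 - beta + epsilon))
}

# Vectorised Welch two-sample t over rows of M-value matrices with NA
# masking. Returns list(stat, df, p, n1, n2).
row_welch <- function(m1, m2) {
  n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
  mu1 <- rowMeans(m1, na.rm = TRUE); mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- apply(m1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(m2, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  stat <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # both groups constant: difference untestable, report p = 1
  degenerate <- is.finite(mu1) & is.finite(mu2) & (v1 + v2) == 0
  p[degenerate] <- 1
  list(stat = stat, df = df, p = p, n1 = n1, n2 = n2,
       degenerate = degenerate)
}

#' Per-CpG differential methylation tests
#'
#' For the simple cold contrasts (COLD_lean, COLD_DIO) the fold change is
#' the log2 ratio of epsilon-offset group-mean betas (cold over warm,
#' within the given metabolic state) and the p-value a two-sided Welch t
#' on M-values. For the interaction contrast (DeltaCOLD) the fold change
#' is the log2 ratio of the two states' cold/warm beta ratios and the
#' p-value comes from the interaction term of an ordinary least-squares
#' model on M-values with state, temperature and their interaction.
#' A call is retained as a DMP when `|log2FC| > lfc_min` and
#' `p < alpha`.
#'
#' @param cpgs a masked `cpg_set`.
#' @param samples sample sheet.
#' @param contrast one of "COLD_lean", "COLD_DIO", "DeltaCOLD".
#' @param epsilon ratio offset.
#' @param lfc_min,alpha DMP retention thresholds.
#' @return data frame with `chrom`, `pos`, `site_idx`, `contrast`,
#'   `log2FC`, `p`, `retained`, `degenerate`.
#' @export
test_dmps <- function(cpgs, samples, contrast = c("COLD_lean", "COLD_DIO",
                                                  "DeltaCOLD"),
                      epsilon = 0.01, lfc_min = 1, alpha = 0.05) {
  contrast <- match.arg(contrast)
  beta <- beta_values(cpgs)
  m <- beta_to_m(beta, epsilon)
  cold <- samples$temperature == 8
  dio <- samples$metabolic_state == "DIO"
  grp_mean <- function(cols) rowMeans(beta[, cols, drop = FALSE], na.rm = TRUE)
  if (contrast != "DeltaCOLD") {
    in_state <- if (contrast == "COLD_lean") !dio else dio
    g_cold <- in_state & cold; g_warm <- in_state & !cold
    lfc <- log2((grp_mean(g_cold) + epsilon) / (grp_mean(g_warm) + epsilon))
    wt <- row_welch(m[, g_cold, drop = FALSE], m[, g_warm, drop = FALSE])
    p <- wt$p; degenerate <- wt$degenerate
  } else {
    r_dio <- (grp_mean(dio & cold) + epsilon) / (grp_mean(dio & !cold) + epsilon)
    r_lean <- (grp_mean(!dio & cold) + epsilon) /
      (grp_mean(!dio & !cold) + epsilon)
    lfc <- log2(r_dio / r_lean)
    X <- design_matrix(samples)
    p <- rep(NA_real_, nrow(m)); degenerate <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(m))) {
      yi <- m[i, ]; use <- !is.na(yi)
      if (sum(use) < 5L) next
      fit <- stats::lm.fit(X[use, , drop = FALSE], yi[use])
      rdf <- fit$df.residual
      s2 <- sum(fit$residuals^2) / rdf
      if (s2 == 0) { p[i] <- 1; degenerate[i] <- TRUE; next }
      xtxi <- tryCatch(solve(crossprod(X[use, , drop = FALSE])),
                       error = function(e) NULL)
      if (is.null(xtxi)) next
      tstat <- fit$coefficients[4] / sqrt(s2 * xtxi[4, 4])
      p[i] <- 2 * stats::pt(-abs(tstat), rdf)
    }
  }
  out <- data.frame(chrom = cpgs$sites$chrom, pos = cpgs$sites$pos,
                    site_idx = seq_len(nrow(cpgs$sites)),
                    contrast = contrast, log2FC = lfc, p = p,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  out$retained <- !cpgs$dropped & is.finite(out$log2FC) & !is.na(out$p) &
    abs(out$log2FC) > lfc_min & out$p < alpha
  out[!cpgs$dropped, , drop = FALSE]
}

#' Fisher's combination of p-values
#'
#' `-2 * sum(log p)` referred to a chi-squared distribution with `2k`
#' degrees of freedom.
#' @param p vector of p-values.
#' @export
fisher_combine <- function(p) {
  p <- pmax(p, .Machine$double.xmin)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Aggregate retained DMPs into gene-level regions
#'
#' For each (gene, context, contrast), the retained DMPs falling in the
#' gene body or promoter window form a differentially methylated region
#' (DMR); the region significance is Fisher's combination of member DMP
#' p-values. Only non-empty regions are returned.
#'
#' @param dmps output of [test_dmps()] (one contrast).
#' @param assignments site-region table from [assign_sites_to_regions()]
#'   computed on the same `cpg_set` site order (`site_idx` keys match).
#' @return data frame with `gene_id`, `context`, `contrast`, `n_dmps`,
#'   `region_p` and a `member_idx` list-column of `site_idx` values.
#' @export
call_dmrs <- function(dmps, assignments) {
  kept <- dmps[dmps$retained, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(data.frame(gene_id = character(), context = character(),
                      contrast = character(), n_dmps = integer(),
                      region_p = numeric(), stringsAsFactors = FALSE))
  }
  hits <- assignments[assignments$site_idx %in% kept$site_idx, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(gene_id = character(), context = character(),
                      contrast = character(), n_dmps = integer(),
                      region_p = numeric(), stringsAsFactors = FALSE))
  }
  hits$p <- kept$p[match(hits$site_idx, kept$site_idx)]
  key <- paste(hits$gene_id, hits$context, sep = "\r")
  groups <- split(hits, key)
  out <- do.call(rbind, lapply(groups, function(h) {
    data.frame(gene_id = h$gene_id[1], context = h$context[1],
               contrast = dmps$contrast[1], n_dmps = nrow(h),
               region_p = fisher_combine(h$p), stringsAsFactors = FALSE)
  }))
  out$member_idx <- lapply(groups, function(h) sort(unique(h$site_idx)))
  rownames(out) <- NULL
  out
}
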