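#' Remove genes with low total counts
#'
#' Genes whose total count across all samples is below `min_total` are
#' dropped; gene order is otherwise preserved. The default mirrors the
#' usual "total count sum < 10" pre-filter.
#'
#' @param counts integer matrix, genes x samples.
#' @param min_total minimum total count a gene must reach to be kept.
#' @return the filtered matrix.
#' @export
filter_low_count <- function(counts, min_total = 10) {
  keep <- rowSums(counts) >= min_total
  if (!any(keep))
    stop2(sprintf(
      "no genes left after filtering at min_total=%g; lower the threshold",
      min_total))
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Classic ratio-to-geometric-mean-reference estimator: for each sample,
#' the median over genes of count / geometric-mean count, computed over
#' genes expressed in every sample.
#'
#' @param counts count matrix.
#' @return numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) stop2("sample with all-zero counts")
  logs <- log(counts)
  lgm <- rowMeans(logs)
  usable <- is.finite(lgm)
  if (!any(usable))
    stop2("no gene is expressed in every sample; cannot estimate size factors")
  sf <- apply(counts[usable, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - lgm[usable])))
  sf
}

#' Variance-stabilising transform of counts
#'
#' Size-factor-normalised counts on a log2 scale:
#' `log2(count / size_factor + 1)`. Used as the per-sample expression
#' representation for PCA and for methylation-expression correlation.
#'
#' @param counts filtered count matrix.
#' @param sf optional precomputed size factors.
#' @return numeric matrix of the same shape.
#' @export
normalize_transform <- function(counts, sf = size_factors(counts)) {
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Flag PCA outlier samples
#'
#' Projects samples onto the first two principal components of the
#' stabilised expression matrix and flags samples far from their own
#' design-cell centroid: a sample is reported when the z-score of its
#' centroid distance (against the pooled mean and SD of all within-cell
#' distances) exceeds `k_sd`. Flagging is advisory; nothing is removed.
#'
#' @param expr stabilised expression matrix (genes x samples).
#' @param samples sample sheet (`sample_id`, `metabolic_state`,
#'   `temperature`) matching the columns of `expr`.
#' @param k_sd flagging threshold in SD units.
#' @return data frame of all samples with their distances, z-scores and an
#'   `outlier` flag.
#' @export
pca_outliers <- function(expr, samples, k_sd = 3) {
  cell <- design_cells(samples)
  if (length(unique(cell)) < 3L) stop2("need at least 3 populated design cells")
  if (min(table(cell)) < 3L) stop2("need >=3 samples per design cell")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  xy <- pc$x[, 1:2, drop = FALSE]
  dist <- numeric(nrow(xy))
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    ctr <- colMeans(xy[idx, , drop = FALSE])
    dist[idx] <- sqrt(rowSums(sweep(xy[idx, , drop = FALSE], 2, ctr)^2))
  }
  z <- (dist - mean(dist)) / stats::sd(dist)
  data.frame(sample_id = samples$sample_id, cell = cell,
             pc1 = xy[, 1], pc2 = xy[, 2], dist = dist, z = z,
             outlier = is.finite(z) & z > k_sd,
             stringsAsFactors = FALSE)
}

design_cells <- function(samples) {
  paste(samples$metabolic_state, samples$temperature, sep = "_")
}

# Design matrix for ~ state + temperature + state:temperature with
# treatment coding, reference lean / 30 C. Columns: intercept, stateDIO,
# temp8, stateDIO:temp8.
design_matrix <- function(samples) {
  s <- as.integer(samples$metabolic_state == "DIO")
  t8 <- as.integer(samples$temperature == 8)
  cbind(intercept = 1, stateDIO = s, temp8 = t8, interaction = s * t8)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper over the step-up procedure; order-preserving
#' with the input.
#' @param p vector of p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit the three design contrasts per gene
#'
#' Per-gene negative-binomial log-linear model with design
#' `~ state + temperature + state:temperature` (treatment coding,
#' reference lean / 30 C) and log size-factor offsets. The cold response
#' of lean animals (COLD_lean) is the temperature coefficient; the cold
#' response of obese animals (COLD_DIO) is temperature + interaction; the
#' interaction coefficient itself is the state-dependent difference
#' (DeltaCOLD), so DeltaCOLD = COLD_DIO - COLD_lean identically.
#'
#' Dispersion is estimated per gene by method of moments on normalised
#' counts (pooled within-cell variance) and shrunk 50/50 toward a fitted
#' `a0 + a1/mean` mean-dispersion trend. Wald tests per coefficient;
#' BH adjustment across genes within each contrast. Genes whose IRLS fit
#' fails to converge are reported with NA statistics and excluded from the
#' FDR ranking.
#'
#' @param counts filtered count matrix.
#' @param samples sample sheet matching the columns.
#' @param sf optional size factors.
#' @return data frame with one row per gene and contrast: `gene_id`,
#'   `contrast` (COLD_lean, COLD_DIO, DeltaCOLD), `base_mean`, `log2FC`,
#'   `se`, `p`, `fdr`.
#' @export
fit_contrasts <- function(counts, samples, sf = size_factors(counts)) {
  cell <- design_cells(samples)
  if (length(unique(cell)) != 4L) stop2("need a full 2x2 design")
  if (min(table(cell)) < 2L) stop2("need >=2 samples per design cell")
  X <- design_matrix(samples)
  disp <- estimate_dispersions(counts, sf, cell)
  n_genes <- nrow(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  est <- matrix(NA_real_, n_genes, 3,
                dimnames = list(rownames(counts),
                                c("COLD_lean", "COLD_DIO", "DeltaCOLD")))
  se <- est; pval <- est
  # contrast vectors on the coefficient scale
  L <- cbind(COLD_lean = c(0, 0, 1, 0),
             COLD_DIO = c(0, 0, 1, 1),
             DeltaCOLD = c(0, 0, 0, 1))
  off <- log(sf)
  for (g in seq_len(n_genes)) {
    fit <- nb_irls(counts[g, ], X, off, disp[g])
    if (is.null(fit)) next
    for (k in 1:3) {
      l <- L[, k]
      est[g, k] <- sum(l * fit$beta) / log(2)
      v <- drop(t(l) %*% fit$cov %*% l)
      se[g, k] <- sqrt(v) / log(2)
      z <- sum(l * fit$beta) / sqrt(v)
      pval[g, k] <- 2 * stats::pnorm(-abs(z))
    }
  }
  res <- do.call(rbind, lapply(colnames(est), function(ct) {
    data.frame(gene_id = rownames(counts), contrast = ct,
               base_mean = base_mean, log2FC = est[, ct], se = se[, ct],
               p = pval[, ct], fdr = bh_adjust(pval[, ct]),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

# Method-of-moments dispersion with 50/50 shrink toward an a0 + a1/mu trend.
estimate_dispersions <- function(counts, sf, cell) {
  norm <- sweep(counts, 2, sf, "/")
  cells <- unique(cell)
  # pooled within-cell variance of normalised counts
  ss <- 0; dfree <- 0
  cm <- matrix(0, nrow(counts), length(cells))
  for (i in seq_along(cells)) {
    idx <- which(cell == cells[i])
    m <- rowMeans(norm[, idx, drop = FALSE])
    cm[, i] <- m
    ss <- ss + rowSums((norm[, idx, drop = FALSE] - m)^2)
    dfree <- dfree + length(idx) - 1L
  }
  v <- ss / dfree
  mu <- rowMeans(norm)
  raw <- pmax((v - mu) / mu^2, 1e-8)
  # trend a0 + a1/mu, fitted on informative genes, coefficients kept >= 0
  ok <- is.finite(raw) & mu > 1 & raw > 1e-8
  if (sum(ok) >= 10) {
    xf <- 1 / mu[ok]; yf <- raw[ok]
    # one round of trimming against a first pass to resist outliers
    f1 <- stats::lm.fit(cbind(1, xf), yf)
    r <- yf - f1$fitted.values
    keep <- abs(r) <= 3 * stats::mad(r) + 1e-12
    f2 <- stats::lm.fit(cbind(1, xf[keep]), yf[keep])
    a0 <- max(f2$coefficients[1], 1e-4)
    a1 <- max(f2$coefficients[2], 0)
  } else {
    a0 <- max(stats::median(raw, na.rm = TRUE), 1e-4); a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  0.5 * raw + 0.5 * trend
}

# Fisher-scoring IRLS for a log-link NB GLM with fixed dispersion phi
# (var = mu + phi mu^2). Returns beta (natural log scale) and covariance,
# or NULL on non-convergence.
nb_irls <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-8) {
  # start from cell means via the saturated structure of X
  eta <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(stats::lm.fit(X, eta)$coefficients, error = function(e) NULL)
  if (is.null(beta) || any(is.na(beta))) beta <- c(log(mean(y) + 0.5), 0, 0, 0)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
    new_beta <- fit$coefficients
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) break
  }
  if (delta >= 1e-4) return(NULL)
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(beta = beta, cov = cov)
}
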