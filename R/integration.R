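#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation with the usual two-sided test
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  if (length(x) < 3L) stop2("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("undefined correlation: constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Four-way methylation/expression category
#'
#' Sign pair of (methylation change, expression change):
#' hypomethylated + upregulated = "hypo_up", and so on.
#'
#' @param dmp_log2FC methylation log2 fold change (nonzero).
#' @param expr_log2FC expression log2 fold change (nonzero).
#' @export
categorize <- function(dmp_log2FC, expr_log2FC) {
  if (any(dmp_log2FC == 0) || any(expr_log2FC == 0))
    stop2("zero fold change has no category")
  paste0(ifelse(dmp_log2FC < 0, "hypo", "hyper"),
         "_",
         ifelse(expr_log2FC > 0, "up", "down"))
}

#' Pick the assigned context by region significance
#'
#' Among candidate contexts the one whose region has the smaller combined
#' p-value wins; an exact tie goes to the promoter.
#'
#' @param contexts character vector ("body"/"promoter").
#' @param region_p matching region p-values.
#' @export
assign_context <- function(contexts, region_p) {
  stopifnot(length(contexts) == length(region_p), length(contexts) >= 1L)
  best <- min(region_p)
  cand <- contexts[region_p == best]
  if ("promoter" %in% cand) "promoter" else cand[1]
}

contrast_samples <- function(samples, contrast) {
  switch(contrast,
         COLD_lean = which(samples$metabolic_state == "lean"),
         COLD_DIO = which(samples$metabolic_state == "DIO"),
         DeltaCOLD = seq_len(nrow(samples)),
         stop2("unknown contrast ", contrast))
}

#' Call differentially methylated and expressed genes (DMEGs)
#'
#' The integrative core: a gene qualifies when it is a DEG at
#' `|log2FC| > expr_lfc_min` and `fdr < expr_fdr`, owns at least one
#' region (gene body or promoter) with retained DMPs, and at least one of
#' those DMPs' M-values correlates with the gene's stabilised expression
#' across the contrast's samples at `|r| > r_min` with correlation p
#' (BH-adjusted within the gene's candidate set when
#' `adjusted_correlation_p`) below `alpha`. For an emitted gene the
#' assigned context is the region with the smaller combined p (ties to
#' promoter) and the best DMP is the qualifying DMP in that context with
#' the smallest correlation p (ties: larger `|r|`, then smaller
#' position).
#'
#' @param degs output of [fit_contrasts()].
#' @param dmrs output of [call_dmrs()] for the same contrast.
#' @param dmps output of [test_dmps()] for the same contrast.
#' @param expr stabilised expression matrix ([normalize_transform()]),
#'   all samples in columns.
#' @param cpgs the masked `cpg_set` the DMPs were computed from.
#' @param samples sample sheet.
#' @param contrast contrast name.
#' @param expr_lfc_min,expr_fdr expression gates.
#' @param r_min,alpha correlation gates.
#' @param adjusted_correlation_p adjust correlation p-values (BH) within
#'   each gene's candidate-DMP set before gating.
#' @param epsilon M-value offset.
#' @return a `dmeg_set`: data frame with one row per DMEG (`gene_id`,
#'   `contrast`, `assigned_context`, `best_chrom`, `best_pos`,
#'   `expr_log2FC`, `expr_fdr`, `dmp_log2FC`, `dmp_p`, `r`, `r_p`,
#'   `category`, `n_correlated_dmps`).
#' @export
call_dmegs <- function(degs, dmrs, dmps, expr, cpgs, samples,
                       contrast = dmps$contrast[1],
                       expr_lfc_min = 0.5, expr_fdr = 0.05,
                       r_min = 0.5, alpha = 0.05,
                       adjusted_correlation_p = TRUE, epsilon = 0.01) {
  if (!identical(colnames(expr), samples$sample_id) ||
      !identical(colnames(cpgs$cov), samples$sample_id))
    stop2("sample sets of expression, methylation and sample sheet differ")
  use <- contrast_samples(samples, contrast)
  m_all <- beta_to_m(beta_values(cpgs), epsilon)
  degs_c <- degs[degs$contrast == contrast & !is.na(degs$fdr) &
                   abs(degs$log2FC) > expr_lfc_min & degs$fdr < expr_fdr, ,
                 drop = FALSE]
  dmrs_c <- dmrs[dmrs$contrast == contrast, , drop = FALSE]
  empty <- data.frame(gene_id = character(), contrast = character(),
                      assigned_context = character(),
                      best_chrom = character(), best_pos = integer(),
                      expr_log2FC = numeric(), expr_fdr = numeric(),
                      dmp_log2FC = numeric(), dmp_p = numeric(),
                      r = numeric(), r_p = numeric(), category = character(),
                      n_correlated_dmps = integer(), stringsAsFactors = FALSE)
  genes <- intersect(degs_c$gene_id, dmrs_c$gene_id)
  rows <- list()
  for (g in genes) {
    if (!g %in% rownames(expr)) next
    x <- expr[g, use]
    gr <- degs_c[match(g, degs_c$gene_id), ]
    regions <- dmrs_c[dmrs_c$gene_id == g, , drop = FALSE]
    cand_idx <- sort(unique(unlist(regions$member_idx)))
    # correlate each candidate DMP's M-values with expression
    cor_tab <- lapply(cand_idx, function(si) {
      y <- m_all[si, use]
      ok <- !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NULL)
      pt <- pearson_test(x[ok], y[ok])
      data.frame(site_idx = si, r = pt$r, p = pt$p)
    })
    cor_tab <- do.call(rbind, cor_tab)
    if (is.null(cor_tab) || nrow(cor_tab) == 0L) next
    cor_tab$p_gate <- if (adjusted_correlation_p) bh_adjust(cor_tab$p) else
      cor_tab$p
    ok <- abs(cor_tab$r) > r_min & cor_tab$p_gate < alpha
    if (!any(ok)) next
    qual <- cor_tab[ok, , drop = FALSE]
    # context assignment: regions containing >=1 qualifying DMP
    has_qual <- vapply(seq_len(nrow(regions)), function(i)
      any(regions$member_idx[[i]] %in% qual$site_idx), TRUE)
    cand_regions <- regions[has_qual, , drop = FALSE]
    ctx <- assign_context(cand_regions$context, cand_regions$region_p)
    ctx_members <- unlist(
      cand_regions$member_idx[cand_regions$context == ctx])
    in_ctx <- qual[qual$site_idx %in% ctx_members, , drop = FALSE]
    pos <- cpgs$sites$pos[in_ctx$site_idx]
    ord <- order(in_ctx$p, -abs(in_ctx$r), pos)
    best <- in_ctx[ord[1], ]
    dmp_row <- dmps[match(best$site_idx, dmps$site_idx), ]
    rows[[g]] <- data.frame(
      gene_id = g, contrast = contrast, assigned_context = ctx,
      best_chrom = dmp_row$chrom, best_pos = dmp_row$pos,
      expr_log2FC = gr$log2FC, expr_fdr = gr$fdr,
      dmp_log2FC = dmp_row$log2FC, dmp_p = dmp_row$p,
      r = best$r, r_p = best$p,
      category = categorize(dmp_row$log2FC, gr$log2FC),
      n_correlated_dmps = length(unique(qual$site_idx)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  structure(out, class = c("dmeg_set", "data.frame"),
            thresholds = list(expr_lfc_min = expr_lfc_min,
                              expr_fdr = expr_fdr, r_min = r_min,
                              alpha = alpha,
                              adjusted = adjusted_correlation_p),
            contrast = contrast)
}

#' @export
print.dmeg_set <- function(x, ...) {
  cat(sprintf("dmeg_set: %d DMEGs (%s)\n", nrow(x),
              attr(x, "contrast") %||% "?"))
  if (nrow(x)) {
    tab <- table(x$category)
    cat("  categories:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    ctx <- table(x$assigned_context)
    cat("  contexts:  ",
        paste(sprintf("%s=%d", names(ctx), ctx), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method summary dmeg_set
#' @export
summary.dmeg_set <- function(object, ...) {
  mult <- dmp_multiplicity(object)
  out <- list(n = nrow(object), contrast = attr(object, "contrast"),
              categories = table(object$category),
              contexts = mult$context_proportions,
              multiplicity = mult$histogram,
              frac_ge4 = mult$frac_ge4)
  class(out) <- "summary.dmeg_set"
  out
}

#' @export
print.summary.dmeg_set <- function(x, ...) {
  cat(sprintf("%d DMEGs in contrast %s\n", x$n, x$contrast %||% "?"))
  if (x$n) {
    print(x$categories)
    cat(sprintf("fraction with >=4 correlated DMPs: %.1f%%\n",
                100 * x$frac_ge4))
  }
  invisible(x)
}

#' @method plot dmeg_set
#' @export
plot.dmeg_set <- function(x, ...) {
  if (!nrow(x)) { plot.new(); return(invisible(x)) }
  cols <- c(hypo_up = "#1b9e77", hypo_down = "#7570b3",
            hyper_up = "#d95f02", hyper_down = "#e7298a")
  plot(x$dmp_log2FC, x$expr_log2FC, col = cols[x$category], pch = 19,
       xlab = "methylation log2 FC (best DMP)",
       ylab = "expression log2 FC",
       main = sprintf("DMEGs (%s)", attr(x, "contrast") %||% ""), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' DMP-per-DMEG multiplicity and context proportions
#'
#' @param dmegs a `dmeg_set`.
#' @return list with `histogram` (named counts of DMEGs by number of
#'   correlated DMPs), `frac_ge4` (fraction with four or more),
#'   `context_proportions` (body/promoter shares, summing to 1).
#' @export
dmp_multiplicity <- function(dmegs) {
  if (nrow(dmegs) == 0L)
    return(list(histogram = table(integer()), frac_ge4 = NA_real_,
                context_proportions = c(body = NA_real_,
                                        promoter = NA_real_)))
  hist <- table(dmegs$n_correlated_dmps)
  ctx <- table(factor(dmegs$assigned_context,
                      levels = c("body", "promoter")))
  list(histogram = hist,
       frac_ge4 = mean(dmegs$n_correlated_dmps >= 4),
       context_proportions = stats::setNames(as.numeric(ctx) / sum(ctx),
                                             names(ctx)))
}
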