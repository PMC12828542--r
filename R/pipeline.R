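#' Pipeline configuration
#'
#' Collects every numeric threshold of the analysis with the defaults
#' the pipeline is built around: DEG gates (|log2FC| > 0.5, FDR < 0.05),
#' DMP gates (|log2FC| > 1, p < 0.05), correlation gates (|r| > 0.5,
#' p < 0.05), promoter window 1500/500 bp, motif windows +/- 20 nt with
#' 5000 background draws at an 80 % score threshold, and the count
#' filter at a total of 10. Validation happens here, before any
#' computation.
#'
#' @param min_total low-count filter threshold.
#' @param expr_lfc_min,expr_fdr DEG gates.
#' @param meth_lfc_min,meth_p DMP gates.
#' @param r_min,r_alpha correlation gates.
#' @param promoter_up,promoter_down promoter extents (bp).
#' @param min_cov,high_cov_quantile CpG masking parameters.
#' @param k_sd PCA outlier threshold (SD units).
#' @param epsilon beta/M offset.
#' @param flank,n_background,min_score_frac motif-stage parameters.
#' @param seed RNG seed for the motif background sampler.
#' @param exclude_sex_chroms,adjusted_correlation_p,celltype_denominator
#'   behaviour switches.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_total = 10, expr_lfc_min = 0.5,
                            expr_fdr = 0.05, meth_lfc_min = 1,
                            meth_p = 0.05, r_min = 0.5, r_alpha = 0.05,
                            promoter_up = 1500, promoter_down = 500,
                            min_cov = 5, high_cov_quantile = 0.999,
                            k_sd = 3, epsilon = 0.01, flank = 20,
                            n_background = 5000, min_score_frac = 0.80,
                            seed = 1, exclude_sex_chroms = TRUE,
                            adjusted_correlation_p = TRUE,
                            celltype_denominator = "markers") {
  cfg <- list(min_total = check_number(min_total, "min_total", 0),
              expr_lfc_min = check_number(expr_lfc_min, "expr_lfc_min", 0),
              expr_fdr = check_number(expr_fdr, "expr_fdr", 0, 1),
              meth_lfc_min = check_number(meth_lfc_min, "meth_lfc_min", 0),
              meth_p = check_number(meth_p, "meth_p", 0, 1),
              r_min = check_number(r_min, "r_min", 0, 1),
              r_alpha = check_number(r_alpha, "r_alpha", 0, 1),
              promoter_up = check_number(promoter_up, "promoter_up", 0),
              promoter_down = check_number(promoter_down, "promoter_down", 0),
              min_cov = check_number(min_cov, "min_cov", 0),
              high_cov_quantile = check_number(high_cov_quantile,
                                               "high_cov_quantile", 0, 1),
              k_sd = check_number(k_sd, "k_sd", 0),
              epsilon = check_number(epsilon, "epsilon", 0),
              flank = check_number(flank, "flank", 1),
              n_background = check_number(n_background, "n_background", 100),
              min_score_frac = check_number(min_score_frac,
                                            "min_score_frac", 0, 1),
              seed = as.integer(seed),
              exclude_sex_chroms = isTRUE(exclude_sex_chroms),
              adjusted_correlation_p = isTRUE(adjusted_correlation_p),
              celltype_denominator = match.arg(celltype_denominator,
                                               c("markers", "dmegs")))
  structure(cfg, class = "pipeline_config")
}

CONTRASTS <- c("COLD_lean", "COLD_DIO", "DeltaCOLD")

#' Run the full integration pipeline
#'
#' Executes filtering, normalisation, PCA outlier reporting, the three
#' expression contrasts, CpG masking, DMP/DMR calling, DMEG integration
#' and the cross-condition comparison; optionally motif enrichment when
#' a genome and PWM set are supplied. When `outdir` is given all result
#' tables are written as TSV plus a JSON summary and a run log.
#'
#' @param counts gene x sample count matrix.
#' @param cpgs a `cpg_set` over the same samples.
#' @param annotation gene annotation (attribute `chrom_lengths` used for
#'   promoter clipping when present).
#' @param samples sample sheet.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param genome,pwms optional genome sequences and PWM list enabling
#'   the motif stage.
#' @param regulators optional regulator gene symbols for
#'   cross-referencing.
#' @param markers optional cell-type marker table (`cell_type`,
#'   `gene_id`).
#' @param snp_positions optional SNP mask positions.
#' @return object of class `methexpr_pipeline`: list with all stage
#'   results and `stage_counts`.
#' @export
run_pipeline <- function(counts, cpgs, annotation, samples,
                         config = pipeline_config(), outdir = NULL,
                         genome = NULL, pwms = NULL, regulators = NULL,
                         markers = NULL, snp_positions = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  chrom_lengths <- attr(annotation, "chrom_lengths")
  ann <- annotation
  if (config$exclude_sex_chroms)
    ann <- ann[!ann$chrom %in% SEX_CHROMS, , drop = FALSE]
  counts <- counts[rownames(counts) %in% ann$gene_id, , drop = FALSE]

  stage_counts <- list()
  filtered <- filter_low_count(counts, config$min_total)
  stage_counts$genes_in <- nrow(counts)
  stage_counts$genes_filtered <- nrow(filtered)
  sf <- size_factors(filtered)
  expr <- normalize_transform(filtered, sf)
  outliers <- pca_outliers(expr, samples, config$k_sd)
  stage_counts$pca_outliers <- sum(outliers$outlier)
  degs <- fit_contrasts(filtered, samples, sf)
  stage_counts$degs_fdr <- stats::setNames(
    vapply(CONTRASTS, function(ct)
      sum(degs$contrast == ct & !is.na(degs$fdr) &
            degs$fdr < config$expr_fdr), 0L), CONTRASTS)

  masked <- mask_sites(cpgs, samples, min_cov = config$min_cov,
                       high_cov_quantile = config$high_cov_quantile,
                       snp_positions = snp_positions,
                       exclude_sex_chroms = config$exclude_sex_chroms)
  stage_counts$cpgs_in <- nrow(masked$sites)
  stage_counts$cpgs_usable <- sum(!masked$dropped)
  assignments <- assign_sites_to_regions(masked$sites, ann, chrom_lengths,
                                         config$promoter_up,
                                         config$promoter_down)
  dmps <- list(); dmrs <- list(); dmegs <- list()
  for (ct in CONTRASTS) {
    dmps[[ct]] <- test_dmps(masked, samples, ct, config$epsilon,
                            config$meth_lfc_min, config$meth_p)
    dmrs[[ct]] <- call_dmrs(dmps[[ct]], assignments)
    dmegs[[ct]] <- call_dmegs(degs, dmrs[[ct]], dmps[[ct]], expr, masked,
                              samples, ct, config$expr_lfc_min,
                              config$expr_fdr, config$r_min,
                              config$r_alpha,
                              config$adjusted_correlation_p,
                              config$epsilon)
  }
  stage_counts$dmps <- stats::setNames(
    vapply(dmps, function(d) sum(d$retained), 0L), CONTRASTS)
  stage_counts$dmrs <- stats::setNames(
    vapply(dmrs, nrow, 0L), CONTRASTS)
  stage_counts$dmegs <- stats::setNames(
    vapply(dmegs, nrow, 0L), CONTRASTS)

  # cross-condition overlap of the two cold responses
  directed <- function(ct, tab) {
    sig <- tab[tab$contrast == ct & !is.na(tab$fdr) &
                 tab$fdr < config$expr_fdr &
                 abs(tab$log2FC) > config$expr_lfc_min, , drop = FALSE]
    data.frame(gene_id = sig$gene_id,
               direction = ifelse(sig$log2FC > 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  deg_overlap <- classify_overlap(directed("COLD_lean", degs),
                                  directed("COLD_DIO", degs))
  dmeg_dir <- function(d) data.frame(
    gene_id = d$gene_id,
    direction = ifelse(d$expr_log2FC > 0, "up", "down"),
    stringsAsFactors = FALSE)
  dmeg_overlap <- classify_overlap(dmeg_dir(dmegs$COLD_lean),
                                   dmeg_dir(dmegs$COLD_DIO))
  regulator_hits <- if (!is.null(regulators))
    crossref_regulators(degs, do.call(rbind, lapply(dmrs, function(d)
      d[, c("gene_id", "context", "contrast")])),
      do.call(rbind, lapply(dmegs, as.data.frame)), regulators,
      config$expr_lfc_min, config$expr_fdr) else NULL
  celltypes <- if (!is.null(markers) && nrow(dmegs$COLD_lean))
    celltype_overlap(dmegs$COLD_lean, markers,
                     config$celltype_denominator) else NULL

  motifs <- NULL
  if (!is.null(genome) && !is.null(pwms)) {
    prom_dmegs <- dmegs$COLD_lean[
      dmegs$COLD_lean$assigned_context == "promoter", , drop = FALSE]
    if (nrow(prom_dmegs)) {
      loci <- data.frame(chrom = prom_dmegs$best_chrom,
                         pos = prom_dmegs$best_pos,
                         stringsAsFactors = FALSE)
      fg <- extract_windows(loci, genome, config$flank)
      bg <- sample_background(ann, genome, 2L * config$flank + 1L,
                              config$n_background, config$seed,
                              chrom_lengths, config$promoter_up,
                              config$promoter_down)
      motifs <- motif_enrichment(fg$sequence, bg, pwms,
                                 config$min_score_frac)
    }
  }

  res <- structure(list(config = config, size_factors = sf, expr = expr,
                        outliers = outliers, degs = degs, dmps = dmps,
                        dmrs = dmrs, dmegs = dmegs,
                        deg_overlap = deg_overlap,
                        dmeg_overlap = dmeg_overlap,
                        regulator_hits = regulator_hits,
                        celltypes = celltypes, motifs = motifs,
                        stage_counts = stage_counts),
                   class = "methexpr_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' @export
print.methexpr_pipeline <- function(x, ...) {
  sc <- x$stage_counts
  cat("methexpr pipeline run\n")
  cat(sprintf("  genes: %d in, %d after low-count filter\n",
              sc$genes_in, sc$genes_filtered))
  cat(sprintf("  PCA outlier flags: %d\n", sc$pca_outliers))
  cat(sprintf("  CpGs: %d in, %d usable after masking\n",
              sc$cpgs_in, sc$cpgs_usable))
  for (ct in CONTRASTS) {
    cat(sprintf("  %-10s DEGs(FDR)=%d DMPs=%d DMRs=%d DMEGs=%d\n", ct,
                sc$degs_fdr[ct], sc$dmps[ct], sc$dmrs[ct], sc$dmegs[ct]))
  }
  invisible(x)
}

#' @method summary methexpr_pipeline
#' @export
summary.methexpr_pipeline <- function(object, ...) {
  lapply(object$dmegs, summary)
}

write_pipeline_outputs <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$degs, "deg_results.tsv")
  wt(res$outliers, "pca_outliers.tsv")
  for (ct in CONTRASTS) {
    wt(res$dmps[[ct]], sprintf("dmps_%s.tsv", ct))
    dmr <- res$dmrs[[ct]]
    dmr$member_idx <- NULL
    wt(dmr, sprintf("dmrs_%s.tsv", ct))
    wt(as.data.frame(res$dmegs[[ct]]), sprintf("dmegs_%s.tsv", ct))
  }
  wt(res$deg_overlap, "deg_overlap.tsv")
  wt(res$dmeg_overlap, "dmeg_overlap.tsv")
  if (!is.null(res$regulator_hits)) wt(res$regulator_hits, "regulators.tsv")
  if (!is.null(res$celltypes)) wt(res$celltypes, "celltypes.tsv")
  if (!is.null(res$motifs)) wt(res$motifs, "motif_enrichment.tsv")
  summary_json <- list(
    stage_counts = res$stage_counts,
    dmeg_categories = lapply(res$dmegs, function(d)
      as.list(table(d$category))),
    dmeg_contexts = lapply(res$dmegs, function(d)
      as.list(table(d$assigned_context))),
    dmeg_multiplicity = lapply(res$dmegs, function(d)
      as.list(dmp_multiplicity(d)$histogram)))
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log <- c(sprintf("methexpr %s", as.character(utils::packageVersion("methexpr"))),
           sprintf("R %s", R.version.string),
           sprintf("seed %d", res$config$seed),
           "config:",
           vapply(names(res$config), function(k)
             sprintf("  %s = %s", k, paste(res$config[[k]], collapse = ",")),
             ""),
           "stage record counts:",
           vapply(names(res$stage_counts), function(k)
             sprintf("  %s = %s", k,
                     paste(res$stage_counts[[k]], collapse = ",")), ""))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
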