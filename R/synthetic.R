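#' Design specification for the 2x2 study layout
#'
#' Two metabolic states (lean, DIO) crossed with two housing temperatures
#' (30 C thermoneutrality, 8 C cold), `n_per_cell` animals per cell.
#'
#' @param n_per_cell samples per design cell (>= 2).
#' @param seed integer RNG seed carried along with the design.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(n_per_cell = 7, seed = 1) {
  check_number(n_per_cell, "n_per_cell", min = 2)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 states = c("lean", "DIO"), temperatures = c(30, 8),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' @rdname design_spec
#' @param design a `design_spec`.
#' @return `design_samples()` returns the sample sheet implied by the
#'   design.
#' @export
design_samples <- function(design) {
  cells <- expand.grid(temperature = design$temperatures,
                       metabolic_state = design$states,
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%d_%d", cells$metabolic_state[i],
                          cells$temperature[i], seq_len(design$n_per_cell)),
      metabolic_state = cells$metabolic_state[i],
      temperature = cells$temperature[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a non-overlapping synthetic gene annotation
#'
#' Genes are packed left to right on each chromosome with random lengths
#' and intergenic gaps, on random strands. The first gene of the first
#' chromosome is placed with its TSS closer than 1,500 bp to the
#' chromosome start so promoter clipping is always exercised, and a
#' slice of genes is placed on a chromosome named "chrX" so
#' sex-chromosome exclusion has something to act on.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms number of autosomes (chrX is added on top).
#' @param gene_length_range min/max gene length in bp.
#' @param seed RNG seed.
#' @param gap_range min/max intergenic gap in bp.
#' @param chrom_length optional fixed chromosome length; an error names
#'   the required length when the packing does not fit.
#' @param frac_chrx fraction of genes placed on chrX.
#' @return annotation data frame with attribute `chrom_lengths` (named
#'   integer vector).
#' @export
generate_annotation <- function(n_genes = 2000, n_chroms = 4,
                                gene_length_range = c(2000, 8000),
                                seed = 1, gap_range = c(2500, 6000),
                                chrom_length = NULL, frac_chrx = 0.05) {
  check_number(n_genes, "n_genes", min = 1)
  chroms <- c(paste0("chr", seq_len(n_chroms)), "chrX")
  n_x <- if (n_genes >= 20) max(1L, round(frac_chrx * n_genes)) else 0L
  per_auto <- diff_split(n_genes - n_x, n_chroms)
  per_chrom <- c(per_auto, n_x)
  with_seed(seed, {
    rows <- list(); lengths <- integer(length(chroms))
    for (ci in seq_along(chroms)) {
      k <- per_chrom[ci]
      if (k == 0L) { lengths[ci] <- 10000L; next }
      glen <- as.integer(round(stats::runif(k, gene_length_range[1],
                                            gene_length_range[2])))
      gap <- as.integer(round(stats::runif(k, gap_range[1], gap_range[2])))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      if (ci == 1L) {  # promoter-clipping sentinel at the chromosome start
        gap[1] <- 400L
        strand[1] <- "+"
      }
      # sequential packing: start_i = previous end + gap_i
      start <- integer(k); end <- integer(k); cur <- 0L
      for (i in seq_len(k)) {
        start[i] <- cur + gap[i]
        end[i] <- start[i] + glen[i] - 1L
        cur <- end[i]
      }
      clen <- cur + 2000L
      if (!is.null(chrom_length)) {
        if (cur > chrom_length)
          stop2(sprintf(
            "cannot pack %d genes on %s within %d bp; need at least %d bp",
            k, chroms[ci], chrom_length, cur))
        clen <- as.integer(chrom_length)
      }
      lengths[ci] <- clen
      rows[[ci]] <- data.frame(
        gene_id = sprintf("gene_%s_%04d", sub("chr", "", chroms[ci]),
                          seq_len(k)),
        chrom = chroms[ci], start = start, end = end, strand = strand,
        stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    attr(ann, "chrom_lengths") <- stats::setNames(lengths, chroms)
    ann
  })
}

diff_split <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

#' Plant ground truth effects on an annotation
#'
#' Chooses planted DMEGs (coupled expression and methylation effects),
#' expression-only genes, low-count genes and leaves the rest null.
#' Planted DMEGs follow one of three profiles: `shared` (equal cold
#' response in both states, zero interaction), `lean_only` and
#' `dio_only` (state-specific cold response, nonzero interaction).
#' Each planted DMEG carries 1-3 DMP positions inside its gene body or
#' promoter window, with a methylation fold change of random sign; the
#' target correlation sign is the product of the methylation and
#' expression signs.
#'
#' @param annotation output of [generate_annotation()] (autosomal genes
#'   are eligible for planting).
#' @param frac_dmeg fraction of genes planted as DMEGs.
#' @param frac_deg_only fraction planted with expression effects only.
#' @param n_low_count number of genes forced to near-zero counts.
#' @param expr_lfc,meth_lfc absolute planted log2 fold changes.
#' @param profiles named probabilities for shared/lean_only/dio_only.
#' @param n_dmps_range min/max planted DMPs per DMEG.
#' @param seed RNG seed.
#' @param epsilon offset used in the beta fold-change definition.
#' @return object of class `synthetic_truth`: list with `genes` (per
#'   gene: planted log2FCs per contrast, flags, profile, expected DMEG
#'   contrasts) and `dmps` (per planted site: gene, chrom, pos, context,
#'   meth_log2FC, beta levels, correlation sign).
#' @export
plant_truth <- function(annotation, frac_dmeg = 0.10, frac_deg_only = 0.15,
                        n_low_count = 50, expr_lfc = 1.5, meth_lfc = 1.5,
                        profiles = c(shared = 0.4, lean_only = 0.3,
                                     dio_only = 0.3),
                        n_dmps_range = c(1, 3), seed = 1, epsilon = 0.01) {
  chrom_lengths <- attr(annotation, "chrom_lengths")
  eligible <- which(!annotation$chrom %in% SEX_CHROMS)
  n <- nrow(annotation)
  n_dmeg <- round(frac_dmeg * n)
  n_deg <- round(frac_deg_only * n)
  if (n_dmeg + n_deg + n_low_count > length(eligible))
    stop2("not enough autosomal genes for the requested planting fractions")
  with_seed(seed, {
    picked <- sample(eligible, n_dmeg + n_deg + n_low_count)
    idx_dmeg <- picked[seq_len(n_dmeg)]
    idx_deg <- picked[n_dmeg + seq_len(n_deg)]
    idx_low <- picked[n_dmeg + n_deg + seq_len(n_low_count)]
    genes <- data.frame(gene_id = annotation$gene_id,
                        lfc_COLD_lean = 0, lfc_COLD_DIO = 0,
                        lfc_interaction = 0,
                        is_planted_dmeg = FALSE, is_planted_deg = FALSE,
                        is_low_count = FALSE, profile = "null",
                        expr_sign = 0L, meth_sign = 0L,
                        stringsAsFactors = FALSE)
    genes$is_low_count[idx_low] <- TRUE
    genes$profile[idx_low] <- "low_count"
    assign_effects <- function(idx, dmeg) {
      prof <- sample(names(profiles), length(idx), replace = TRUE,
                     prob = profiles)
      sgn <- sample(c(-1L, 1L), length(idx), replace = TRUE)
      lfc <- sgn * expr_lfc
      genes$profile[idx] <<- prof
      genes$expr_sign[idx] <<- sgn
      genes$lfc_COLD_lean[idx] <<- ifelse(prof == "dio_only", 0, lfc)
      genes$lfc_COLD_DIO[idx] <<- ifelse(prof == "lean_only", 0, lfc)
      genes$lfc_interaction[idx] <<-
        genes$lfc_COLD_DIO[idx] - genes$lfc_COLD_lean[idx]
      if (dmeg) genes$is_planted_dmeg[idx] <<- TRUE else
        genes$is_planted_deg[idx] <<- TRUE
    }
    assign_effects(idx_dmeg, dmeg = TRUE)
    assign_effects(idx_deg, dmeg = FALSE)
    genes$meth_sign[idx_dmeg] <- sample(c(-1L, 1L), n_dmeg, replace = TRUE)

    # planted DMP positions inside each DMEG's body or promoter
    dmp_rows <- lapply(idx_dmeg, function(gi) {
      k <- sample(seq(n_dmps_range[1], n_dmps_range[2]), 1)
      ctx <- sample(c("body", "promoter"), k, replace = TRUE,
                    prob = c(0.55, 0.45))
      tss <- if (annotation$strand[gi] == "+") annotation$start[gi] else
        annotation$end[gi]
      cl <- unname(chrom_lengths[annotation$chrom[gi]])
      pos <- vapply(ctx, function(cx) {
        if (cx == "body") {
          sample(seq(annotation$start[gi], annotation$end[gi]), 1)
        } else {
          w <- promoter_window(tss, annotation$strand[gi],
                               chrom_length = cl)
          sample(seq(w[1], w[2]), 1)
        }
      }, 0)
      msign <- genes$meth_sign[gi]
      data.frame(gene_id = annotation$gene_id[gi],
                 chrom = annotation$chrom[gi], pos = as.integer(pos),
                 context = ctx, meth_log2FC = msign * meth_lfc,
                 corr_sign = msign * genes$expr_sign[gi],
                 stringsAsFactors = FALSE)
    })
    dmps <- do.call(rbind, dmp_rows)
    if (is.null(dmps))
      dmps <- data.frame(gene_id = character(), chrom = character(),
                         pos = integer(), context = character(),
                         meth_log2FC = numeric(), corr_sign = numeric(),
                         stringsAsFactors = FALSE)
    dmps <- dmps[!duplicated(paste(dmps$chrom, dmps$pos)), , drop = FALSE]
    rownames(dmps) <- NULL
    # beta levels realising the planted fold change:
    # log2((b_high+eps)/(b_low+eps)) = meth_lfc
    b_low <- 0.20
    b_high <- (b_low + epsilon) * 2^meth_lfc - epsilon
    if (b_high > 0.95) stop2("meth_lfc too large for the beta parametrisation")
    dmps$beta_warm <- ifelse(dmps$meth_log2FC > 0, b_low, b_high)
    dmps$beta_cold <- ifelse(dmps$meth_log2FC > 0, b_high, b_low)
    # contrasts in which the gene is expected to surface as a DMEG
    prof <- genes$profile
    genes$dmeg_contrasts <- ifelse(!genes$is_planted_dmeg, "",
                            ifelse(prof == "shared", "COLD_lean,COLD_DIO",
                            ifelse(prof == "lean_only", "COLD_lean",
                                   "COLD_DIO")))
    structure(list(genes = genes, dmps = dmps,
                   params = list(expr_lfc = expr_lfc, meth_lfc = meth_lfc,
                                 epsilon = epsilon)),
              class = "synthetic_truth")
  })
}

#' Generate a count matrix with planted effects
#'
#' Counts are negative-binomially distributed around
#' `base_mean * 2^(design effect)` with the given dispersion, where the
#' design effect per cell follows the truth table (reference cell:
#' lean at 30 C; cold effects within each state as planted). Planted
#' DMEG genes additionally receive a per-sample lognormal deviation
#' `2^(tau * z)` whose latent `z` is shared with the methylation
#' generator to realise the planted methylation-expression correlation.
#' Low-count genes are drawn with near-zero means and resampled until
#' their total stays below 10.
#'
#' @param annotation gene annotation.
#' @param design a `design_spec`.
#' @param truth a `synthetic_truth`.
#' @param dispersion NB dispersion (> 0), variance = mu + dispersion*mu^2.
#' @param base_mean_range counts are drawn around log-uniform base means
#'   in this range.
#' @param tau scale of the shared latent deviation (log2 units).
#' @param seed RNG seed (defaults to the design's seed + 1).
#' @return object of class `synthetic_counts`: list with `counts`
#'   (integer matrix), `samples` (sample sheet) and `latent` (planted
#'   gene x sample matrix of shared deviations).
#' @export
generate_counts <- function(annotation, design, truth, dispersion = 0.1,
                            base_mean_range = c(20, 2000), tau = 0.4,
                            seed = design$seed + 1L) {
  if (dispersion <= 0) stop2("dispersion must be positive")
  if (!all(truth$genes$gene_id %in% annotation$gene_id))
    stop2("truth genes are not a subset of the annotation")
  samples <- design_samples(design)
  n <- nrow(annotation); k <- nrow(samples)
  g <- truth$genes[match(annotation$gene_id, truth$genes$gene_id), ]
  cold <- samples$temperature == 8
  dio <- samples$metabolic_state == "DIO"
  with_seed(seed, {
    base <- exp(stats::runif(n, log(base_mean_range[1]),
                             log(base_mean_range[2])))
    # per-sample log2 effect: cold response within the sample's state
    eff <- outer(g$lfc_COLD_lean, as.numeric(cold & !dio)) +
      outer(g$lfc_COLD_DIO, as.numeric(cold & dio))
    planted <- which(g$is_planted_dmeg)
    latent <- matrix(0, length(planted), k,
                     dimnames = list(annotation$gene_id[planted],
                                     samples$sample_id))
    if (length(planted)) {
      latent[] <- stats::rnorm(length(planted) * k)
      eff[planted, ] <- eff[planted, ] + tau * latent
    }
    mu <- base * 2^eff
    counts <- matrix(stats::rnbinom(n * k, mu = mu, size = 1 / dispersion),
                     n, k, dimnames = list(annotation$gene_id,
                                           samples$sample_id))
    low <- which(g$is_low_count)
    for (i in low) {
      repeat {
        draw <- stats::rpois(k, 0.15)
        if (sum(draw) < 10) break
      }
      counts[i, ] <- draw
    }
    structure(list(counts = counts, samples = samples, latent = latent),
              class = "synthetic_counts")
  })
}

#' Generate per-CpG methylation calls with planted coupling
#'
#' Every site gets per-sample coverage drawn around `coverage_mean`
#' (Poisson) and methylated counts drawn binomially around a latent
#' per-sample methylation probability. For planted DMEG sites the
#' latent logit moves between the planted warm/cold beta levels
#' according to the gene's profile and is additionally coupled, with
#' scale `lambda` and the planted sign, to the same per-sample latent
#' deviation the count generator used — so M-values and stabilised
#' expression correlate with the planted sign. Background CpGs are
#' uncorrelated, a tranche of them is generated at low coverage and a
#' tranche on chrX to exercise masking and exclusion.
#'
#' @param annotation gene annotation.
#' @param design a `design_spec`.
#' @param truth a `synthetic_truth`.
#' @param coverage_mean mean read coverage (>= 1).
#' @param n_background_cpgs background (null) CpG count.
#' @param expr the `synthetic_counts` object whose `latent` matrix
#'   carries the shared deviations; omit for uncoupled (null) data.
#' @param lambda coupling scale on the logit of the latent methylation
#'   probability.
#' @param sample_jitter SD of per-sample logit noise at background
#'   sites.
#' @param frac_low_cov fraction of background sites generated at low
#'   coverage (mean 2 reads).
#' @param frac_chrx fraction of background sites placed on chrX.
#' @param seed RNG seed (defaults to the design's seed + 2).
#' @return a `cpg_set` (unmasked) whose sites include every planted DMP
#'   position.
#' @export
generate_methylation <- function(annotation, design, truth,
                                 coverage_mean = 30,
                                 n_background_cpgs = 2000, expr = NULL,
                                 lambda = 0.6, sample_jitter = 0.3,
                                 frac_low_cov = 0.05, frac_chrx = 0.05,
                                 seed = design$seed + 2L) {
  check_number(coverage_mean, "coverage_mean", min = 1)
  chrom_lengths <- attr(annotation, "chrom_lengths")
  samples <- design_samples(design)
  k <- nrow(samples)
  cold <- samples$temperature == 8
  dio <- samples$metabolic_state == "DIO"
  dmps <- truth$dmps
  # planted sites must lie in the owning gene's body or promoter
  if (nrow(dmps)) {
    asn <- assign_sites_to_regions(dmps, annotation, chrom_lengths)
    ok <- paste(dmps$gene_id, dmps$chrom, dmps$pos) %in%
      paste(asn$gene_id, asn$chrom, asn$pos)
    if (!all(ok))
      stop2("planted DMP outside its gene/promoter: ",
            paste(dmps$gene_id[!ok], collapse = ", "))
  }
  g <- truth$genes
  with_seed(seed, {
    # background positions scattered over all chromosomes
    n_x <- round(frac_chrx * n_background_cpgs)
    bg_chrom <- c(sample(setdiff(names(chrom_lengths), SEX_CHROMS),
                         n_background_cpgs - n_x, replace = TRUE),
                  rep("chrX", n_x))
    bg_pos <- vapply(bg_chrom, function(cc)
      sample.int(chrom_lengths[[cc]], 1), 0L)
    bg <- data.frame(chrom = bg_chrom, pos = bg_pos,
                     stringsAsFactors = FALSE)
    bg <- bg[!paste(bg$chrom, bg$pos) %in% paste(dmps$chrom, dmps$pos), ,
             drop = FALSE]
    sites <- data.frame(chrom = c(dmps$chrom, bg$chrom),
                        pos = as.integer(c(dmps$pos, bg$pos)),
                        strand = "+", stringsAsFactors = FALSE)
    planted <- c(rep(TRUE, nrow(dmps)), rep(FALSE, nrow(bg)))
    ns <- nrow(sites)

    # latent per-sample methylation probability
    logit_p <- matrix(0, ns, k)
    # background: site-specific base level, mildly bimodal, plus jitter
    n_bg <- sum(!planted)
    base_beta <- stats::rbeta(n_bg, 0.8, 0.8) * 0.9 + 0.05
    logit_p[!planted, ] <- stats::qlogis(base_beta) +
      matrix(stats::rnorm(n_bg * k, 0, sample_jitter), n_bg, k)
    if (nrow(dmps)) {
      prof <- g$profile[match(dmps$gene_id, g$gene_id)]
      for (i in seq_len(nrow(dmps))) {
        # cells carrying the cold beta level depend on the profile
        shifted <- if (prof[i] == "lean_only") cold & !dio
        else if (prof[i] == "dio_only") cold & dio
        else cold
        beta_s <- ifelse(shifted, dmps$beta_cold[i], dmps$beta_warm[i])
        lp <- stats::qlogis(beta_s)
        if (!is.null(expr) && dmps$gene_id[i] %in% rownames(expr$latent)) {
          z <- expr$latent[dmps$gene_id[i], ]
          lp <- lp + lambda * dmps$corr_sign[i] * z
        }
        logit_p[i, ] <- lp
      }
    }
    cov <- matrix(stats::rpois(ns * k, coverage_mean), ns, k)
    # a tranche of low-coverage background sites
    n_low <- round(frac_low_cov * n_bg)
    if (n_low > 0) {
      low_rows <- which(!planted)[seq_len(n_low)]
      cov[low_rows, ] <- stats::rpois(n_low * k, 2)
    }
    meth <- matrix(stats::rbinom(ns * k, cov, stats::plogis(logit_p)),
                   ns, k)
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]; rownames(sites) <- NULL
    dimnames(meth) <- list(NULL, samples$sample_id)
    dimnames(cov) <- list(NULL, samples$sample_id)
    new_cpg_set(sites, meth[o, , drop = FALSE], cov[o, , drop = FALSE])
  })
}

#' One-call synthetic dataset with ground truth
#'
#' Wires [generate_annotation()], [plant_truth()], [generate_counts()]
#' and [generate_methylation()] together with sub-seeds derived from
#' one master seed.
#'
#' @param seed master seed.
#' @param n_genes,n_per_cell,dispersion,coverage_mean,n_background_cpgs
#'   generator parameters (see the individual generators).
#' @param ... further arguments forwarded to [plant_truth()].
#' @return list with `annotation`, `chrom_lengths`, `design`, `samples`,
#'   `truth`, `expr` (`synthetic_counts`), `counts` (matrix) and `cpgs`.
#' @export
simulate_dataset <- function(seed = 1, n_genes = 2000, n_per_cell = 7,
                             dispersion = 0.1, coverage_mean = 30,
                             n_background_cpgs = 2000, ...) {
  design <- design_spec(n_per_cell = n_per_cell, seed = seed)
  ann <- generate_annotation(n_genes = n_genes, seed = seed)
  truth <- plant_truth(ann, seed = seed + 10L, ...)
  expr <- generate_counts(ann, design, truth, dispersion = dispersion,
                          seed = seed + 20L)
  cpgs <- generate_methylation(ann, design, truth,
                               coverage_mean = coverage_mean,
                               n_background_cpgs = n_background_cpgs,
                               expr = expr, seed = seed + 30L)
  list(annotation = ann, chrom_lengths = attr(ann, "chrom_lengths"),
       design = design, samples = expr$samples, truth = truth,
       expr = expr, counts = expr$counts, cpgs = cpgs)
}

#' Random genome sequences for a synthetic annotation
#'
#' Uniform-random DNA per chromosome at the annotated lengths, for
#' motif-window extraction on synthetic data.
#'
#' @param chrom_lengths named integer vector.
#' @param seed RNG seed.
#' @param gc GC content.
#' @return named `Biostrings::DNAStringSet`.
#' @export
generate_genome <- function(chrom_lengths, seed = 1, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(n)
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""),
      "")
    Biostrings::DNAStringSet(seqs)
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the pipeline's external formats: counts TSV, sample sheet TSV,
#' one Bismark-style cytosine report per sample, a GTF and the truth
#' tables.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  write_gtf(sim$annotation, file.path(dir, "genes.gtf"))
  for (j in seq_len(ncol(sim$cpgs$cov))) {
    rep <- data.frame(chrom = sim$cpgs$sites$chrom,
                      pos = sim$cpgs$sites$pos,
                      strand = sim$cpgs$sites$strand,
                      meth = sim$cpgs$meth[, j],
                      unmeth = sim$cpgs$cov[, j] - sim$cpgs$meth[, j])
    write_cytosine_report(rep, file.path(
      dir, sprintf("%s.cytosine_report.tsv",
                   colnames(sim$cpgs$cov)[j])))
  }
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$dmps, file.path(dir, "truth_dmps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
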