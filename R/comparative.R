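#' Classify the overlap of two directed gene sets
#'
#' Given two sets of significant genes with regulation directions
#' (up/down), each gene in the union falls into exactly one class:
#' `similar_up` / `similar_down` (both sets, same sign), `contrary`
#' (both sets, opposite sign), `unique_A` / `unique_B` (one set only).
#'
#' @param setA,setB data frames with `gene_id` and `direction`
#'   ("up"/"down"); duplicate gene ids within a set are an error.
#' @return data frame with `gene_id` and `class`.
#' @export
classify_overlap <- function(setA, setB) {
  for (s in list(setA, setB)) {
    if (anyDuplicated(s$gene_id)) stop2("duplicate gene within a set")
    if (!all(s$direction %in% c("up", "down")))
      stop2("direction must be 'up' or 'down'")
  }
  genes <- union(setA$gene_id, setB$gene_id)
  da <- setA$direction[match(genes, setA$gene_id)]
  db <- setB$direction[match(genes, setB$gene_id)]
  cls <- ifelse(is.na(da), "unique_B",
         ifelse(is.na(db), "unique_A",
         ifelse(da != db, "contrary",
         ifelse(da == "up", "similar_up", "similar_down"))))
  data.frame(gene_id = genes, class = cls, stringsAsFactors = FALSE)
}

#' Format a count ratio as a printed percentage
#'
#' Reports `100 * numerator / denominator` rounded to an integer, except
#' when the value lies within `half_window` points of a half-integer —
#' where integer rounding is unstable — in which case one decimal is
#' kept. With the defaults 1524/7089 prints "21.5" while 1001/5249
#' prints "19".
#'
#' @param numerator,denominator counts.
#' @param half_window half-integer proximity (percentage points) below
#'   which one decimal is used.
#' @return character scalar (no percent sign).
#' @export
format_percentage <- function(numerator, denominator, half_window = 0.05) {
  if (denominator <= 0) stop2("denominator must be positive")
  v <- 100 * numerator / denominator
  frac <- v - floor(v)
  if (abs(frac - 0.5) <= half_window) {
    format(round(v, 1), nsmall = 1)
  } else {
    format(round(v))
  }
}

#' Percentage report for a set of count pairs
#'
#' @param numerators,denominators equal-length count vectors.
#' @inheritParams format_percentage
#' @return data frame with the raw value and the printed string.
#' @export
overlap_percentages <- function(numerators, denominators,
                                half_window = 0.05) {
  stopifnot(length(numerators) == length(denominators))
  printed <- mapply(format_percentage, numerators, denominators,
                    MoreArgs = list(half_window = half_window))
  data.frame(numerator = numerators, denominator = denominators,
             value = 100 * numerators / denominators,
             printed = unname(printed), stringsAsFactors = FALSE)
}

#' Cross-reference epigenetic regulators
#'
#' For each gene in a regulator list (e.g. DNA-methylation-related
#' factors), reports in which contrasts it is differentially expressed,
#' whether any retained DMP lies in its gene body or promoter regions,
#' and whether it meets the full DMEG criteria.
#'
#' @param degs combined [fit_contrasts()] table (all contrasts).
#' @param dmrs combined [call_dmrs()] tables.
#' @param dmegs combined `dmeg_set` tables (data frame with `gene_id`,
#'   `contrast`).
#' @param regulators character vector of gene symbols (non-empty).
#' @param expr_lfc_min,expr_fdr DEG gates used for the contrast listing.
#' @return data frame with `gene_id`, `contrasts` (comma-separated),
#'   `has_dmp`, `is_dmeg`.
#' @export
crossref_regulators <- function(degs, dmrs, dmegs, regulators,
                                expr_lfc_min = 0.5, expr_fdr = 0.05) {
  if (length(regulators) == 0L) stop2("empty regulator list")
  sig <- degs[!is.na(degs$fdr) & degs$fdr < expr_fdr &
                abs(degs$log2FC) > expr_lfc_min, , drop = FALSE]
  out <- do.call(rbind, lapply(regulators, function(g) {
    cts <- sort(unique(sig$contrast[sig$gene_id == g]))
    data.frame(gene_id = g,
               contrasts = paste(cts, collapse = ","),
               has_dmp = g %in% dmrs$gene_id,
               is_dmeg = g %in% dmegs$gene_id,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Overlap DMEGs with cell-type marker sets
#'
#' For each cell type, the fraction of its marker genes that are DMEGs
#' (default denominator) or the fraction of DMEGs that are markers
#' (`denominator = "dmegs"`), plus the four-way category breakdown of
#' the intersection. A gene in several marker sets counts in each.
#'
#' @param dmegs `dmeg_set` (needs `gene_id` and `category`).
#' @param markers data frame with `cell_type` and `gene_id`.
#' @param denominator "markers" or "dmegs".
#' @return data frame per cell type with `n_markers`, `n_overlap`,
#'   `percent` and one count column per category.
#' @export
celltype_overlap <- function(dmegs, markers,
                             denominator = c("markers", "dmegs")) {
  denominator <- match.arg(denominator)
  if (nrow(markers) == 0L) stop2("marker table is empty")
  cats <- c("hypo_up", "hypo_down", "hyper_up", "hyper_down")
  out <- do.call(rbind, lapply(split(markers, markers$cell_type), function(m) {
    inter <- dmegs[dmegs$gene_id %in% m$gene_id, , drop = FALSE]
    den <- if (denominator == "markers") length(unique(m$gene_id)) else
      max(nrow(dmegs), 1L)
    counts <- table(factor(inter$category, levels = cats))
    cbind(data.frame(cell_type = m$cell_type[1],
                     n_markers = length(unique(m$gene_id)),
                     n_overlap = nrow(inter),
                     percent = 100 * nrow(inter) / den,
                     stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(counts))))
  }))
  rownames(out) <- NULL
  out
}
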