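#' Gene annotation tables and promoter windows
#'
#' The pipeline represents gene annotation as a plain data frame with one
#' row per gene and 1-based inclusive coordinates (GTF convention):
#' `gene_id`, `chrom`, `start`, `end`, `strand` ("+" or "-"). The
#' transcription start site (TSS) is `start` on the plus strand and `end`
#' on the minus strand.
#'
#' @param annotation data frame as described above.
#' @return `annotation_tss()` returns an integer vector of TSS positions.
#' @export
annotation_tss <- function(annotation) {
  validate_annotation(annotation)
  ifelse(annotation$strand == "+", annotation$start, annotation$end)
}

validate_annotation <- function(annotation) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!is.data.frame(annotation) || !all(req %in% names(annotation)))
    stop2("annotation must be a data frame with columns ",
          paste(req, collapse = ", "))
  if (any(annotation$start > annotation$end))
    stop2("annotation has start > end")
  if (!all(annotation$strand %in% c("+", "-")))
    stop2("annotation strand must be '+' or '-'")
  invisible(annotation)
}

#' Promoter window around a transcription start site
#'
#' The promoter of a gene spans `upstream` bases upstream and `downstream`
#' bases downstream of its TSS, strand-aware, clipped to the chromosome.
#' With the defaults (1500 up, 500 down) an unclipped promoter is 2001 bp
#' in 1-based inclusive coordinates.
#'
#' @param tss TSS position (1-based).
#' @param strand "+" or "-".
#' @param upstream,downstream window extents in bp.
#' @param chrom_length chromosome length in bp; the window is clipped to
#'   `[1, chrom_length]`.
#' @return integer vector `c(start, end)`.
#' @examples
#' promoter_window(10000, "+")   # 8500..10500
#' promoter_window(10000, "-")   # 9500..11500
#' @export
promoter_window <- function(tss, strand, upstream = 1500, downstream = 500,
                            chrom_length = NULL) {
  check_number(tss, "tss", min = 1)
  if (!strand %in% c("+", "-")) stop2("strand must be '+' or '-'")
  if (!is.null(chrom_length) && tss > chrom_length)
    stop2("tss lies outside the chromosome (tss > chrom_length)")
  if (strand == "+") {
    w <- c(tss - upstream, tss + downstream)
  } else {
    w <- c(tss - downstream, tss + upstream)
  }
  w[1] <- max(1, w[1])
  if (!is.null(chrom_length)) w[2] <- min(chrom_length, w[2])
  as.integer(w)
}

#' Promoter windows for a whole annotation table
#'
#' @inheritParams annotation_tss
#' @param chrom_lengths named integer vector of chromosome lengths; optional
#'   (no right clipping where missing).
#' @inheritParams promoter_window
#' @return data frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_windows <- function(annotation, chrom_lengths = NULL,
                             upstream = 1500, downstream = 500) {
  validate_annotation(annotation)
  tss <- annotation_tss(annotation)
  n <- nrow(annotation)
  out <- data.frame(gene_id = annotation$gene_id,
                    chrom = annotation$chrom,
                    start = integer(n), end = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cl <- if (is.null(chrom_lengths)) NULL else
      unname(chrom_lengths[annotation$chrom[i]])
    if (!is.null(cl) && is.na(cl)) cl <- NULL
    w <- promoter_window(tss[i], annotation$strand[i], upstream, downstream, cl)
    out$start[i] <- w[1]; out$end[i] <- w[2]
  }
  out
}

#' Assign CpG sites to gene-body and promoter regions
#'
#' Builds an interval index over gene bodies and promoter windows and
#' returns every (site, gene, context) overlap. A site inside both the
#' body of one gene and the promoter of another (or the same) gene gets
#' one row per assignment; sites in neither get none. Coordinates are
#' 1-based inclusive.
#'
#' @param sites data frame with `chrom` and `pos`.
#' @param annotation gene annotation table.
#' @param chrom_lengths optional named lengths for promoter clipping.
#' @param upstream,downstream promoter extents.
#' @return data frame with `site_idx` (row in `sites`), `chrom`, `pos`,
#'   `gene_id`, `context` ("body" or "promoter").
#' @export
assign_sites_to_regions <- function(sites, annotation, chrom_lengths = NULL,
                                    upstream = 1500, downstream = 500) {
  validate_annotation(annotation)
  if (!all(c("chrom", "pos") %in% names(sites)))
    stop2("sites must have columns chrom, pos")
  prom <- promoter_windows(annotation, chrom_lengths, upstream, downstream)
  regions <- rbind(
    data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
               start = annotation$start, end = annotation$end,
               context = "body", stringsAsFactors = FALSE),
    data.frame(gene_id = prom$gene_id, chrom = prom$chrom,
               start = prom$start, end = prom$end,
               context = "promoter", stringsAsFactors = FALSE))
  if (nrow(sites) == 0L || nrow(regions) == 0L) {
    return(data.frame(site_idx = integer(), chrom = character(),
                      pos = integer(), gene_id = character(),
                      context = character(), stringsAsFactors = FALSE))
  }
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_reg, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(site_idx = qi,
                    chrom = sites$chrom[qi],
                    pos = sites$pos[qi],
                    gene_id = regions$gene_id[si],
                    context = regions$context[si],
                    stringsAsFactors = FALSE)
  out[order(out$site_idx, out$gene_id, out$context), , drop = FALSE]
}
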