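#' Read a gene-level count matrix
#'
#' Expects a tab-separated file whose first column is `gene_id` and whose
#' remaining columns are integer counts, one per sample.
#'
#' @param path file path.
#' @return integer matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop2("count file needs gene_id plus >=1 sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0))
    stop2("count matrix contains negative or missing values")
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_counts
#' @param counts integer matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' Tab-separated with columns `sample_id`, `metabolic_state` (lean/DIO) and
#' `temperature` (8/30).
#' @param path file path.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "metabolic_state", "temperature")
  if (!all(req %in% names(df)))
    stop2("sample sheet must have columns ", paste(req, collapse = ", "))
  if (!all(df$metabolic_state %in% c("lean", "DIO")))
    stop2("metabolic_state must be 'lean' or 'DIO'")
  if (!all(df$temperature %in% c(8, 30)))
    stop2("temperature must be 8 or 30")
  df
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style genome-wide cytosine report
#'
#' One row per cytosine: chrom, 1-based position, strand, count methylated,
#' count unmethylated, context, trinucleotide. Malformed rows raise an
#' error naming the offending line.
#'
#' @param path file path.
#' @param sample_id label attached to the result.
#' @param exclude_sex_chroms drop rows on sex chromosomes.
#' @param sex_chroms chromosome names treated as sex chromosomes.
#' @return data frame with `chrom`, `pos`, `strand`, `meth`, `unmeth`, plus
#'   a `sample_id` attribute.
#' @export
read_cytosine_report <- function(path, sample_id,
                                 exclude_sex_chroms = TRUE,
                                 sex_chroms = SEX_CHROMS) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "strand", "meth",
                                        "unmeth", "context", "tri"))
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop2(sprintf("line %d: unknown strand symbol '%s'",
                  bad_strand[1], df$strand[bad_strand[1]]))
  num_bad <- which(is.na(df$pos) | is.na(df$meth) | is.na(df$unmeth) |
                     df$pos < 1 | df$meth < 0 | df$unmeth < 0)
  if (length(num_bad))
    stop2(sprintf("line %d: malformed position or negative count", num_bad[1]))
  if (exclude_sex_chroms) df <- df[!df$chrom %in% sex_chroms, , drop = FALSE]
  df <- df[, c("chrom", "pos", "strand", "meth", "unmeth")]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  df
}

#' @rdname read_cytosine_report
#' @param report data frame with `chrom`, `pos`, `strand`, `meth`, `unmeth`
#'   (as produced by the generator or `read_cytosine_report`).
#' @export
write_cytosine_report <- function(report, path) {
  out <- data.frame(report$chrom, report$pos, report$strand,
                    report$meth, report$unmeth, "CpG", "CGG")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Combine per-sample cytosine reports into a CpG set
#'
#' Sites are matched on (chrom, pos, strand); a site absent from a sample
#' gets coverage 0 there. The result is the container all methylation
#' stages operate on.
#'
#' @param reports named list of per-sample report data frames (names =
#'   sample ids; unnamed lists fall back to each report's `sample_id`
#'   attribute).
#' @return an object of class `cpg_set`: list with `sites` (chrom, pos,
#'   strand), `meth` and `cov` integer matrices (sites x samples), `mask`
#'   character matrix of masking reasons ("" = usable) and `dropped`
#'   logical per site.
#' @export
combine_cytosine_reports <- function(reports) {
  ids <- names(reports)
  if (is.null(ids) || any(ids == ""))
    ids <- vapply(reports, function(r) attr(r, "sample_id") %||% "", "")
  if (any(ids == "")) stop2("every report needs a sample id")
  key_all <- unique(unlist(lapply(reports, function(r)
    paste(r$chrom, r$pos, r$strand, sep = "\r"))))
  parts <- strsplit(key_all, "\r", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      strand = vapply(parts, `[`, "", 3L),
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos, sites$strand)
  sites <- sites[o, , drop = FALSE]; key_all <- key_all[o]
  rownames(sites) <- NULL
  ns <- nrow(sites); k <- length(reports)
  meth <- matrix(0L, ns, k, dimnames = list(NULL, ids))
  cov <- matrix(0L, ns, k, dimnames = list(NULL, ids))
  for (j in seq_len(k)) {
    r <- reports[[j]]
    idx <- match(paste(r$chrom, r$pos, r$strand, sep = "\r"), key_all)
    meth[idx, j] <- as.integer(r$meth)
    cov[idx, j] <- as.integer(r$meth + r$unmeth)
  }
  new_cpg_set(sites, meth, cov)
}

new_cpg_set <- function(sites, meth, cov) {
  stopifnot(nrow(sites) == nrow(meth), all(dim(meth) == dim(cov)))
  structure(list(sites = sites, meth = meth, cov = cov,
                 mask = matrix("", nrow(meth), ncol(meth),
                               dimnames = dimnames(meth)),
                 dropped = rep(FALSE, nrow(meth))),
            class = "cpg_set")
}

#' @export
print.cpg_set <- function(x, ...) {
  cat(sprintf("cpg_set: %d sites x %d samples (%d dropped by masking)\n",
              nrow(x$sites), ncol(x$cov), sum(x$dropped)))
  invisible(x)
}

#' Beta values of a CpG set
#'
#' methylated / coverage per site and sample; NA where coverage is zero or
#' the call is masked.
#' @param cpgs a `cpg_set`.
#' @export
beta_values <- function(cpgs) {
  b <- ifelse(cpgs$cov > 0, cpgs$meth / pmax(cpgs$cov, 1L), NA_real_)
  b[cpgs$mask != ""] <- NA_real_
  b
}

#' Read gene annotation from GTF
#'
#' Transcript- or exon-level features are collapsed to one record per gene
#' using the outermost coordinates; the TSS is taken from the collapsed
#' record. Coordinates stay 1-based inclusive.
#'
#' @param path GTF file.
#' @param exclude_sex_chroms drop genes on sex chromosomes.
#' @param sex_chroms sex-chromosome name set.
#' @return annotation data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
read_gtf <- function(path, exclude_sex_chroms = FALSE,
                     sex_chroms = SEX_CHROMS) {
  gr <- rtracklayer::import(path, format = "gtf")
  ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids)) stop2("GTF lacks gene_id attributes")
  df <- data.frame(gene_id = ids,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df <- df[df$strand %in% c("+", "-"), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(df, df$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (exclude_sex_chroms) agg <- agg[!agg$chrom %in% sex_chroms, , drop = FALSE]
  agg[order(agg$chrom, agg$start), , drop = FALSE]
}

#' @rdname read_gtf
#' @param annotation annotation data frame to write (one gene feature per
#'   row).
#' @export
write_gtf <- function(annotation, path) {
  validate_annotation(annotation)
  lines <- sprintf(
    '%s\tmethexpr\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    annotation$chrom, annotation$start, annotation$end,
    annotation$strand, annotation$gene_id, annotation$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Export regions as BED6
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so start is shifted by one on the way out.
#' @param regions data frame with `chrom`, `start`, `end` and optionally
#'   `gene_id` and `strand`.
#' @param path output path.
#' @export
export_bed <- function(regions, path) {
  name <- regions$gene_id %||% "."
  strand <- regions$strand %||% "."
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                   name, 0L, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
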