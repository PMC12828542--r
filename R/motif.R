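#' Read JASPAR-format position matrices
#'
#' Parses the JASPAR text layout: a `>ID NAME` header followed by four
#' rows `A [ 4 19 0 ... ]` (brackets optional) for A, C, G, T. Count
#' columns are converted to probabilities after adding `pseudocount` to
#' every cell.
#'
#' @param path JASPAR-format file.
#' @param pseudocount value added to each matrix cell before column
#'   normalisation.
#' @return named list of PWMs (4 x L probability matrices with rownames
#'   A, C, G, T; each column sums to 1).
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop2("no JASPAR records ('>' headers) found")
  pwms <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4L)
      stop2("JASPAR record must have 4 base rows: ",
            sub("^>", "", lines[heads[i]]))
    id <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]][1]
    rows <- lapply(block, function(l) {
      base <- sub("^\\s*([ACGTacgt]).*", "\\1", l)
      nums <- as.numeric(strsplit(trimws(gsub("^\\s*[ACGTacgt]\\s*|\\[|\\]",
                                              " ", l)), "\\s+")[[1]])
      list(base = toupper(base), counts = nums)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop2("JASPAR record ", id, " lacks A/C/G/T rows")
    mat <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(mat) <- bases
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
    pwms[[id]] <- pwm_from_counts(mat, pseudocount)
  }
  pwms
}

#' @rdname read_jaspar
#' @param counts 4 x L count (or probability) matrix with rownames
#'   A, C, G, T.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.01) {
  if (!identical(rownames(counts), c("A", "C", "G", "T")))
    stop2("count matrix needs rownames A, C, G, T")
  m <- counts + pseudocount
  sweep(m, 2, colSums(m), "/")
}

pwm_logodds <- function(pwm, background = 0.25) log2(pwm / background)

#' Count PWM matches in a sequence
#'
#' Scores every offset on both strands with the log-odds of the PWM
#' against a uniform 0.25 background; an offset is a match when its
#' score reaches `min_score_frac` of the maximum attainable score for
#' that PWM. Overlapping matches all count. `N` bases contribute zero
#' log-odds. Letters outside A, C, G, T, N are an error.
#'
#' @param sequence character scalar (or `Biostrings::DNAString`).
#' @param pwm probability matrix from [read_jaspar()] /
#'   [pwm_from_counts()].
#' @param min_score_frac relative score threshold.
#' @return integer match count (both strands).
#' @export
scan_pwm <- function(sequence, pwm, min_score_frac = 0.80) {
  seq_chr <- toupper(as.character(sequence))
  chars <- strsplit(seq_chr, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    stop2("sequence contains letters outside A, C, G, T, N")
  L <- ncol(pwm); n <- length(chars)
  if (n < L) return(0L)
  lo <- pwm_logodds(pwm)
  lo <- rbind(lo, N = 0)  # N row contributes nothing
  threshold <- min_score_frac * sum(apply(lo[1:4, , drop = FALSE], 2, max))
  count_strand <- function(ch) {
    idx <- match(ch, c("A", "C", "G", "T", "N"))
    n_off <- length(ch) - L + 1L
    scores <- numeric(n_off)
    for (j in seq_len(L)) {
      scores <- scores + lo[cbind(idx[j:(j + n_off - 1L)], j)]
    }
    sum(scores >= threshold)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- rev(unname(comp[chars]))
  as.integer(count_strand(chars) + count_strand(rc))
}

#' Extract +/- flank windows around DMEG methylation loci
#'
#' For each promoter-context DMEG the best-DMP position is extended
#' `flank` bases in both directions and the forward-strand sequence
#' extracted from the genome (strand handling is left to the scanner,
#' which covers both strands). Windows are clipped at chromosome ends
#' and flagged when shortened.
#'
#' @param loci data frame with `chrom` and `pos` (e.g. `best_chrom` /
#'   `best_pos` of a promoter-context `dmeg_set`, renamed).
#' @param genome named `Biostrings::DNAStringSet` (or named character
#'   vector of chromosome sequences).
#' @param flank extension in bp (window length `2 * flank + 1` when
#'   unclipped).
#' @return data frame with `chrom`, `pos`, `start`, `end`, `clipped`,
#'   `sequence` (uppercase).
#' @export
extract_windows <- function(loci, genome, flank = 20) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  seqs <- character(nrow(loci)); starts <- integer(nrow(loci))
  ends <- integer(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    if (!chrom %in% names(genome))
      stop2("locus on unknown chromosome: ", chrom)
    clen <- Biostrings::nchar(genome[[chrom]])
    if (loci$pos[i] < 1 || loci$pos[i] > clen)
      stop2("locus outside chromosome bounds: ", chrom, ":", loci$pos[i])
    starts[i] <- max(1L, loci$pos[i] - flank)
    ends[i] <- min(clen, loci$pos[i] + flank)
    seqs[i] <- toupper(as.character(
      Biostrings::subseq(genome[[chrom]], starts[i], ends[i])))
  }
  data.frame(chrom = loci$chrom, pos = loci$pos, start = starts,
             end = ends, clipped = (ends - starts + 1L) < (2L * flank + 1L),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Sample background promoter windows
#'
#' Each iteration picks one promoter uniformly among those long enough,
#' then a window start uniformly inside it, and extracts the
#' `window_length`-bp sequence. The per-iteration windows feed the
#' enrichment test's background dispersion estimate.
#'
#' @param annotation gene annotation table.
#' @param genome named sequence set (as in [extract_windows()]).
#' @param window_length window size in bp.
#' @param n_iter number of background windows.
#' @param seed RNG seed.
#' @param chrom_lengths optional chromosome lengths for promoter
#'   clipping (defaults to the genome's sequence lengths).
#' @inheritParams promoter_windows
#' @return character vector of `n_iter` uppercase sequences.
#' @export
sample_background <- function(annotation, genome, window_length = 41,
                              n_iter = 5000, seed = NULL,
                              chrom_lengths = NULL,
                              upstream = 1500, downstream = 500) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(chrom_lengths))
    chrom_lengths <- stats::setNames(Biostrings::nchar(genome), names(genome))
  prom <- promoter_windows(annotation, chrom_lengths, upstream, downstream)
  prom <- prom[prom$chrom %in% names(genome), , drop = FALSE]
  len <- prom$end - prom$start + 1L
  prom <- prom[len >= window_length, , drop = FALSE]
  if (nrow(prom) == 0L)
    stop2("no promoter is at least ", window_length, " bp long")
  with_seed(seed, {
    pi_ <- sample.int(nrow(prom), n_iter, replace = TRUE)
    max_start <- prom$end[pi_] - window_length + 1L
    starts <- prom$start[pi_] +
      floor(stats::runif(n_iter) * (max_start - prom$start[pi_] + 1L))
    out <- vapply(seq_len(n_iter), function(i) {
      toupper(as.character(Biostrings::subseq(
        genome[[prom$chrom[pi_[i]]]], starts[i],
        starts[i] + window_length - 1L)))
    }, "")
    attr(out, "promoter_idx") <- pi_
    attr(out, "gene_id") <- prom$gene_id[pi_]
    out
  })
}

#' Overdispersed-Poisson motif enrichment test
#'
#' Models per-window match counts of each motif with a
#' quasipoisson-style rate comparison: foreground windows versus
#' background iteration windows, Wald test on the log rate difference
#' from a `glm(count ~ group, family = quasipoisson)` fit. When the
#' combined counts show no variance beyond one group (glm degenerate),
#' an exact Poisson rate test against the background mean is used and
#' flagged.
#'
#' @param fg_counts integer vector: matches per foreground window.
#' @param bg_counts integer vector: matches per background window
#'   (>= 100 iterations).
#' @return list with `observed` (total foreground matches),
#'   `fg_rate`, `bg_mean`, `bg_var`, `log2_rate_ratio`, `direction`
#'   ("over"/"under"), `p`, `method`.
#' @export
test_enrichment <- function(fg_counts, bg_counts) {
  if (length(fg_counts) < 1L) stop2("need at least one foreground window")
  if (length(bg_counts) < 100L) stop2("need >=100 background iterations")
  fg_rate <- mean(fg_counts); bg_mean <- mean(bg_counts)
  bg_var <- stats::var(bg_counts)
  rr <- (fg_rate + 0.5 / length(fg_counts)) /
    (bg_mean + 0.5 / length(bg_counts))
  direction <- if (fg_rate >= bg_mean) "over" else "under"
  y <- c(fg_counts, bg_counts)
  grp <- rep(c(1L, 0L), c(length(fg_counts), length(bg_counts)))
  p <- NA_real_; method <- "quasipoisson"
  if (bg_var > 0 && sum(y) > 0) {
    fit <- tryCatch(
      stats::glm(y ~ grp, family = stats::quasipoisson()),
      warning = function(w) NULL, error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      sm <- summary(fit)$coefficients
      if (nrow(sm) == 2L && is.finite(sm[2, 4])) p <- sm[2, 4]
    }
  }
  if (is.na(p)) {
    method <- "poisson_exact"
    p <- stats::poisson.test(sum(fg_counts),
                             T = length(fg_counts),
                             r = max(bg_mean, 1e-12))$p.value
  }
  list(observed = sum(fg_counts), fg_rate = fg_rate, bg_mean = bg_mean,
       bg_var = bg_var, log2_rate_ratio = log2(rr),
       direction = direction, p = p, method = method)
}

#' Motif enrichment over a PWM collection
#'
#' Scans foreground and background windows with every PWM and applies
#' [test_enrichment()] per motif, with BH adjustment across motifs.
#'
#' @param fg_seqs foreground window sequences.
#' @param bg_seqs background window sequences.
#' @param pwms named list of PWMs.
#' @param min_score_frac relative score threshold for a match.
#' @return data frame with one row per motif: `motif_id`, `observed`,
#'   `bg_mean`, `bg_var`, `log2_rate_ratio`, `direction`, `p`, `fdr`,
#'   `method`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs, pwms,
                             min_score_frac = 0.80) {
  rows <- lapply(names(pwms), function(id) {
    fg <- vapply(fg_seqs, scan_pwm, 0L, pwm = pwms[[id]],
                 min_score_frac = min_score_frac, USE.NAMES = FALSE)
    bg <- vapply(bg_seqs, scan_pwm, 0L, pwm = pwms[[id]],
                 min_score_frac = min_score_frac, USE.NAMES = FALSE)
    te <- test_enrichment(fg, bg)
    data.frame(motif_id = id, observed = te$observed,
               bg_mean = te$bg_mean, bg_var = te$bg_var,
               log2_rate_ratio = te$log2_rate_ratio,
               direction = te$direction, p = te$p, method = te$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out
}

#' One-sided hypergeometric comparison of motif hit sets
#'
#' Upper-tail probability of observing at least `hits_in_subset`
#' marked elements when drawing `subset_size` from a reference
#' population of `reference_size` containing `hits_in_reference`
#' marked elements.
#'
#' @param hits_in_subset,subset_size,hits_in_reference,reference_size
#'   consistent counts (`hits_in_subset <= subset_size`,
#'   `hits_in_subset <= hits_in_reference`,
#'   `subset_size <= reference_size`).
#' @return one-sided p-value.
#' @export
hypergeom_contrast <- function(hits_in_subset, subset_size,
                               hits_in_reference, reference_size) {
  if (hits_in_subset > subset_size || hits_in_subset > hits_in_reference ||
      subset_size > reference_size || hits_in_reference > reference_size ||
      min(hits_in_subset, subset_size, hits_in_reference,
          reference_size) < 0)
    stop2("inconsistent hypergeometric counts")
  stats::phyper(hits_in_subset - 1, hits_in_reference,
                reference_size - hits_in_reference, subset_size,
                lower.tail = FALSE)
}
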