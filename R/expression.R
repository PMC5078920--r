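#' Count expressed genes per sample
#'
#' A gene counts as expressed in a sample when its length-normalized
#' expression reaches the detection threshold (at least `threshold` reads per
#' nucleotide; the boundary is inclusive). Also reports the percentage of the
#' panel's gene universe that is expressed, the usual way breadth of
#' expression is summarized across tissues.
#'
#' @param panel an [expression_panel()].
#' @param threshold reads/nt detection threshold (default 0.01).
#' @return data frame with columns `sample`, `n_expressed`, `pct_of_panel`.
#' @export
count_expressed_genes <- function(panel, threshold = 0.01) {
  expressed <- panel$reads_per_nt >= threshold
  n <- colSums(expressed)
  data.frame(
    sample = panel$samples,
    n_expressed = as.integer(n),
    pct_of_panel = 100 * n / length(panel$genes),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Subsample a sample's gene counts to a fixed depth
#'
#' Draws `n_reads` reads without replacement from one sample's per-gene
#' counts (a multivariate hypergeometric draw). This operates at the
#' gene-count level -- an approximation of read-level subsampling appropriate
#' when the input is a count table rather than alignments -- and is how
#' samples are put on comparable depth before threshold-based comparisons.
#'
#' @param counts genes x samples count matrix.
#' @param sample column to subsample.
#' @param n_reads target depth; must not exceed the column total.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return the count matrix with the chosen column replaced by the
#'   subsampled counts (column sum exactly `n_reads`).
#' @export
subsample_counts <- function(counts, sample, n_reads, seed) {
  counts <- as.matrix(counts)
  if (!sample %in% colnames(counts)) stop("unknown sample: ", sample)
  x <- counts[, sample]
  total <- sum(x)
  if (n_reads > total) {
    stop(sprintf("n_reads (%s) exceeds total counts (%s) in sample %s",
                 format(n_reads, scientific = FALSE),
                 format(total, scientific = FALSE), sample))
  }
  res <- local_seed(seed, {
    out <- numeric(length(x))
    rem <- n_reads
    rest <- total
    nz <- which(x > 0)
    for (i in nz) {
      if (rem == 0) break
      rest <- rest - x[i]
      d <- stats::rhyper(1L, m = x[i], n = rest, k = rem)
      out[i] <- d
      rem <- rem - d
    }
    out
  })
  counts[, sample] <- res
  counts
}

#' Assign expressed genes to expression quartiles
#'
#' Ranks the genes expressed in one sample by their length-normalized
#' expression and splits them into four equal-size bins, `Q1` (lowest) to
#' `Q4` (highest). Ties keep the stable input order; when the gene count is
#' not divisible by four the remainder genes go to the lower quartiles first,
#' so bin sizes differ by at most one.
#'
#' @param panel an [expression_panel()].
#' @param sample sample label.
#' @param threshold reads/nt expression threshold gating entry (inclusive).
#' @param genes optional subset of gene ids to bin (already-expressed genes
#'   only are kept).
#' @return named factor (levels `Q1`..`Q4`) over the expressed genes.
#' @export
expression_quartiles <- function(panel, sample, threshold = 0.01,
                                 genes = NULL) {
  v <- panel$reads_per_nt[, sample]
  keep <- v >= threshold
  if (!is.null(genes)) keep <- keep & panel$genes %in% genes
  ids <- panel$genes[keep]
  v <- v[keep]
  n <- length(ids)
  if (n == 0L) {
    return(factor(character(0), levels = paste0("Q", 1:4)))
  }
  # stable ascending rank: order() breaks ties by position
  o <- order(v)
  sizes <- rep(n %/% 4L, 4L)
  rem <- n %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  lab <- rep(paste0("Q", 1:4), times = sizes)
  out <- factor(character(n), levels = paste0("Q", 1:4))
  out[o] <- lab
  names(out) <- ids
  out
}

#' Median-of-ratios size factors
#'
#' The classic count-normalization used for cross-sample comparison of
#' individual genes (e.g. editing-enzyme expression): each gene's geometric
#' mean across samples forms a pseudo-reference, and a sample's size factor
#' is the median ratio of its counts to that reference, taken over genes
#' positive in every sample. Normalized counts are `count / factor`.
#'
#' @param counts genes x samples count matrix.
#' @param pseudocount added to every count before computing factors; leave at
#'   0 unless no gene is positive in all samples.
#' @return named numeric vector of per-sample size factors.
#' @export
median_of_ratios_factors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no gene has positive counts in every sample; ",
         "consider the pseudocount argument")
  }
  factors <- apply(counts[use, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - loggeo[use]))
  })
  factors
}

#' Normalize counts by median-of-ratios size factors
#'
#' @inheritParams median_of_ratios_factors
#' @return matrix of normalized counts (`count / factor`).
#' @export
normalize_counts <- function(counts, pseudocount = 0) {
  f <- median_of_ratios_factors(counts, pseudocount)
  sweep(as.matrix(counts), 2L, f, "/")
}
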