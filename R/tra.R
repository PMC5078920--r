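#' Thresholds for tissue-restricted antigen calling
#'
#' Collects the FPKM and reads/nt cut-offs used by TRA detection, mirror
#' coverage and the leave-one-out analysis. A TRA gene must be highly
#' expressed (FPKM strictly above `high_fpkm`) in exactly one non-excluded
#' tissue and lowly expressed (FPKM strictly below `low_fpkm`) in every
#' other; values falling in the middle band `[low_fpkm, high_fpkm]` make a
#' gene neither high nor low, which both disqualifies TRA status in that
#' tissue and blocks it elsewhere. The reference (mTEC-like) samples are
#' excluded from the restriction test via `excluded_samples`.
#'
#' `expressed_fpkm` is the separate "gene is expressed" FPKM rule used for
#' mirror coverage, and `expressed_reads_per_nt` the reads/nt rule used by
#' the leave-one-out analysis; the two coexist because different analyses
#' use different units.
#'
#' @param high_fpkm high-expression threshold (strict `>`, default 5).
#' @param low_fpkm low-expression threshold (strict `<`, default 0.3).
#' @param expressed_fpkm expression threshold for mirror coverage
#'   (strict `>`, default 0.3).
#' @param expressed_reads_per_nt expression threshold for leave-one-out
#'   (strict `>`, default 0.01).
#' @param excluded_samples labels of reference samples excluded from the
#'   restriction test.
#' @return a `tra_call_config` list.
#' @export
tra_call_config <- function(high_fpkm = 5, low_fpkm = 0.3,
                            expressed_fpkm = 0.3,
                            expressed_reads_per_nt = 0.01,
                            excluded_samples = character()) {
  stopifnot(high_fpkm > low_fpkm, low_fpkm >= 0)
  structure(
    list(high_fpkm = high_fpkm, low_fpkm = low_fpkm,
         expressed_fpkm = expressed_fpkm,
         expressed_reads_per_nt = expressed_reads_per_nt,
         excluded_samples = excluded_samples),
    class = "tra_call_config"
  )
}

#' Detect tissue-restricted antigen genes
#'
#' A gene belongs to tissue `t`'s TRA set iff its FPKM exceeds
#' `config$high_fpkm` in `t` and is below `config$low_fpkm` in every other
#' non-excluded tissue. Both inequalities are strict. The resulting sets are
#' pairwise disjoint by construction.
#'
#' @param panel an [expression_panel()] with an `fpkm` matrix.
#' @param config a [tra_call_config()].
#' @return named list, tissue label -> character vector of TRA gene ids.
#' @export
detect_tra_genes <- function(panel, config = tra_call_config()) {
  miss <- setdiff(config$excluded_samples, panel$samples)
  if (length(miss) > 0L) {
    stop("excluded sample not in panel: ", paste(miss, collapse = ", "))
  }
  tissues <- setdiff(panel$samples, config$excluded_samples)
  if (length(tissues) < 2L) {
    stop("TRA detection needs at least 2 non-excluded tissues")
  }
  f <- panel$fpkm[, tissues, drop = FALSE]
  high <- f > config$high_fpkm
  not_low <- f >= config$low_fpkm
  out <- lapply(tissues, function(t) {
    others <- setdiff(tissues, t)
    ok <- high[, t] & rowSums(not_low[, others, drop = FALSE]) == 0L
    panel$genes[ok]
  })
  names(out) <- tissues
  out
}

#' Fraction of each tissue's TRA genes expressed in a reference sample
#'
#' For each tissue, the fraction of its TRA genes whose FPKM in the
#' reference sample exceeds `expressed_fpkm` (strict). Tissues with an empty
#' TRA set are reported as `NA` (undefined), not 0.
#'
#' @param tra_sets output of [detect_tra_genes()].
#' @param panel an [expression_panel()].
#' @param reference_sample label of the reference (e.g. mTEC-like) sample.
#' @param expressed_fpkm expression threshold (default 0.3).
#' @return named numeric vector of per-tissue coverage fractions.
#' @export
mirror_coverage <- function(tra_sets, panel, reference_sample,
                            expressed_fpkm = 0.3) {
  if (!reference_sample %in% panel$samples) {
    stop("unknown reference sample: ", reference_sample)
  }
  ref <- panel$fpkm[, reference_sample]
  vapply(tra_sets, function(genes) {
    if (length(genes) == 0L) return(NA_real_)
    mean(ref[genes] > expressed_fpkm)
  }, numeric(1L))
}

#' Leave-one-out tissue-specificity overlap matrix
#'
#' Entry `(t1, t2)` answers: of the genes expressed in `t1` and in no other
#' sample except possibly `t2`, what fraction is actually expressed in `t2`?
#' Formally the numerator is the number of genes expressed in `t1` and `t2`
#' and nowhere else, and the denominator the number of genes expressed in
#' `t1` and in no sample other than possibly `t2`. "Expressed" means
#' length-normalized counts strictly above `threshold`. The matrix is
#' asymmetric by construction (the denominator depends on `t1`); the
#' diagonal and denominator-zero entries are `NA`.
#'
#' Run this on panels already subsampled to equal depth so the threshold is
#' comparable across columns.
#'
#' @param panel an [expression_panel()].
#' @param threshold reads/nt expression threshold (strict `>`, default 0.01).
#' @param samples optional subset/ordering of samples to analyze.
#' @return square numeric matrix with sample labels as dimnames.
#' @export
leave_one_out_matrix <- function(panel, threshold = 0.01, samples = NULL) {
  samples <- samples %||% panel$samples
  e <- panel$reads_per_nt[, samples, drop = FALSE] > threshold
  k <- length(samples)
  m <- matrix(NA_real_, k, k, dimnames = list(samples, samples))
  n_expr <- rowSums(e)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      # genes expressed in t1 and nowhere else but possibly t2
      only_t1 <- e[, i] & (n_expr - e[, j]) == 1L
      denom <- sum(only_t1)
      if (denom == 0L) next
      m[i, j] <- sum(only_t1 & e[, j]) / denom
    }
  }
  m
}
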