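#' Per-site RNA-editing level
#'
#' The editing level of a site in a sample is the fraction of reads covering
#' the site that carry the edited base: `edited / total`. Sites with no
#' covering reads are undefined (`NA`).
#'
#' @param total_reads,edited_reads vectors of covering and edited read
#'   counts (`0 <= edited <= total`).
#' @return numeric vector of levels in `[0, 1]`, `NA` where `total == 0`.
#' @export
editing_level <- function(total_reads, edited_reads) {
  if (any(edited_reads > total_reads)) stop("edited_reads > total_reads")
  if (any(total_reads < 0 | edited_reads < 0)) stop("negative read counts")
  ifelse(total_reads == 0, NA_real_, edited_reads / total_reads)
}

#' Four-way support classification of an editing site
#'
#' The classification behind site-level heat maps: a site with no covering
#' reads is `no_coverage`; with fewer than `min_total` reads it is
#' `low_support`; otherwise it is `well_supported_edited` when at least
#' `min_edited` edited reads are seen and `well_supported_unedited` when not.
#'
#' @inheritParams editing_level
#' @param min_total well-supported coverage floor (default 10).
#' @param min_edited edited-read floor for calling the site edited
#'   (default 1).
#' @return factor with levels `no_coverage`, `low_support`,
#'   `well_supported_unedited`, `well_supported_edited`.
#' @export
site_support_class <- function(total_reads, edited_reads, min_total = 10,
                               min_edited = 1) {
  if (any(edited_reads > total_reads)) stop("edited_reads > total_reads")
  out <- rep("low_support", length(total_reads))
  out[total_reads == 0] <- "no_coverage"
  well <- total_reads >= min_total
  out[well & edited_reads >= min_edited] <- "well_supported_edited"
  out[well & edited_reads < min_edited] <- "well_supported_unedited"
  factor(out, levels = c("no_coverage", "low_support",
                         "well_supported_unedited",
                         "well_supported_edited"))
}

#' Editing rate of one sample over a panel of editable sites
#'
#' The fraction of known editable sites expressed in the sample (at least
#' `min_total` covering reads) at which the edited variant is observed (at
#' least `min_edited` edited reads). Undefined (`NA`) when no site is
#' expressed.
#'
#' Two presets reflect the two thresholds used in different analyses:
#' the global rate uses `min_edited = 1`, while the stringent known-site
#' screen uses `min_edited = 5`.
#'
#' @param pileups data frame with columns `site_key`, `sample`,
#'   `total_reads`, `edited_reads`.
#' @param sample sample label; `NULL` if `pileups` already holds one sample.
#' @param site_whitelist optional character vector of site keys restricting
#'   the editable-site universe.
#' @param min_total coverage floor defining "expressed" (default 1).
#' @param min_edited edited-read floor defining "edited" (default 1).
#' @return a single fraction (or `NA`), with the numerator and denominator
#'   attached as attributes `n_edited` and `n_expressed`.
#' @export
editing_rate <- function(pileups, sample = NULL, site_whitelist = NULL,
                         min_total = 1, min_edited = 1) {
  p <- pileups
  if (!is.null(sample)) p <- p[p$sample == sample, , drop = FALSE]
  if (!is.null(site_whitelist)) {
    p <- p[p$site_key %in% site_whitelist, , drop = FALSE]
  }
  expressed <- p$total_reads >= min_total
  denom <- sum(expressed)
  num <- sum(expressed & p$edited_reads >= min_edited)
  out <- if (denom == 0L) NA_real_ else num / denom
  attr(out, "n_edited") <- num
  attr(out, "n_expressed") <- denom
  out
}

#' Classify a read as hyper-edited from its mismatch profile
#'
#' A read is called hyper-edited when it carries at least `min_mismatches`
#' mismatches and the fraction of them consistent with A-to-I editing --
#' A>G on the plus strand or T>C on the minus strand -- is at least
#' `frac_a2g`. Both thresholds are inclusive and configurable; the
#' A>G-fraction reading of the screen is an interpretation and can be tuned.
#'
#' @param mismatches data frame for one read with columns `ref_base`,
#'   `read_base`, `strand`.
#' @param min_mismatches minimum mismatch count (default 5).
#' @param frac_a2g minimum fraction of editing-consistent mismatches
#'   (default 0.8).
#' @return logical.
#' @export
classify_hyper_read <- function(mismatches, min_mismatches = 5,
                                frac_a2g = 0.8) {
  n <- nrow(mismatches)
  if (n < min_mismatches) return(FALSE)
  a2g <- (mismatches$ref_base == "A" & mismatches$read_base == "G" &
            mismatches$strand == "+") |
    (mismatches$ref_base == "T" & mismatches$read_base == "C" &
       mismatches$strand == "-")
  mean(a2g) >= frac_a2g
}

#' Classify every read in a mismatch-record table
#'
#' @param mismatches data frame with columns `read_id`, `chrom`, `pos`,
#'   `ref_base`, `read_base`, `strand` (one row per mismatch).
#' @inheritParams classify_hyper_read
#' @return data frame with one row per read: `read_id`, `n_mismatches`,
#'   `frac_a2g`, `hyper`.
#' @export
classify_hyper_reads <- function(mismatches, min_mismatches = 5,
                                 frac_a2g = 0.8) {
  a2g <- (mismatches$ref_base == "A" & mismatches$read_base == "G" &
            mismatches$strand == "+") |
    (mismatches$ref_base == "T" & mismatches$read_base == "C" &
       mismatches$strand == "-")
  n <- tapply(a2g, mismatches$read_id, length)
  k <- tapply(a2g, mismatches$read_id, sum)
  ids <- names(n)
  frac <- as.numeric(k) / as.numeric(n)
  data.frame(
    read_id = ids,
    n_mismatches = as.integer(n),
    frac_a2g = frac,
    hyper = as.integer(n) >= min_mismatches & frac >= frac_a2g,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Unique hyper-editing sites from classified reads
#'
#' Counts the distinct `(chrom, pos, strand)` mismatch positions carried by
#' reads classified as hyper-edited.
#'
#' @param mismatches mismatch-record table (see [classify_hyper_reads()]).
#' @param hyper_read_ids ids of reads classified hyper-edited.
#' @return character vector of unique site keys.
#' @export
hyper_edited_sites <- function(mismatches, hyper_read_ids) {
  m <- mismatches[mismatches$read_id %in% hyper_read_ids, , drop = FALSE]
  unique(site_key(m$chrom, m$pos, m$strand))
}

#' Hyper-editing site density
#'
#' Number of unique hyper-editing sites per million aligned reads:
#' `unique_site_count * 1e6 / aligned_reads_total`. This normalization makes
#' samples of different sequencing depth comparable.
#'
#' @param unique_site_count number of distinct hyper-editing sites.
#' @param aligned_reads_total aligned reads in the sample.
#' @return sites per million aligned reads.
#' @export
hyper_editing_density <- function(unique_site_count, aligned_reads_total) {
  if (any(aligned_reads_total <= 0)) stop("aligned_reads_total must be positive")
  unique_site_count * 1e6 / aligned_reads_total
}

# Two-sided Fisher exact p for the 2x2 table [[x11, x12], [x21, x22]],
# via the point-probability rule: the sum of hypergeometric outcomes whose
# probability does not exceed that of the observed table (with the
# conventional 1e-7 relative slack against floating-point ties).
fisher_exact_p <- function(x11, x12, x21, x22) {
  n1 <- x11 + x12
  n2 <- x21 + x22
  if (n1 == 0 || n2 == 0) return(NA_real_)
  k <- x11 + x21
  xs <- max(0, k - n2):min(k, n1)
  probs <- stats::dhyper(xs, n1, n2, k)
  p_obs <- stats::dhyper(x11, n1, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-site Fisher exact comparison of editing between two samples
#'
#' For each site, a two-sided Fisher exact test on the 2x2 table
#' `[[edited_a, unedited_a], [edited_b, unedited_b]]` asks whether the
#' editing level differs between the samples. Sites with zero coverage in
#' either sample are undefined (`NA`) and excluded from the FDR correction.
#' The two-sided p-value follows the point-probability rule (sum of
#' hypergeometric outcomes no more likely than the observed table).
#'
#' @param edited_a,total_a,edited_b,total_b vectors of edited/total read
#'   counts per site in the two samples.
#' @return numeric vector of two-sided p-values (`NA` where undefined).
#' @export
fisher_site_compare <- function(edited_a, total_a, edited_b, total_b) {
  if (any(edited_a > total_a) || any(edited_b > total_b)) {
    stop("edited_reads > total_reads")
  }
  mapply(function(ea, ta, eb, tb) {
    fisher_exact_p(ea, ta - ea, eb, tb - eb)
  }, edited_a, total_a, edited_b, total_b)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate correction. `NA` p-values propagate
#' `NA` and are excluded from the number of tests `m`.
#'
#' @param p_values numeric vector of p-values (may contain `NA`).
#' @return numeric vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Compare editing at many sites between two samples, with FDR
#'
#' Convenience wrapper joining two samples' pileups by site key, running
#' [fisher_site_compare()] per site and [benjamini_hochberg()] across sites.
#'
#' @param pileups pileup table (`site_key`, `sample`, `total_reads`,
#'   `edited_reads`).
#' @param sample_a,sample_b the two sample labels.
#' @param alpha FDR flag threshold (default 0.05, inclusive).
#' @return data frame per site with counts, `level_a`, `level_b`,
#'   `p_value`, `q_value`, `significant`.
#' @export
compare_editing_samples <- function(pileups, sample_a, sample_b,
                                    alpha = 0.05) {
  pa <- pileups[pileups$sample == sample_a, ]
  pb <- pileups[pileups$sample == sample_b, ]
  keys <- union(pa$site_key, pb$site_key)
  ia <- match(keys, pa$site_key)
  ib <- match(keys, pb$site_key)
  ta <- ifelse(is.na(ia), 0L, pa$total_reads[ia])
  ea <- ifelse(is.na(ia), 0L, pa$edited_reads[ia])
  tb <- ifelse(is.na(ib), 0L, pb$total_reads[ib])
  eb <- ifelse(is.na(ib), 0L, pb$edited_reads[ib])
  p <- fisher_site_compare(ea, ta, eb, tb)
  q <- benjamini_hochberg(p)
  data.frame(
    site_key = keys,
    total_a = ta, edited_a = ea, total_b = tb, edited_b = eb,
    level_a = editing_level(ta, ea),
    level_b = editing_level(tb, eb),
    p_value = p,
    q_value = q,
    significant = !is.na(q) & q <= alpha,
    stringsAsFactors = FALSE
  )
}

#' Aggregate editing level over a site panel
#'
#' Total edited reads over total covering reads across all sites of a panel
#' in one sample -- the coverage-weighted mean of per-site levels. Undefined
#' (`NA`) when no read covers any site.
#'
#' @inheritParams editing_rate
#' @return a single fraction or `NA`.
#' @export
aggregate_editing_level <- function(pileups, sample = NULL,
                                    site_whitelist = NULL) {
  p <- pileups
  if (!is.null(sample)) p <- p[p$sample == sample, , drop = FALSE]
  if (!is.null(site_whitelist)) {
    p <- p[p$site_key %in% site_whitelist, , drop = FALSE]
  }
  tot <- sum(p$total_reads)
  if (tot == 0) return(NA_real_)
  sum(p$edited_reads) / tot
}

#' Correlate editing-enzyme expression with editing level across samples
#'
#' Pearson (default) or Spearman correlation of per-sample normalized enzyme
#' counts against per-sample aggregate editing levels. Requires at least
#' three complete pairs; a constant input yields `NA` estimates rather than
#' an error.
#'
#' @param expression per-sample normalized enzyme expression.
#' @param editing per-sample aggregate editing levels.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p_value`, `method`, `n`.
#' @export
correlate_expression_editing <- function(expression, editing,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(expression, editing)
  x <- expression[ok]
  y <- editing[ok]
  if (length(x) < 3L) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_,
                method = method, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(x))
}
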