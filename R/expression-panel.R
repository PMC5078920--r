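#' Multi-sample expression panel
#'
#' Bundles a genes x samples raw count matrix with its gene models and the
#' per-sample aligned-read totals, and derives the two normalized views used
#' throughout the analysis:
#'
#' * `reads_per_nt` -- raw count divided by the gene's exonic length; the unit
#'   of the expressed-gene detection threshold (default 0.01 reads/nt).
#' * `fpkm` -- fragments per kilobase per million aligned reads, computed with
#'   the reference formula `count * 1e9 / (aligned_total * exonic_length)`.
#'   If an externally computed FPKM matrix is supplied (e.g. from a dedicated
#'   quantifier) it is accepted verbatim instead.
#'
#' The aligned-read total is a separate field rather than the column sum
#' because reads aligning outside the gene panel (intergenic, non-coding)
#' still count toward sequencing depth.
#'
#' @param counts integer-like matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample labels).
#' @param models a [gene_models()] table covering every row of `counts`.
#' @param aligned_reads_total named numeric vector of per-sample aligned read
#'   totals; defaults to the column sums of `counts`.
#' @param fpkm optional externally computed FPKM matrix with the same
#'   dimnames as `counts`.
#'
#' @return An `expression_panel` list with elements `counts`, `models`,
#'   `aligned_reads_total`, `reads_per_nt`, `fpkm`, `samples`, `genes`.
#' @export
expression_panel <- function(counts, models, aligned_reads_total = NULL,
                             fpkm = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (any(counts < 0)) stop("negative counts")
  lens <- exonic_lengths(models, rownames(counts))
  if (is.null(aligned_reads_total)) {
    aligned_reads_total <- colSums(counts)
  }
  aligned_reads_total <- aligned_reads_total[colnames(counts)]
  if (anyNA(aligned_reads_total)) {
    stop("aligned_reads_total missing for some samples")
  }
  if (any(colSums(counts) > aligned_reads_total + 1e-8)) {
    stop("per-sample count sum exceeds aligned_reads_total")
  }
  if (is.null(fpkm)) {
    fpkm <- compute_fpkm(counts, models, aligned_reads_total)
  } else {
    fpkm <- as.matrix(fpkm)[rownames(counts), colnames(counts), drop = FALSE]
  }
  structure(
    list(
      counts = counts,
      models = models,
      aligned_reads_total = aligned_reads_total,
      reads_per_nt = compute_reads_per_nt(counts, models),
      fpkm = fpkm,
      samples = colnames(counts),
      genes = rownames(counts)
    ),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' Length-normalized expression (reads per nucleotide)
#'
#' Divides each gene's raw count by its exonic length. Zero counts map to
#' zero; a gene without a model is an error naming the gene.
#'
#' @param counts genes x samples count matrix (gene ids as rownames) or a
#'   named numeric vector for a single sample.
#' @param models a [gene_models()] table.
#' @return matrix (or vector) of reads-per-nucleotide values.
#' @export
compute_reads_per_nt <- function(counts, models) {
  if (is.null(dim(counts))) {
    lens <- exonic_lengths(models, names(counts))
    return(counts / lens)
  }
  lens <- exonic_lengths(models, rownames(counts))
  counts / lens
}

#' Reference FPKM
#'
#' `count * 1e9 / (aligned_total * exonic_length)`. Used by the synthetic
#' generator and as a fallback when no external FPKM table is given;
#' externally quantified FPKM values can be attached to a panel verbatim.
#'
#' @inheritParams compute_reads_per_nt
#' @param aligned_reads_total named per-sample aligned read totals.
#' @return FPKM matrix with the dimnames of `counts`.
#' @export
compute_fpkm <- function(counts, models, aligned_reads_total) {
  lens <- exonic_lengths(models, rownames(counts))
  tot <- aligned_reads_total[colnames(counts)]
  if (any(tot <= 0)) stop("aligned_reads_total must be positive")
  sweep(counts / lens, 2L, tot, "/") * 1e9
}
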