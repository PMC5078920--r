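#' Gene models
#'
#' A gene model records the identity, location and exon structure of one gene.
#' The exonic length -- the length of the union of all exon intervals -- is the
#' denominator of both the reads-per-nucleotide normalization and the reference
#' FPKM formula, so it is computed once here and carried along.
#'
#' All coordinates are 0-based, half-open. Conversion to the 1-based formats
#' used on disk (BED-like site tables, STAR junction tables) happens only in
#' the I/O layer.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param strand character vector, `"+"` or `"-"`.
#' @param exons list of two-column matrices (`start`, `end`), one per gene,
#'   holding 0-based half-open exon intervals.
#'
#' @return A `gene_models` data frame with columns `gene_id`, `chrom`,
#'   `strand`, `n_exons`, `exonic_length`, `span_start`, `span_end` and a
#'   list-column `exons`.
#' @export
gene_models <- function(gene_id, chrom, strand, exons) {
  n <- length(gene_id)
  stopifnot(length(chrom) == n, length(strand) == n, length(exons) == n)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  exons <- lapply(exons, function(e) {
    e <- matrix(as.integer(e), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    if (nrow(e) == 0L) stop("gene model with no exons")
    if (any(e[, 2L] <= e[, 1L])) stop("exon with non-positive length")
    e[order(e[, 1L]), , drop = FALSE]
  })
  exonic_length <- vapply(
    exons, function(e) interval_union_length(e[, 1L], e[, 2L]), integer(1L)
  )
  if (any(exonic_length <= 0L)) stop("gene with exonic_length <= 0")
  out <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    n_exons = vapply(exons, nrow, integer(1L)),
    exonic_length = exonic_length,
    span_start = vapply(exons, function(e) min(e[, 1L]), integer(1L)),
    span_end = vapply(exons, function(e) max(e[, 2L]), integer(1L)),
    stringsAsFactors = FALSE
  )
  out$exons <- exons
  rownames(out) <- out$gene_id
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Exonic lengths for a set of genes
#'
#' @param models a [gene_models()] table.
#' @param gene_id genes to look up; errors (naming the gene) on any id without
#'   a model.
#' @return named integer vector of union-of-exons lengths.
#' @export
exonic_lengths <- function(models, gene_id) {
  miss <- setdiff(gene_id, models$gene_id)
  if (length(miss) > 0L) {
    stop("no gene model for gene_id: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  stats::setNames(models[gene_id, "exonic_length"], gene_id)
}
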