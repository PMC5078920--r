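# Format readers and writers.  Package-internal junction coordinates are
# 0-based half-open; the STAR SJ.out.tab dialect on disk is 1-based inclusive
# intron coordinates, and the conversion happens here and only here.  Editing
# site tables carry 1-based positions both on disk and in memory (they are
# single bases; no half-open arithmetic applies).

#' Read a STAR-style splice junction table
#'
#' Parses the 9-column `SJ.out.tab` dialect: chrom, intron start (1-based),
#' intron end (1-based inclusive), strand code (0 undefined / 1 plus /
#' 2 minus), intron motif, annotation flag, unique-mapping read count,
#' multi-mapping read count, maximum overhang. Coordinates are converted to
#' the package's 0-based half-open convention. Malformed rows are an error
#' naming the line number.
#'
#' @param path file path.
#' @param sample sample label attached to every junction.
#' @return data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `strand`, `motif`, `annotated`, `unique_reads`, `multi_reads`,
#'   `max_overhang`.
#' @export
read_sj_tab <- function(path, sample = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), motif = integer(0),
                      annotated = integer(0), unique_reads = integer(0),
                      multi_reads = integer(0), max_overhang = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed SJ record at line %d of %s: expected 9 fields, got %d",
                 bad[1L], path, lengths(parts)[bad[1L]]))
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.integer))
  num <- matrix(num, ncol = 8L)
  if (anyNA(num)) {
    stop(sprintf("malformed SJ record at line %d of %s: non-integer field",
                 which(rowSums(is.na(num)) > 0L)[1L], path))
  }
  strand_code <- num[, 3L]
  if (!all(strand_code %in% 0:2)) {
    stop(sprintf("malformed SJ record at line %d of %s: strand code not in 0..2",
                 which(!strand_code %in% 0:2)[1L], path))
  }
  data.frame(
    sample = sample,
    chrom = m[, 1L],
    start = num[, 1L] - 1L,   # 1-based inclusive -> 0-based half-open
    end = num[, 2L],
    strand = c("*", "+", "-")[strand_code + 1L],
    motif = num[, 4L],
    annotated = num[, 5L],
    unique_reads = num[, 6L],
    multi_reads = num[, 7L],
    max_overhang = num[, 8L],
    stringsAsFactors = FALSE
  )
}

#' Write a STAR-style splice junction table
#'
#' Inverse of [read_sj_tab()]; converts the internal 0-based half-open
#' intron coordinates back to the 1-based inclusive dialect.
#'
#' @param junctions junction table for one sample.
#' @param path output path.
#' @export
write_sj_tab <- function(junctions, path) {
  strand_code <- match(junctions$strand, c("*", "+", "-")) - 1L
  lines <- sprintf(
    "%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
    junctions$chrom,
    junctions$start + 1L,
    junctions$end,
    strand_code,
    junctions$motif %||% rep(0L, nrow(junctions)),
    junctions$annotated %||% rep(0L, nrow(junctions)),
    junctions$unique_reads,
    junctions$multi_reads %||% rep(0L, nrow(junctions)),
    junctions$max_overhang %||% rep(50L, nrow(junctions))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-level count table
#'
#' Tab-separated with header: `gene_id`, `length`, then one column per
#' sample. Duplicate gene ids are an error.
#'
#' @param path file path.
#' @return list with `counts` (matrix), `lengths` (named vector) and
#'   `samples`.
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length") %in% names(d))) {
    stop("counts table must have 'gene_id' and 'length' columns: ", path)
  }
  if (anyDuplicated(d$gene_id)) {
    stop("duplicate gene_id in ", path, ": ",
         d$gene_id[duplicated(d$gene_id)][1L])
  }
  samples <- setdiff(names(d), c("gene_id", "length"))
  counts <- as.matrix(d[, samples, drop = FALSE])
  rownames(counts) <- d$gene_id
  list(counts = counts,
       lengths = stats::setNames(as.integer(d$length), d$gene_id),
       samples = samples)
}

#' Write a gene-level count table
#'
#' @param counts genes x samples matrix.
#' @param lengths named per-gene exonic lengths.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, lengths, path) {
  d <- data.frame(gene_id = rownames(counts),
                  length = as.integer(lengths[rownames(counts)]),
                  counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an editing-site annotation table
#'
#' BED-like tab-separated file with header columns `chrom`, `pos` (1-based
#' site position), `strand`, `ref_base`, `alt_base`, `edit_type`
#' (`A2I`/`C2U`) and `effect`. Duplicate sites are an error. The A2I type
#' must carry reference base A (on the annotated strand) and C2U reference
#' base C.
#'
#' @param path file path.
#' @return site annotation data frame with a derived `site_key` column.
#' @export
read_sites_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "ref_base", "alt_base",
            "edit_type", "effect")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) stop("site table lacks columns: ",
                              paste(miss, collapse = ", "))
  if (!all(d$edit_type %in% c("A2I", "C2U"))) {
    stop("edit_type must be A2I or C2U")
  }
  bad <- (d$edit_type == "A2I" & d$ref_base != "A") |
    (d$edit_type == "C2U" & d$ref_base != "C")
  if (any(bad)) {
    stop("edit_type inconsistent with ref_base at ",
         site_key(d$chrom[bad][1L], d$pos[bad][1L], d$strand[bad][1L]))
  }
  d$site_key <- site_key(d$chrom, d$pos, d$strand)
  if (anyDuplicated(d$site_key)) {
    stop("duplicate editing site in ", path, ": ",
         d$site_key[duplicated(d$site_key)][1L])
  }
  d
}

#' Write an editing-site annotation table
#'
#' @param sites site annotation data frame (see [read_sites_tsv()]).
#' @param path output path.
#' @export
write_sites_tsv <- function(sites, path) {
  cols <- c("chrom", "pos", "strand", "ref_base", "alt_base",
            "edit_type", "effect")
  utils::write.table(sites[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-site pileup table
#'
#' Tab-separated with header columns `site_key`, `sample`, `total_reads`,
#' `edited_reads`. Duplicate (site, sample) pairs and edited counts
#' exceeding totals are errors.
#'
#' @param path file path.
#' @return pileup data frame.
#' @export
read_pileups_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("site_key", "sample", "total_reads", "edited_reads")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) stop("pileup table lacks columns: ",
                              paste(miss, collapse = ", "))
  key <- paste(d$site_key, d$sample)
  if (anyDuplicated(key)) {
    stop("duplicate (site, sample) pileup in ", path, ": ",
         key[duplicated(key)][1L])
  }
  if (any(d$edited_reads > d$total_reads)) {
    stop("edited_reads > total_reads in ", path)
  }
  d
}

#' Write a per-site pileup table
#'
#' @param pileups pileup data frame.
#' @param path output path.
#' @export
write_pileups_tsv <- function(pileups, path) {
  cols <- c("site_key", "sample", "total_reads", "edited_reads")
  utils::write.table(pileups[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the synthetic ground truth as JSON
#'
#' @param truth a `synthetic_truth` list.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    tra_assignment = truth$tra_assignment,
    mirrored_genes = truth$mirrored_genes,
    housekeeping_genes = truth$housekeeping_genes,
    restricted_junctions = truth$restricted_junctions,
    true_editing_levels = truth$true_editing_levels,
    hyper_edited_read_ids = truth$hyper_edited_read_ids
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON written by [write_truth_json()]
#'
#' @param path file path.
#' @return a `synthetic_truth`-like list (the editing-level matrix comes
#'   back without dimnames preserved beyond row/column order).
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "synthetic_truth")
}

#' Write a full synthetic dataset to a directory
#'
#' Emits `counts.tsv`, one `SJ.<sample>.tab` per sample, `sites.tsv`,
#' `pileups.tsv`, `mismatches.tsv`, `reads.tsv` and `truth.json`.
#'
#' @param dataset output of [generate_synthetic_dataset()].
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_counts_tsv(dataset$panel$counts,
                   stats::setNames(dataset$panel$models$exonic_length,
                                   dataset$panel$models$gene_id),
                   file.path(outdir, "counts.tsv"))
  for (s in dataset$panel$samples) {
    j <- dataset$junctions[dataset$junctions$sample == s, ]
    write_sj_tab(j, file.path(outdir, sprintf("SJ.%s.tab", s)))
  }
  write_sites_tsv(dataset$sites, file.path(outdir, "sites.tsv"))
  write_pileups_tsv(dataset$pileups, file.path(outdir, "pileups.tsv"))
  utils::write.table(dataset$mismatches, file.path(outdir, "mismatches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$reads, file.path(outdir, "reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth_json(dataset$truth, file.path(outdir, "truth.json"))
  invisible(outdir)
}
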