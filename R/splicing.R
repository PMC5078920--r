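#' Assign splice junctions to genes
#'
#' A junction is assigned to a gene iff both flanking exonic bases (the base
#' immediately before the intron start and the base immediately after the
#' intron end) lie within the gene's span and the strands are compatible
#' (a junction with undefined strand `"*"` matches either gene strand).
#' When a junction is contained in several overlapping genes the tie is
#' broken towards the gene with the longer span ("longer containment"),
#' then towards the lexicographically smaller `gene_id`. Junctions contained
#' in no gene are retained with `gene_id = NA`.
#'
#' @param junctions data frame with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open intron interval), `strand` (`"+"`, `"-"` or
#'   `"*"`), `unique_reads`.
#' @param models a [gene_models()] table.
#' @return the junction table with `gene_id` and `key` columns added
#'   (class `junction_panel`).
#' @export
assign_junctions_to_genes <- function(junctions, models) {
  need <- c("sample", "chrom", "start", "end", "strand", "unique_reads")
  miss <- setdiff(need, names(junctions))
  if (length(miss) > 0L) stop("junction table lacks columns: ",
                              paste(miss, collapse = ", "))
  if (nrow(junctions) > 0L && any(junctions$start >= junctions$end)) {
    stop("junction with intron_start >= intron_end")
  }
  if (nrow(junctions) == 0L) {
    junctions$key <- character(0)
    junctions$gene_id <- character(0)
    class(junctions) <- c("junction_panel", "data.frame")
    return(junctions)
  }
  junctions$key <- junction_key(junctions$chrom, junctions$start,
                                junctions$end, junctions$strand)
  uj <- junctions[!duplicated(junctions$key),
                  c("key", "chrom", "start", "end", "strand")]
  uj$gene_id <- NA_character_
  span_w <- models$span_end - models$span_start
  for (ch in unique(uj$chrom)) {
    qi <- which(uj$chrom == ch)
    si <- which(models$chrom == ch)
    if (length(si) == 0L) next
    # flanking bases: start-1 and end (0-based); as a 1-based closed interval
    # the junction plus flanks is [start, end + 1]
    q <- IRanges::IRanges(start = uj$start[qi], end = uj$end[qi] + 1L)
    s <- IRanges::IRanges(start = models$span_start[si] + 1L,
                          end = models$span_end[si])
    hits <- IRanges::findOverlaps(q, s, type = "within")
    if (length(hits) == 0L) next
    qh <- IRanges::from(hits)
    sh <- IRanges::to(hits)
    jstrand <- uj$strand[qi][qh]
    gstrand <- models$strand[si][sh]
    ok <- jstrand == "*" | jstrand == gstrand
    qh <- qh[ok]
    sh <- sh[ok]
    if (length(qh) == 0L) next
    cand <- data.frame(
      j = qh,
      gene_id = models$gene_id[si][sh],
      width = span_w[si][sh],
      stringsAsFactors = FALSE
    )
    # longer containment first, then lexicographically smaller id
    cand <- cand[order(cand$j, -cand$width, cand$gene_id), ]
    cand <- cand[!duplicated(cand$j), ]
    uj$gene_id[qi[cand$j]] <- cand$gene_id
  }
  junctions$gene_id <- uj$gene_id[match(junctions$key, uj$key)]
  class(junctions) <- c("junction_panel", "data.frame")
  junctions
}

#' Detect alternatively spliced genes in one sample
#'
#' A gene is flagged alternatively spliced iff, among its junctions with at
#' least `min_reads` supporting unique reads in the sample, two distinct
#' junctions share an intron start or share an intron end (alternative
#' donor/acceptor usage).
#'
#' @param junction_panel output of [assign_junctions_to_genes()].
#' @param sample sample label.
#' @param min_reads minimum unique-read support for a junction to count as
#'   detected (default 1).
#' @return character vector of AS gene ids.
#' @export
detect_as_genes <- function(junction_panel, sample, min_reads = 1) {
  j <- junction_panel[junction_panel$sample == sample &
                        junction_panel$unique_reads >= min_reads &
                        !is.na(junction_panel$gene_id), , drop = FALSE]
  if (nrow(j) == 0L) return(character(0))
  j <- j[!duplicated(j$key), ]
  shared_start <- j$gene_id[duplicated(paste(j$gene_id, j$chrom, j$start))]
  shared_end <- j$gene_id[duplicated(paste(j$gene_id, j$chrom, j$end))]
  sort(unique(c(shared_start, shared_end)))
}

#' Fraction of alternatively spliced genes by expression quartile
#'
#' Restricts to multi-exon genes expressed in the sample (the denominator of
#' the AS rate), bins them into expression quartiles, and reports the
#' fraction of AS genes in each bin.
#'
#' @param junction_panel output of [assign_junctions_to_genes()].
#' @param expression_panel an [expression_panel()].
#' @param sample sample label.
#' @param threshold reads/nt expression threshold (inclusive, default 0.01).
#' @param min_reads junction detection support (default 1).
#' @return data frame with columns `quartile`, `n_genes`, `n_as`, `fraction`.
#' @export
as_fraction_by_quartile <- function(junction_panel, expression_panel, sample,
                                    threshold = 0.01, min_reads = 1) {
  multi <- expression_panel$models$gene_id[expression_panel$models$n_exons >= 2L]
  q <- expression_quartiles(expression_panel, sample, threshold,
                            genes = multi)
  as_genes <- detect_as_genes(junction_panel, sample, min_reads)
  lev <- paste0("Q", 1:4)
  n_genes <- as.integer(table(q)[lev])
  n_as <- as.integer(table(factor(q[names(q) %in% as_genes], levels = lev))[lev])
  data.frame(
    quartile = lev,
    n_genes = n_genes,
    n_as = n_as,
    fraction = ifelse(n_genes > 0L, n_as / n_genes, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Compare junctions-per-gene between two samples
#'
#' For genes expressed in both samples, counts the junctions detected per
#' gene in each, and partitions genes by whether the counts differ by more
#' than `big_difference` (the "many more junctions in one sample" flag).
#'
#' @param junction_panel output of [assign_junctions_to_genes()].
#' @param expression_panel an [expression_panel()].
#' @param sample_a,sample_b sample labels.
#' @param big_difference difference considered large (default 5, strict `>`).
#' @param threshold reads/nt expression threshold (inclusive, default 0.01).
#' @param min_reads junction detection support (default 1).
#' @return data frame with columns `gene_id`, `n_a`, `n_b`, `class`
#'   (`"a_higher"`, `"b_higher"`, `"within"`); the partition sizes are in
#'   `attr(, "summary")`.
#' @export
junctions_per_gene_compare <- function(junction_panel, expression_panel,
                                       sample_a, sample_b,
                                       big_difference = 5,
                                       threshold = 0.01, min_reads = 1) {
  rpn <- expression_panel$reads_per_nt
  genes <- expression_panel$genes[rpn[, sample_a] >= threshold &
                                    rpn[, sample_b] >= threshold]
  count_one <- function(s) {
    j <- junction_panel[junction_panel$sample == s &
                          junction_panel$unique_reads >= min_reads &
                          !is.na(junction_panel$gene_id), , drop = FALSE]
    j <- j[!duplicated(j$key), ]
    tab <- table(j$gene_id)
    n <- integer(length(genes))
    names(n) <- genes
    hit <- intersect(genes, names(tab))
    n[hit] <- as.integer(tab[hit])
    n
  }
  n_a <- count_one(sample_a)
  n_b <- count_one(sample_b)
  cls <- rep("within", length(genes))
  cls[n_a - n_b > big_difference] <- "a_higher"
  cls[n_b - n_a > big_difference] <- "b_higher"
  out <- data.frame(gene_id = genes, n_a = unname(n_a), n_b = unname(n_b),
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    a_higher = sum(cls == "a_higher"),
    b_higher = sum(cls == "b_higher"),
    within = sum(cls == "within")
  )
  out
}

#' Detect tissue-restricted splice junctions
#'
#' A junction is a TRA junction of tissue `t` iff it has at least `support`
#' unique reads in `t`, at most `max_other_reads` (default 0) in every other
#' non-excluded tissue, is assigned to a gene, and that gene is expressed
#' (FPKM strictly above `expressed_fpkm`) in at least one non-excluded
#' tissue other than `t` -- i.e. the restriction is at the isoform level,
#' inside a gene that is itself shared. Reference samples named in
#' `excluded_samples` take no part in the restriction test. Junctions with
#' no gene assignment are silently ineligible.
#'
#' @param junction_panel output of [assign_junctions_to_genes()].
#' @param expression_panel an [expression_panel()].
#' @param support minimum unique reads in the home tissue (default 10,
#'   inclusive).
#' @param excluded_samples reference sample labels.
#' @param max_other_reads maximum unique reads tolerated in any other
#'   non-excluded tissue (default 0).
#' @param expressed_fpkm host-gene expression threshold (default 0.3).
#' @return named list, tissue -> character vector of junction keys.
#' @export
detect_tra_junctions <- function(junction_panel, expression_panel,
                                 support = 10,
                                 excluded_samples = character(),
                                 max_other_reads = 0,
                                 expressed_fpkm = 0.3) {
  tissues <- setdiff(expression_panel$samples, excluded_samples)
  if (length(tissues) < 2L) {
    stop("TRA junction detection needs at least 2 non-excluded tissues")
  }
  j <- junction_panel[junction_panel$sample %in% tissues, , drop = FALSE]
  keys <- unique(j$key)
  reads <- matrix(0, length(keys), length(tissues),
                  dimnames = list(keys, tissues))
  # ascending assignment order makes the last (largest) value win on
  # duplicate (key, sample) rows
  o <- order(j$unique_reads)
  reads[cbind(match(j$key[o], keys), match(j$sample[o], tissues))] <-
    j$unique_reads[o]
  gene_of <- junction_panel$gene_id[match(keys, junction_panel$key)]
  fpkm <- expression_panel$fpkm
  out <- lapply(tissues, function(t) {
    others <- setdiff(tissues, t)
    restricted <- reads[, t] >= support &
      rowSums(reads[, others, drop = FALSE] > max_other_reads) == 0L
    restricted <- restricted & !is.na(gene_of)
    if (!any(restricted)) return(character(0))
    host <- gene_of[restricted]
    host_shared <- rowSums(
      fpkm[host, others, drop = FALSE] > expressed_fpkm) >= 1L
    keys[restricted][host_shared]
  })
  names(out) <- tissues
  out
}

#' Coverage of tissue-restricted junctions in a reference sample
#'
#' For each tissue, the fraction of its TRA junctions detected (at least
#' `min_reads` unique reads) in the reference sample. Tissues with no TRA
#' junctions are `NA`.
#'
#' @param tra_junction_sets output of [detect_tra_junctions()].
#' @param junction_panel output of [assign_junctions_to_genes()].
#' @param reference_sample reference sample label.
#' @param min_reads detection support in the reference (default 1).
#' @return named numeric vector of per-tissue coverage fractions.
#' @export
tra_junction_coverage <- function(tra_junction_sets, junction_panel,
                                  reference_sample, min_reads = 1) {
  ref <- junction_panel[junction_panel$sample == reference_sample &
                          junction_panel$unique_reads >= min_reads, ]
  ref_keys <- unique(ref$key)
  vapply(tra_junction_sets, function(keys) {
    if (length(keys) == 0L) return(NA_real_)
    mean(keys %in% ref_keys)
  }, numeric(1L))
}

#' Compare TRA-junction coverage between two reference samples
#'
#' Per tissue, tests whether the fraction of TRA junctions covered differs
#' between two reference samples, with a two-sided Fisher exact test on the
#' 2x2 table of covered/uncovered junctions. Tissues with no TRA junctions
#' yield `NA`.
#'
#' @inheritParams tra_junction_coverage
#' @param ref_a,ref_b the two reference sample labels.
#' @param alpha significance flag threshold (default 0.05, inclusive).
#' @return data frame with per-tissue covered counts, set size, `p_value`
#'   and `significant`.
#' @export
compare_coverage_two_references <- function(tra_junction_sets, junction_panel,
                                            ref_a, ref_b, min_reads = 1,
                                            alpha = 0.05) {
  keys_in <- function(s) {
    r <- junction_panel[junction_panel$sample == s &
                          junction_panel$unique_reads >= min_reads, ]
    unique(r$key)
  }
  ka <- keys_in(ref_a)
  kb <- keys_in(ref_b)
  rows <- lapply(names(tra_junction_sets), function(t) {
    keys <- tra_junction_sets[[t]]
    n <- length(keys)
    if (n == 0L) {
      return(data.frame(tissue = t, n_tra_junctions = 0L,
                        covered_a = NA_integer_, covered_b = NA_integer_,
                        p_value = NA_real_, significant = NA,
                        stringsAsFactors = FALSE))
    }
    ca <- sum(keys %in% ka)
    cb <- sum(keys %in% kb)
    p <- fisher_exact_p(ca, n - ca, cb, n - cb)
    data.frame(tissue = t, n_tra_junctions = n,
               covered_a = ca, covered_b = cb,
               p_value = p, significant = !is.na(p) & p <= alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
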