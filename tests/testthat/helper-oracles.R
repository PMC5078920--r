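# Independent brute-force oracles and small fixture builders.  The oracles
# deliberately use naive set enumeration / double loops so they share no code
# path with the package implementations they check.

# single-exon gene models with given lengths, laid end to end
toy_models <- function(lengths, chrom = "chr1", strand = NULL) {
  n <- length(lengths)
  ids <- names(lengths) %||% sprintf("g%03d", seq_len(n))
  if (is.null(strand)) strand <- rep("+", n)
  pos <- 0L
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    exons[[i]] <- matrix(c(pos, pos + lengths[i]), 1L)
    pos <- pos + lengths[i] + 1000L
  }
  gene_models(ids, rep(chrom, n), strand, exons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random FPKM panel for oracle-equivalence trials
random_fpkm_panel <- function(n_genes, tissues, seed) {
  set.seed(seed)
  # mixture spanning the three FPKM bands so TRA patterns actually occur
  f <- matrix(
    sample(c(0, 0.1, 0.2, 0.4, 2, 6, 20), n_genes * length(tissues),
           replace = TRUE,
           prob = c(0.35, 0.1, 0.1, 0.15, 0.1, 0.1, 0.1)),
    n_genes, length(tissues),
    dimnames = list(sprintf("g%04d", seq_len(n_genes)), tissues)
  )
  f
}

# brute-force TRA detection: explicit double loop over genes x tissues
brute_tra <- function(fpkm, high = 5, low = 0.3) {
  tissues <- colnames(fpkm)
  out <- lapply(tissues, function(t) {
    hits <- character(0)
    for (g in rownames(fpkm)) {
      if (fpkm[g, t] <= high) next
      ok <- TRUE
      for (t2 in setdiff(tissues, t)) {
        if (fpkm[g, t2] >= low) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, g)
    }
    hits
  })
  names(out) <- tissues
  out
}

# brute-force leave-one-out matrix from a logical expressed matrix
brute_loo <- function(expressed) {
  s <- colnames(expressed)
  k <- length(s)
  m <- matrix(NA_real_, k, k, dimnames = list(s, s))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      denom <- 0L; num <- 0L
      for (g in seq_len(nrow(expressed))) {
        others <- setdiff(seq_len(k), c(i, j))
        if (expressed[g, i] && !any(expressed[g, others])) {
          denom <- denom + 1L
          if (expressed[g, j]) num <- num + 1L
        }
      }
      if (denom > 0L) m[i, j] <- num / denom
    }
  }
  m
}

# brute-force AS call: pairwise junction comparison per gene
brute_as_genes <- function(junctions, sample, min_reads = 1) {
  j <- junctions[junctions$sample == sample &
                   junctions$unique_reads >= min_reads &
                   !is.na(junctions$gene_id), ]
  j <- j[!duplicated(j[, c("chrom", "start", "end", "strand")]), ]
  hits <- character(0)
  for (g in unique(j$gene_id)) {
    jg <- j[j$gene_id == g, ]
    if (nrow(jg) < 2L) next
    found <- FALSE
    for (a in seq_len(nrow(jg) - 1L)) {
      for (b in (a + 1L):nrow(jg)) {
        if (jg$start[a] == jg$start[b] || jg$end[a] == jg$end[b]) {
          found <- TRUE
        }
      }
    }
    if (found) hits <- c(hits, g)
  }
  sort(hits)
}

# brute-force two-sided Fisher exact p via explicit table enumeration with
# closed-form hypergeometric probabilities (lchoose, not dhyper)
brute_fisher <- function(x11, x12, x21, x22) {
  n1 <- x11 + x12; n2 <- x21 + x22; k <- x11 + x21
  if (n1 == 0 || n2 == 0) return(NA_real_)
  xs <- max(0, k - n2):min(k, n1)
  lp <- lchoose(n1, xs) + lchoose(n2, k - xs) - lchoose(n1 + n2, k)
  probs <- exp(lp)
  p_obs <- exp(lchoose(n1, x11) + lchoose(n2, k - x11) - lchoose(n1 + n2, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# step-up BH from the definition: q_(i) = min_{j >= i} min(1, m p_(j) / j)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# tiny junction table builder (internal 0-based half-open coordinates)
jtab <- function(sample, chrom, start, end, strand = "+", unique_reads = 10) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             strand = strand, unique_reads = unique_reads,
             stringsAsFactors = FALSE)
}
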