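#' Configuration of the synthetic multi-tissue panel
#'
#' Describes a panel of single-sample tissues plus one mTEC-like reference
#' sample, with planted ground truth for every analysis: housekeeping genes
#' highly expressed everywhere, per-tissue TRA genes, a configurable fraction
#' of each tissue's TRAs mirrored into the reference, tissue-restricted
#' splice junctions (a fraction of which is mirrored too), binomially sampled
#' editing pileups, and hyper-edited read mismatch records.
#'
#' Counts are drawn negative-binomially and then clamped so the planted FPKM
#' threshold relations (`> 5` in the home tissue, `< 0.3` elsewhere,
#' `> 0.3` for mirrored/housekeeping/background genes) hold deterministically
#' rather than merely in expectation, so recovery tests have exact ground
#' truth. One sample per tissue; the per-sample aligned-read total is
#' `library_size` (gene counts sum to less -- reads also align outside the
#' gene panel).
#'
#' @param n_tissues number of peripheral tissues.
#' @param n_genes genes in the panel.
#' @param frac_housekeeping fraction of genes highly expressed in every
#'   sample.
#' @param tra_per_tissue planted TRA genes per tissue.
#' @param mirror_fraction fraction of each tissue's TRAs expressed in the
#'   reference sample (the first `ceiling(mirror_fraction * tra_per_tissue)`
#'   of each tissue's block).
#' @param library_size aligned reads per sample.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param gene_length_range exonic-length interval (nt), sampled uniformly.
#' @param junctions_per_gene_range junctions per gene (so exons per gene is
#'   this plus one); minimum must be >= 1 so every gene can carry junctions.
#' @param restricted_junctions_per_tissue planted tissue-restricted junctions
#'   per tissue (hosted in housekeeping genes, which are expressed in every
#'   tissue).
#' @param junction_mirror_fraction fraction of each tissue's restricted
#'   junctions also planted into the reference sample.
#' @param junction_support_range unique-read support for ordinary (shared)
#'   junctions.
#' @param restricted_support_range support for restricted junctions in their
#'   home tissue; keep the minimum at or above the downstream detection
#'   threshold (10).
#' @param n_editing_sites annotated editing sites.
#' @param frac_a2i fraction of sites that are A-to-I (the rest are C-to-U).
#' @param editing_level_distribution list with `prop_edited` (fraction of
#'   sites with nonzero true level) and either `fixed_level` or Beta
#'   parameters `shape1`, `shape2` for the nonzero levels.
#' @param coverage_distribution list with `mean` and `size` of the
#'   negative-binomial per-site read coverage.
#' @param n_hyper_reads planted hyper-edited reads.
#' @param n_background_reads background reads constructed to violate the
#'   hyper-read thresholds.
#' @param reference_label name of the mTEC-like reference sample.
#' @param seed integer seed; the whole dataset is deterministic given the
#'   config.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_tissues = 5,
                             n_genes = 5000,
                             frac_housekeeping = 0.1,
                             tra_per_tissue = 40,
                             mirror_fraction = 0.6,
                             library_size = 5e6,
                             nb_dispersion = 0.15,
                             gene_length_range = c(1000, 5000),
                             junctions_per_gene_range = c(2, 8),
                             restricted_junctions_per_tissue = 20,
                             junction_mirror_fraction = 0.4,
                             junction_support_range = c(5, 50),
                             restricted_support_range = c(10, 50),
                             n_editing_sites = 500,
                             frac_a2i = 0.8,
                             editing_level_distribution =
                               list(prop_edited = 0.3, shape1 = 1.5, shape2 = 4),
                             coverage_distribution = list(mean = 60, size = 3),
                             n_hyper_reads = 100,
                             n_background_reads = 900,
                             reference_label = "mTEC_like",
                             seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_tissues", "n_genes", "tra_per_tissue",
              "restricted_junctions_per_tissue", "n_editing_sites",
              "n_hyper_reads", "n_background_reads")
  for (f in counts) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  for (f in c("frac_housekeeping", "mirror_fraction",
              "junction_mirror_fraction", "frac_a2i")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (frac_housekeeping + n_tissues * tra_per_tissue / n_genes > 1) {
    stop("frac_housekeeping plus the TRA fraction exceeds 1: ",
         "reduce n_tissues, tra_per_tissue or frac_housekeeping")
  }
  if (n_tissues < 2) stop("n_tissues must be >= 2")
  if (junctions_per_gene_range[1] < 1) {
    stop("junctions_per_gene_range minimum must be >= 1 ",
         "(a gene needs >= 2 exons to carry a junction)")
  }
  n_hk <- round(frac_housekeeping * n_genes)
  if (restricted_junctions_per_tissue * n_tissues > n_hk) {
    stop("not enough housekeeping genes to host ",
         "restricted_junctions_per_tissue restricted junctions per tissue")
  }
  if (library_size <= 0) stop("library_size must be positive")
  # the low-FPKM band must contain at least the zero count, and the high
  # band must be reachable within the library
  max_len <- gene_length_range[2]
  if (floor(5 * library_size * max_len / 1e9) + 1 > library_size / 10) {
    stop("library_size too small to reach FPKM > 5 for genes of length ",
         max_len)
  }
  cfg$n_housekeeping <- n_hk
  structure(cfg, class = "synthetic_config")
}

# sample labels implied by a config
synthetic_samples <- function(config) {
  c(sprintf("tissue%02d", seq_len(config$n_tissues)), config$reference_label)
}

# smallest integer count giving FPKM strictly above `fpkm`
count_above_fpkm <- function(fpkm, library_size, len) {
  floor(fpkm * library_size * len / 1e9) + 1L
}

# largest integer count giving FPKM strictly below `fpkm`
count_below_fpkm <- function(fpkm, library_size, len) {
  as.integer(ceiling(fpkm * library_size * len / 1e9)) - 1L
}

#' Generate the synthetic expression panel and its ground truth
#'
#' Draw order (all from one stream seeded with `config$seed`): gene lengths,
#' exon counts, strands, per-gene target FPKM levels, then the count matrix
#' column by column. Housekeeping genes are planted above the high-FPKM
#' threshold in every sample; each tissue's TRA genes above it in their home
#' tissue and below the low threshold elsewhere; the first
#' `ceiling(mirror_fraction * tra_per_tissue)` TRAs of each tissue are
#' planted as expressed (FPKM > 0.3) in the reference sample; background
#' genes are moderately expressed in every sample. After drawing, counts are
#' clamped to the planted threshold relations and the relations are
#' re-verified.
#'
#' @param config a [synthetic_config()].
#' @return list with `panel` (an [expression_panel()]) and `truth` (a
#'   `synthetic_truth` list with `tra_assignment`, `mirrored_genes`,
#'   `housekeeping_genes`, `background_genes`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  n_hk <- config$n_housekeeping
  n_tra <- config$n_tissues * config$tra_per_tissue
  n_bg <- n - n_hk - n_tra
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  samples <- synthetic_samples(config)
  L <- config$library_size

  gene_id <- sprintf("g%05d", seq_len(n))
  category <- c(rep("housekeeping", n_hk),
                rep(tissues, each = config$tra_per_tissue),
                rep("background", n_bg))
  hk_ids <- gene_id[category == "housekeeping"]
  bg_ids <- gene_id[category == "background"]
  tra_assignment <- lapply(tissues, function(t) gene_id[category == t])
  names(tra_assignment) <- tissues
  n_mirror <- as.integer(ceiling(config$mirror_fraction * config$tra_per_tissue))
  mirrored <- unlist(lapply(tra_assignment,
                            function(g) g[seq_len(n_mirror)]),
                     use.names = FALSE)

  res <- local_seed(config$seed, {
    len <- as.integer(round(stats::runif(n, config$gene_length_range[1],
                                         config$gene_length_range[2])))
    n_junc <- sample_int_range(config$junctions_per_gene_range[1],
                               config$junctions_per_gene_range[2], n)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # target FPKM means per gene x sample
    mu_fpkm <- matrix(0.02, n, length(samples),
                      dimnames = list(gene_id, samples))
    mu_fpkm[category == "housekeeping", ] <-
      stats::runif(n_hk, 10, 100)
    for (t in tissues) {
      sel <- category == t
      mu_fpkm[sel, t] <- stats::runif(sum(sel), 10, 100)
    }
    mu_fpkm[match(mirrored, gene_id), config$reference_label] <-
      stats::runif(length(mirrored), 0.8, 4)
    mu_fpkm[category == "background", ] <-
      stats::runif(n_bg, 0.6, 3)

    mu_count <- mu_fpkm * (L / 1e9) * len
    counts <- matrix(
      stats::rnbinom(length(mu_count), mu = mu_count,
                     size = 1 / config$nb_dispersion),
      nrow = n, dimnames = dimnames(mu_fpkm)
    )
    list(len = len, n_junc = n_junc, strand = strand, counts = counts)
  })
  len <- res$len
  counts <- res$counts

  # clamp counts so the planted FPKM relations hold deterministically
  c_hi <- count_above_fpkm(5, L, len)
  c_lo <- count_below_fpkm(0.3, L, len)
  c_ex <- count_above_fpkm(0.3, L, len)
  hk <- category == "housekeeping"
  counts[hk, ] <- pmax(counts[hk, , drop = FALSE], c_hi[hk])
  for (t in tissues) {
    sel <- category == t
    counts[sel, t] <- pmax(counts[sel, t], c_hi[sel])
    others <- setdiff(tissues, t)
    counts[sel, others] <- pmin(counts[sel, others, drop = FALSE], c_lo[sel])
  }
  is_mirror <- gene_id %in% mirrored
  is_tra <- category %in% tissues
  counts[is_mirror, config$reference_label] <-
    pmax(counts[is_mirror, config$reference_label], c_ex[is_mirror])
  counts[is_tra & !is_mirror, config$reference_label] <-
    pmin(counts[is_tra & !is_mirror, config$reference_label],
         c_lo[is_tra & !is_mirror])
  bg <- category == "background"
  counts[bg, ] <- pmax(counts[bg, , drop = FALSE], c_ex[bg])

  if (any(colSums(counts) > L)) {
    stop("library_size too small: planted counts exceed it; ",
         "increase library_size or reduce n_genes")
  }

  # gene models: genes laid out non-overlapping per category block
  chrom <- character(n)
  chrom[hk] <- "chrHK"
  chrom[bg] <- "chrBG"
  for (i in seq_along(tissues)) {
    chrom[category == tissues[i]] <- sprintf("chrT%02d", i)
  }
  exons <- vector("list", n)
  offset <- stats::setNames(rep(0L, length(unique(chrom))), unique(chrom))
  intron_len <- 200L
  for (g in seq_len(n)) {
    ne <- res$n_junc[g] + 1L
    base <- floor(len[g] / ne)
    sizes <- rep(base, ne)
    sizes[ne] <- len[g] - base * (ne - 1L)
    start <- offset[chrom[g]]
    ex <- matrix(0L, ne, 2L)
    pos <- start
    for (e in seq_len(ne)) {
      ex[e, 1L] <- pos
      ex[e, 2L] <- pos + sizes[e]
      pos <- ex[e, 2L] + intron_len
    }
    exons[[g]] <- ex
    offset[chrom[g]] <- ex[ne, 2L] + 1000L
  }
  models <- gene_models(gene_id, chrom, res$strand, exons)

  panel <- expression_panel(counts, models,
                            aligned_reads_total =
                              stats::setNames(rep(L, length(samples)), samples))

  # post-generation consistency check of every planted relation
  f <- panel$fpkm
  stopifnot(all(f[hk, ] > 5))
  for (t in tissues) {
    sel <- tra_assignment[[t]]
    stopifnot(all(f[sel, t] > 5))
    stopifnot(all(f[sel, setdiff(tissues, t)] < 0.3))
  }
  stopifnot(all(f[mirrored, config$reference_label] > 0.3))
  non_mirror <- setdiff(unlist(tra_assignment), mirrored)
  stopifnot(all(f[non_mirror, config$reference_label] < 0.3))
  stopifnot(all(f[bg, ] >= 0.3))

  truth <- structure(
    list(
      tra_assignment = tra_assignment,
      mirrored_genes = mirrored,
      housekeeping_genes = hk_ids,
      background_genes = bg_ids,
      restricted_junctions = NULL,
      true_editing_levels = NULL,
      hyper_edited_read_ids = NULL
    ),
    class = "synthetic_truth"
  )
  list(panel = panel, truth = truth)
}

#' Generate the synthetic junction tables
#'
#' Every gene expressed (raw count >= 1) in a sample emits all its annotated
#' introns as shared junctions with support drawn from
#' `junction_support_range`. Each tissue additionally receives
#' `restricted_junctions_per_tissue` planted restricted junctions -- an
#' alternative acceptor inside the first intron of a housekeeping host gene
#' (hosts are disjoint across tissues) -- with support at least the detection
#' threshold in that tissue only; the first
#' `ceiling(junction_mirror_fraction * restricted_junctions_per_tissue)` of
#' each tissue's restricted junctions are also planted into the reference
#' sample. Restricted junction keys are recorded in the truth.
#'
#' @param config a [synthetic_config()].
#' @param panel the expression panel from [generate_expression()].
#' @param truth the matching `synthetic_truth`; updated and returned.
#' @return list with `junctions` (a `junction_panel`) and the updated
#'   `truth`.
#' @export
generate_junctions <- function(config, panel, truth) {
  models <- panel$models
  tissues <- setdiff(panel$samples, config$reference_label)
  ref <- config$reference_label

  # annotated introns per gene
  intr <- lapply(seq_len(nrow(models)), function(g) {
    e <- models$exons[[g]]
    if (nrow(e) < 2L) return(NULL)
    data.frame(
      gene = models$gene_id[g],
      chrom = models$chrom[g],
      start = e[-nrow(e), 2L],
      end = e[-1L, 1L],
      strand = models$strand[g],
      stringsAsFactors = FALSE
    )
  })
  intr <- do.call(rbind, intr)

  # restricted junctions: hosts are disjoint housekeeping genes
  rpt <- config$restricted_junctions_per_tissue
  restricted <- NULL
  if (rpt > 0L) {
    hosts <- truth$housekeeping_genes[seq_len(rpt * length(tissues))]
    host_rows <- models[hosts, ]
    if (any(host_rows$n_exons < 2L)) {
      stop("restricted-junction host gene with fewer than 2 exons: ",
           host_rows$gene_id[host_rows$n_exons < 2L][1L])
    }
    first_intron_start <- vapply(host_rows$exons,
                                 function(e) e[1L, 2L], integer(1L))
    first_intron_end <- vapply(host_rows$exons,
                               function(e) e[2L, 1L], integer(1L))
    alt_end <- first_intron_start +
      pmax(20L, (first_intron_end - first_intron_start) %/% 2L)
    restricted <- data.frame(
      tissue = rep(tissues, each = rpt),
      gene = hosts,
      chrom = host_rows$chrom,
      start = first_intron_start,
      end = alt_end,
      strand = host_rows$strand,
      stringsAsFactors = FALSE
    )
    restricted$key <- junction_key(restricted$chrom, restricted$start,
                                   restricted$end, restricted$strand)
  }

  n_jmirror <- as.integer(ceiling(config$junction_mirror_fraction * rpt))

  tables <- local_seed(config$seed + 1L, {
    out <- list()
    for (s in panel$samples) {
      expressed <- panel$genes[panel$counts[, s] >= 1L]
      shared <- intr[intr$gene %in% expressed, , drop = FALSE]
      shared$unique_reads <- sample_int_range(
        config$junction_support_range[1],
        config$junction_support_range[2], nrow(shared))
      shared$sample <- s
      out[[s]] <- shared
      if (!is.null(restricted)) {
        if (s %in% tissues) {
          r <- restricted[restricted$tissue == s, , drop = FALSE]
          r$unique_reads <- sample_int_range(
            config$restricted_support_range[1],
            config$restricted_support_range[2], nrow(r))
        } else {
          # reference: the first n_jmirror restricted junctions per tissue
          r <- do.call(rbind, lapply(tissues, function(t) {
            rt <- restricted[restricted$tissue == t, , drop = FALSE]
            rt[seq_len(n_jmirror), , drop = FALSE]
          }))
          if (is.null(r) || nrow(r) == 0L) next
          r$unique_reads <- sample(20L, nrow(r), replace = TRUE)
        }
        r$sample <- s
        out[[paste0(s, ".restricted")]] <-
          r[, c("gene", "chrom", "start", "end", "strand",
                "unique_reads", "sample")]
      }
    }
    out
  })
  cols <- c("sample", "chrom", "start", "end", "strand", "unique_reads")
  junctions <- do.call(rbind, lapply(tables, function(x) x[, cols]))
  rownames(junctions) <- NULL
  junctions <- assign_junctions_to_genes(junctions, models)

  if (is.null(restricted)) {
    truth$restricted_junctions <- stats::setNames(
      rep(list(character(0)), length(tissues)), tissues)
  } else {
    truth$restricted_junctions <- lapply(
      stats::setNames(tissues, tissues),
      function(t) restricted$key[restricted$tissue == t]
    )
  }
  list(junctions = junctions, truth = truth)
}

#' Generate synthetic editing sites and pileups
#'
#' Sites are laid on one synthetic chromosome; a fraction `prop_edited` of
#' them receives a nonzero true editing level (fixed or Beta-distributed),
#' identical across samples. Per site and sample, coverage is negative
#' binomial and the edited read count binomial at the true level. True
#' levels are recorded in the truth.
#'
#' @param config a [synthetic_config()].
#' @param truth optional `synthetic_truth` to update.
#' @return list with `sites` (annotation table), `pileups` (site x sample
#'   pileup table) and `truth` (holding the `true_editing_levels` matrix).
#' @export
generate_editing <- function(config, truth = NULL) {
  ns <- config$n_editing_sites
  samples <- synthetic_samples(config)
  eld <- config$editing_level_distribution

  res <- local_seed(config$seed + 2L, {
    strand <- sample(c("+", "-"), ns, replace = TRUE)
    is_a2i <- stats::runif(ns) < config$frac_a2i
    effect <- sample(c("nonsynonymous", "synonymous", "noncoding", "stopgain"),
                     ns, replace = TRUE, prob = c(0.35, 0.25, 0.35, 0.05))
    edited <- stats::runif(ns) < eld$prop_edited
    level <- numeric(ns)
    if (!is.null(eld$fixed_level)) {
      level[edited] <- eld$fixed_level
    } else {
      level[edited] <- stats::rbeta(sum(edited), eld$shape1, eld$shape2)
    }
    coverage <- matrix(
      stats::rnbinom(ns * length(samples),
                     mu = config$coverage_distribution$mean,
                     size = config$coverage_distribution$size),
      nrow = ns
    )
    edited_reads <- matrix(
      stats::rbinom(ns * length(samples), size = as.vector(coverage),
                    prob = rep(level, length(samples))),
      nrow = ns
    )
    list(strand = strand, is_a2i = is_a2i, effect = effect,
         level = level, coverage = coverage, edited_reads = edited_reads)
  })

  pos <- 1000L + 500L * seq_len(ns)  # 1-based positions
  sites <- data.frame(
    chrom = "chrE",
    pos = pos,
    strand = res$strand,
    ref_base = ifelse(res$is_a2i, "A", "C"),
    alt_base = ifelse(res$is_a2i, "G", "T"),
    edit_type = ifelse(res$is_a2i, "A2I", "C2U"),
    effect = res$effect,
    stringsAsFactors = FALSE
  )
  sites$site_key <- site_key(sites$chrom, sites$pos, sites$strand)

  pileups <- data.frame(
    site_key = rep(sites$site_key, length(samples)),
    sample = rep(samples, each = ns),
    total_reads = as.vector(res$coverage),
    edited_reads = as.vector(res$edited_reads),
    stringsAsFactors = FALSE
  )

  levels_mat <- matrix(rep(res$level, length(samples)), nrow = ns,
                       dimnames = list(sites$site_key, samples))
  if (is.null(truth)) {
    truth <- structure(list(), class = "synthetic_truth")
  }
  truth$true_editing_levels <- levels_mat
  list(sites = sites, pileups = pileups, truth = truth)
}

#' Generate hyper-edited and background read mismatch records
#'
#' Plants `n_hyper_reads` reads satisfying the hyper-read classifier
#' (at least 5 mismatches, all of them A>G on the plus strand or T>C on the
#' minus strand) and `n_background_reads` constructed to violate it: a third
#' with too few mismatches, a third with an editing-consistent fraction of
#' 0.75 (below the 0.8 threshold), and a third with non-editing mismatch
#' types. Planted read ids are recorded in the truth.
#'
#' @param config a [synthetic_config()].
#' @param truth optional `synthetic_truth` to update.
#' @return list with `reads` (read table), `mismatches` (one row per
#'   mismatch) and `truth`.
#' @export
generate_hyper_reads <- function(config, truth = NULL) {
  nh <- config$n_hyper_reads
  nb <- config$n_background_reads
  res <- local_seed(config$seed + 3L, {
    make_read <- function(id, n_mm, kind) {
      strand <- sample(c("+", "-"), 1L)
      pos <- sort(sample(seq(1000L, 60000L, by = 25L), n_mm))
      if (kind == "hyper") {
        ref <- if (strand == "+") "A" else "T"
        alt <- if (strand == "+") "G" else "C"
        ref <- rep(ref, n_mm)
        alt <- rep(alt, n_mm)
      } else if (kind == "mixed") {
        n_ok <- floor(0.75 * n_mm)
        ref <- c(rep(if (strand == "+") "A" else "T", n_ok),
                 rep("C", n_mm - n_ok))
        alt <- c(rep(if (strand == "+") "G" else "C", n_ok),
                 rep("A", n_mm - n_ok))
      } else {
        ref <- rep("G", n_mm)
        alt <- rep("T", n_mm)
      }
      data.frame(read_id = id, chrom = "chrH", pos = pos,
                 ref_base = ref, read_base = alt, strand = strand,
                 stringsAsFactors = FALSE)
    }
    mm <- list()
    reads <- list()
    if (nh > 0L) {
      for (i in seq_len(nh)) {
        id <- sprintf("hyp%05d", i)
        n_mm <- sample(5:12, 1L)
        mm[[id]] <- make_read(id, n_mm, "hyper")
        reads[[id]] <- data.frame(read_id = id,
                                  aligned_length = sample(80:100, 1L),
                                  stringsAsFactors = FALSE)
      }
    }
    if (nb > 0L) {
      kinds <- rep(c("few", "mixed", "other"), length.out = nb)
      for (i in seq_len(nb)) {
        id <- sprintf("bkg%05d", i)
        n_mm <- switch(kinds[i],
                       few = sample(1:4, 1L),
                       mixed = sample(c(8L, 12L, 16L), 1L),
                       other = sample(5:10, 1L))
        mm[[id]] <- make_read(id, n_mm, kinds[i])
        reads[[id]] <- data.frame(read_id = id,
                                  aligned_length = sample(80:100, 1L),
                                  stringsAsFactors = FALSE)
      }
    }
    list(mismatches = do.call(rbind, mm), reads = do.call(rbind, reads))
  })
  if (is.null(truth)) {
    truth <- structure(list(), class = "synthetic_truth")
  }
  truth$hyper_edited_read_ids <-
    if (nh > 0L) sprintf("hyp%05d", seq_len(nh)) else character(0)
  if (is.null(res$mismatches)) {
    res$mismatches <- data.frame(read_id = character(0), chrom = character(0),
                                 pos = integer(0), ref_base = character(0),
                                 read_base = character(0),
                                 strand = character(0),
                                 stringsAsFactors = FALSE)
    res$reads <- data.frame(read_id = character(0),
                            aligned_length = integer(0),
                            stringsAsFactors = FALSE)
  }
  rownames(res$mismatches) <- NULL
  rownames(res$reads) <- NULL
  list(reads = res$reads, mismatches = res$mismatches, truth = truth)
}

#' Generate the full synthetic dataset
#'
#' Runs all four generators in order (expression, junctions, editing, hyper
#' reads) and returns every table together with the consolidated ground
#' truth. Deterministic given the config (including its seed).
#'
#' @param config a [synthetic_config()].
#' @return list with `panel`, `junctions`, `sites`, `pileups`, `reads`,
#'   `mismatches`, `truth`, `config`.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  ex <- generate_expression(config)
  jn <- generate_junctions(config, ex$panel, ex$truth)
  ed <- generate_editing(config, jn$truth)
  hy <- generate_hyper_reads(config, ed$truth)
  list(
    panel = ex$panel,
    junctions = jn$junctions,
    sites = ed$sites,
    pileups = ed$pileups,
    reads = hy$reads,
    mismatches = hy$mismatches,
    truth = hy$truth,
    config = config
  )
}
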