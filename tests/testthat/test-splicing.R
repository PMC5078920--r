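# two-gene models used across the splicing tests: each gene has 3 exons of
# 100 nt separated by 200-nt introns
splice_models <- function() {
  ex <- function(off) matrix(off + c(0L, 300L, 600L, 100L, 400L, 700L), 3L)
  gene_models(c("gA", "gB"), c("chr1", "chr1"), c("+", "+"),
              list(ex(0L), ex(5000L)))
}

test_that("junction-to-gene assignment requires contained flanks and compatible strands", {
  models <- splice_models()
  j <- rbind(
    jtab("s1", "chr1", 100L, 300L),          # intron 1 of gA
    jtab("s1", "chr1", 20000L, 20400L),      # intergenic
    jtab("s1", "chr1", 5100L, 5300L, "-")    # inside gB but wrong strand
  )
  out <- assign_junctions_to_genes(j, models)
  expect_equal(out$gene_id, c("gA", NA, NA))
  # undefined strand matches either gene strand
  j2 <- jtab("s1", "chr1", 5100L, 5300L, "*")
  expect_equal(assign_junctions_to_genes(j2, models)$gene_id, "gB")
  # a junction whose flank touches the gene boundary is out
  j3 <- jtab("s1", "chr1", 0L, 300L)  # flanking base -1 outside gA
  expect_true(is.na(assign_junctions_to_genes(j3, models)$gene_id))
})

test_that("ties between overlapping genes go to the longer containment, then smaller id", {
  # two genes sharing a span; gWide is longer, gZ same span as gWide
  exs <- list(
    matrix(c(0L, 2000L), 1L),             # gWide: 0..2000
    matrix(c(400L, 1200L), 1L),           # gNarrow: 400..1200
    matrix(c(0L, 2000L), 1L)              # gZ: same span as gWide
  )
  models <- gene_models(c("gWide", "gNarrow", "gZ"),
                        rep("chr1", 3L), rep("+", 3L), exs)
  j <- jtab("s1", "chr1", 500L, 900L)
  out <- assign_junctions_to_genes(j, models)
  expect_equal(out$gene_id, "gWide")  # longer span wins; gWide < gZ breaks tie
})

test_that("AS detection flags genes with junctions sharing a donor or acceptor", {
  models <- splice_models()
  shared_start <- rbind(
    jtab("s1", "chr1", 100L, 300L),
    jtab("s1", "chr1", 100L, 600L)
  )
  out <- assign_junctions_to_genes(shared_start, models)
  expect_equal(detect_as_genes(out, "s1"), "gA")
  disjoint <- assign_junctions_to_genes(rbind(
    jtab("s1", "chr1", 100L, 300L),
    jtab("s1", "chr1", 400L, 600L)
  ), models)
  expect_equal(detect_as_genes(disjoint, "s1"), character(0))
  single <- assign_junctions_to_genes(jtab("s1", "chr1", 100L, 300L), models)
  expect_equal(detect_as_genes(single, "s1"), character(0))
  # shared end counts too
  shared_end <- assign_junctions_to_genes(rbind(
    jtab("s1", "chr1", 100L, 600L),
    jtab("s1", "chr1", 400L, 600L)
  ), models)
  expect_equal(detect_as_genes(shared_end, "s1"), "gA")
})

test_that("adding a junction never un-flags an AS gene and matches brute force", {
  set.seed(31)
  n_genes <- 12L
  models <- toy_models(stats::setNames(rep(3000L, n_genes),
                                       sprintf("g%02d", 1:n_genes)))
  random_junctions <- function(n) {
    g <- sample(n_genes, n, replace = TRUE)
    off <- (g - 1L) * 4000L  # toy_models gap: length 3000 + 1000
    anchors <- sample(seq(100L, 1400L, by = 100L), n, replace = TRUE)
    ends <- anchors + sample(seq(200L, 1400L, by = 100L), n, replace = TRUE)
    jtab("s1", "chr1", off + anchors, off + ends,
         unique_reads = sample(1:30, n, replace = TRUE))
  }
  for (trial in 1:10) {
    j <- random_junctions(40L)
    out <- assign_junctions_to_genes(j, models)
    expect_identical(detect_as_genes(out, "s1"), brute_as_genes(out, "s1"))
    # monotonicity: append junctions, AS set can only grow
    j2 <- rbind(j, random_junctions(10L))
    out2 <- assign_junctions_to_genes(j2, models)
    expect_true(all(detect_as_genes(out, "s1") %in%
                      detect_as_genes(out2, "s1")))
  }
})

test_that("AS fraction by quartile uses multi-exon expressed genes and planted truth", {
  n <- 40L
  ids <- sprintf("g%02d", 1:n)
  # 3 exons each so all genes are multi-exon; expression increasing with index
  exs <- lapply(seq_len(n), function(i) {
    off <- (i - 1L) * 2000L
    matrix(off + c(0L, 400L, 800L, 300L, 700L, 1100L), 3L)
  })
  models <- gene_models(ids, rep("chr1", n), rep("+", n), exs)
  counts <- matrix(10L * seq_len(n), n, 1L, dimnames = list(ids, "s1"))
  panel <- expression_panel(counts, models)
  # plant AS (two junctions sharing a start) in 3 of the 10 Q4 genes
  q <- expression_quartiles(panel, "s1", threshold = 0)
  q4 <- names(q)[q == "Q4"][1:3]
  j <- do.call(rbind, lapply(q4, function(g) {
    off <- (match(g, ids) - 1L) * 2000L
    rbind(jtab("s1", "chr1", off + 400L, off + 700L),
          jtab("s1", "chr1", off + 400L, off + 800L))
  }))
  out <- assign_junctions_to_genes(j, models)
  res <- as_fraction_by_quartile(out, panel, "s1", threshold = 0)
  expect_equal(res$fraction[res$quartile == "Q4"], 0.3)
  expect_equal(res$fraction[res$quartile == "Q1"], 0)
  expect_equal(res$n_genes, rep(10L, 4L))
  # all genes AS -> 1.0 everywhere
  jall <- do.call(rbind, lapply(ids, function(g) {
    off <- (match(g, ids) - 1L) * 2000L
    rbind(jtab("s1", "chr1", off + 400L, off + 700L),
          jtab("s1", "chr1", off + 400L, off + 800L))
  }))
  resall <- as_fraction_by_quartile(assign_junctions_to_genes(jall, models),
                                    panel, "s1", threshold = 0)
  expect_equal(resall$fraction, rep(1, 4L))
  # no junctions -> 0.0
  res0 <- as_fraction_by_quartile(assign_junctions_to_genes(
    jtab("s1", "chr1", 1L, 2L)[0, ], models),
    panel, "s1", threshold = 0)
  expect_equal(res0$fraction, rep(0, 4L))
})

test_that("junctions-per-gene comparison partitions genes by the five-junction rule", {
  n <- 10L
  ids <- sprintf("g%02d", 1:n)
  models <- toy_models(stats::setNames(rep(5000L, n), ids))
  counts <- matrix(500L, n, 2L, dimnames = list(ids, c("sa", "sb")))
  panel <- expression_panel(counts, models)
  # hand-built junction counts per gene: (n_a, n_b)
  plan <- rbind(c(12, 4), c(4, 12), c(3, 3), c(0, 5), c(6, 0),
                c(8, 8), c(10, 4), c(0, 0), c(1, 7), c(2, 8))
  build <- function(sample, col) {
    rows <- lapply(seq_len(n), function(i) {
      k <- plan[i, col]
      if (k == 0) return(NULL)
      off <- (i - 1L) * 6000L
      jtab(sample, "chr1", off + 100L + seq_len(k) * 40L,
           off + 3000L + seq_len(k) * 40L)
    })
    do.call(rbind, rows)
  }
  j <- assign_junctions_to_genes(rbind(build("sa", 1), build("sb", 2)), models)
  res <- junctions_per_gene_compare(j, panel, "sa", "sb")
  expect_equal(res$n_a, plan[, 1])
  expect_equal(res$n_b, plan[, 2])
  hand <- c("a_higher", "b_higher", "within", "within", "a_higher",
            "within", "a_higher", "within", "b_higher", "b_higher")
  expect_equal(res$class, hand)
  expect_equal(unname(attr(res, "summary")),
               c(sum(hand == "a_higher"), sum(hand == "b_higher"),
                 sum(hand == "within")))
  # identical tables -> everything within
  j_same <- assign_junctions_to_genes(rbind(build("sa", 1),
                                            {x <- build("sa", 1); x$sample <- "sb"; x}),
                                      models)
  res_same <- junctions_per_gene_compare(j_same, panel, "sa", "sb")
  expect_true(all(res_same$class == "within"))
})

test_that("TRA junction detection enforces support, exclusivity and a shared host gene", {
  # host gene expressed in colon and liver; junction supported only in colon
  f <- rbind(host = c(colon = 2, liver = 2, lung = 0.1),
             lonely = c(colon = 2, liver = 0.1, lung = 0.1))
  models <- toy_models(stats::setNames(c(4000L, 4000L), c("host", "lonely")))
  counts <- matrix(0L, 2L, 3L, dimnames = list(c("host", "lonely"),
                                               colnames(f)))
  panel <- expression_panel(counts, models,
                            aligned_reads_total = stats::setNames(
                              rep(1e6, 3L), colnames(f)), fpkm = f)
  mk <- function(support_colon, support_lung = NULL, gene_off = 0L) {
    j <- jtab("colon", "chr1", gene_off + 500L, gene_off + 900L,
              unique_reads = support_colon)
    if (!is.null(support_lung)) {
      j <- rbind(j, jtab("lung", "chr1", gene_off + 500L, gene_off + 900L,
                         unique_reads = support_lung))
    }
    assign_junctions_to_genes(j, models)
  }
  sets <- detect_tra_junctions(mk(10L), panel, support = 10,
                               excluded_samples = character())
  expect_equal(length(sets$colon), 1L)
  # support 9 is below the threshold
  sets9 <- detect_tra_junctions(mk(9L), panel, support = 10,
                                excluded_samples = character())
  expect_equal(sets9$colon, character(0))
  # a single read in another tissue breaks exclusivity
  sets_leak <- detect_tra_junctions(mk(10L, support_lung = 1L), panel,
                                    support = 10,
                                    excluded_samples = character())
  expect_equal(sets_leak$colon, character(0))
  # host gene expressed nowhere else -> ineligible (gene "lonely" at offset 5000)
  sets_lonely <- detect_tra_junctions(mk(10L, gene_off = 5000L), panel,
                                      support = 10,
                                      excluded_samples = character())
  expect_equal(sets_lonely$colon, character(0))
})

test_that("TRA junction sets shrink weakly as the support threshold rises", {
  ds <- generate_synthetic_dataset(synthetic_config(
    n_genes = 600, n_tissues = 3, tra_per_tissue = 10,
    frac_housekeeping = 0.2, restricted_junctions_per_tissue = 8,
    library_size = 1e6, n_editing_sites = 10, n_hyper_reads = 5,
    n_background_reads = 10, seed = 21))
  for (sup in c(5, 10, 20, 60)) {
    assign(paste0("s", sup),
           detect_tra_junctions(ds$junctions, ds$panel, support = sup,
                                excluded_samples = "mTEC_like"))
  }
  for (t in names(s5)) {
    expect_true(all(s10[[t]] %in% s5[[t]]))
    expect_true(all(s20[[t]] %in% s10[[t]]))
    expect_true(all(s60[[t]] %in% s20[[t]]))
  }
})

test_that("TRA junction coverage and the two-reference comparison behave at the boundaries", {
  sets <- list(t1 = c("k1", "k2", "k3", "k4"), t2 = character(0))
  jp <- rbind(
    jtab("ref", "chr1", c(10L, 100L), c(50L, 200L)),
    jtab("refB", "chr1", 10L, 50L)
  )
  jp$key <- sprintf("%s:%d-%d:%s", jp$chrom, jp$start, jp$end, jp$strand)
  jp$gene_id <- NA_character_
  class(jp) <- c("junction_panel", "data.frame")
  keyed <- jp
  keyed$key[1:2] <- c("k1", "k2")
  keyed$key[3] <- "k1"
  cov <- tra_junction_coverage(sets, keyed, "ref")
  expect_equal(unname(cov["t1"]), 0.5)
  expect_true(is.na(cov["t2"]))
  cmp <- compare_coverage_two_references(sets, keyed, "ref", "refB")
  expect_equal(cmp$covered_a[cmp$tissue == "t1"], 2L)
  expect_equal(cmp$covered_b[cmp$tissue == "t1"], 1L)
  expect_true(is.na(cmp$p_value[cmp$tissue == "t2"]))
  # identical coverage counts give p = 1
  cmp_same <- compare_coverage_two_references(sets, keyed, "ref", "ref")
  expect_equal(cmp_same$p_value[cmp_same$tissue == "t1"], 1)
  # (90,10 / 50,50) against the enumeration oracle
  p_pkg <- fisher_site_compare(90, 100, 50, 100)
  expect_equal(p_pkg, brute_fisher(90, 10, 50, 50), tolerance = 1e-12)
})
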