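test_that("per-site editing level is the edited-read fraction, undefined at zero coverage", {
  expect_equal(editing_level(50, 0), 0)
  expect_equal(editing_level(50, 50), 1)
  expect_equal(editing_level(30, 3), 0.1)
  expect_true(is.na(editing_level(0, 0)))
  expect_error(editing_level(10, 11), "edited_reads > total_reads")
})

test_that("site support classification follows the ten-read rule", {
  cls <- site_support_class(
    total_reads = c(0L, 12L, 9L, 12L),
    edited_reads = c(0L, 0L, 2L, 3L)
  )
  expect_equal(as.character(cls),
               c("no_coverage", "well_supported_unedited", "low_support",
                 "well_supported_edited"))
  # the stringent preset needs five edited reads to call a site edited
  cls5 <- site_support_class(c(20L, 20L), c(4L, 5L), min_edited = 5)
  expect_equal(as.character(cls5),
               c("well_supported_unedited", "well_supported_edited"))
})

test_that("editing rate counts edited sites among expressed sites", {
  p <- data.frame(
    site_key = sprintf("s%d", 1:5),
    sample = "x",
    total_reads = c(0L, 10L, 10L, 3L, 10L),
    edited_reads = c(0L, 0L, 2L, 1L, 5L)
  )
  r <- editing_rate(p, "x")
  expect_equal(as.numeric(r), 3 / 4)  # sites 2..5 expressed; 3,4,5 edited
  expect_equal(attr(r, "n_expressed"), 4L)
  # no covered site -> undefined
  p0 <- p; p0$total_reads <- 0L; p0$edited_reads <- 0L
  expect_true(is.na(as.numeric(editing_rate(p0, "x"))))
  # all covered sites edited -> 1
  p1 <- p[p$edited_reads > 0, ]
  expect_equal(as.numeric(editing_rate(p1, "x")), 1)
})

test_that("editing rate responds monotonically to both floors", {
  set.seed(12)
  p <- data.frame(
    site_key = sprintf("s%03d", 1:200),
    sample = "x",
    total_reads = rnbinom(200, mu = 20, size = 2)
  )
  p$edited_reads <- rbinom(200, p$total_reads, 0.15)
  rates_me <- sapply(1:6, function(me) {
    as.numeric(editing_rate(p, "x", min_edited = me))
  })
  expect_true(all(diff(rates_me) <= 0))
  denoms <- sapply(c(1, 5, 10, 20), function(mt) {
    attr(editing_rate(p, "x", min_total = mt), "n_expressed")
  })
  expect_true(all(diff(denoms) <= 0))
})

test_that("hyper-read classifier applies both thresholds inclusively", {
  mm <- function(n_a2g, n_other, strand = "+") {
    data.frame(
      ref_base = c(rep(if (strand == "+") "A" else "T", n_a2g),
                   rep("C", n_other)),
      read_base = c(rep(if (strand == "+") "G" else "C", n_a2g),
                    rep("A", n_other)),
      strand = strand
    )
  }
  expect_true(classify_hyper_read(mm(6, 0)))
  expect_true(classify_hyper_read(mm(6, 0, strand = "-")))
  expect_false(classify_hyper_read(mm(3, 3)))   # fraction 0.5 < 0.8
  expect_false(classify_hyper_read(mm(4, 0)))   # 4 mismatches < 5
  expect_true(classify_hyper_read(mm(4, 1)))    # 5 mismatches, fraction 0.8
  # A>G on the minus strand is not editing-consistent
  minus_wrong <- data.frame(ref_base = rep("A", 6), read_base = rep("G", 6),
                            strand = "-")
  expect_false(classify_hyper_read(minus_wrong))
})

test_that("hyper-editing density normalizes unique sites per million reads", {
  expect_equal(hyper_editing_density(0, 2e7), 0)
  expect_equal(hyper_editing_density(96, 2e7), 4.8)
  expect_error(hyper_editing_density(5, 0), "positive")
})

test_that("per-site Fisher comparison matches the enumeration oracle and is symmetric", {
  expect_equal(fisher_site_compare(5, 10, 5, 10), 1)
  expect_true(is.na(fisher_site_compare(0, 0, 3, 10)))
  set.seed(8)
  for (i in 1:200) {
    ta <- sample(0:25, 1); tb <- sample(0:25, 1)
    ea <- if (ta > 0) sample(0:ta, 1) else 0L
    eb <- if (tb > 0) sample(0:tb, 1) else 0L
    p <- fisher_site_compare(ea, ta, eb, tb)
    expect_equal(p, brute_fisher(ea, ta - ea, eb, tb - eb),
                 tolerance = 1e-12)
    # swapping samples and complementing both rows leave p unchanged
    expect_equal(p, fisher_site_compare(eb, tb, ea, ta))
    expect_equal(p, fisher_site_compare(ta - ea, ta, tb - eb, tb))
    # agrees with stats::fisher.test
    if (!is.na(p)) {
      ft <- stats::fisher.test(matrix(c(ea, ta - ea, eb, tb - eb), 2L,
                                      byrow = TRUE))
      expect_equal(p, ft$p.value, tolerance = 1e-9)
    }
  }
})

test_that("Benjamini-Hochberg q-values follow the step-up definition and handle NA", {
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3L))
  expect_equal(benjamini_hochberg(rep(1, 5L)), rep(1, 5L))
  # NA p-values propagate and do not count toward m
  q <- benjamini_hochberg(c(0.01, NA, 0.02, 0.03))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], rep(0.03, 3L))
  # permutation invariance and oracle agreement on random vectors
  set.seed(3)
  for (i in 1:20) {
    p <- runif(50)
    expect_equal(benjamini_hochberg(p), brute_bh(p), tolerance = 1e-14)
    perm <- sample(50)
    expect_equal(benjamini_hochberg(p[perm]), benjamini_hochberg(p)[perm],
                 tolerance = 1e-14)
  }
})

test_that("aggregate editing level is the coverage-weighted mean of site levels", {
  p <- data.frame(
    site_key = c("a", "b"), sample = "x",
    total_reads = c(10L, 10L), edited_reads = c(2L, 3L)
  )
  expect_equal(aggregate_editing_level(p, "x"), 0.25)
  # algebraic identity with the coverage-weighted mean
  lv <- editing_level(p$total_reads, p$edited_reads)
  expect_equal(aggregate_editing_level(p, "x"),
               sum(lv * p$total_reads) / sum(p$total_reads))
  p0 <- p; p0$edited_reads <- 0L
  expect_equal(aggregate_editing_level(p0, "x"), 0)
  p0$total_reads <- 0L
  expect_true(is.na(aggregate_editing_level(p0, "x")))
})

test_that("sample comparison joins pileups, applies Fisher and FDR", {
  p <- data.frame(
    site_key = rep(c("s1", "s2", "s3"), 2L),
    sample = rep(c("a", "b"), each = 3L),
    total_reads = c(100L, 50L, 0L, 100L, 50L, 20L),
    edited_reads = c(60L, 5L, 0L, 10L, 5L, 3L)
  )
  cmp <- compare_editing_samples(p, "a", "b")
  expect_equal(nrow(cmp), 3L)
  expect_true(is.na(cmp$p_value[cmp$site_key == "s3"]))  # zero total in a
  s1 <- cmp[cmp$site_key == "s1", ]
  expect_equal(s1$p_value, brute_fisher(60, 40, 10, 90), tolerance = 1e-12)
  expect_true(s1$significant)
  expect_equal(cmp$q_value[cmp$site_key == "s2"],
               benjamini_hochberg(cmp$p_value)[2])
})

test_that("expression-editing correlation handles exact, constant and noisy inputs", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlate_expression_editing(x, 2 * x)
  expect_equal(res$estimate, 1)
  const <- correlate_expression_editing(x, rep(0.5, 5))
  expect_true(is.na(const$estimate))
  expect_error(correlate_expression_editing(1:2, 1:2), "at least 3")
  # seeded bivariate draw with known correlation 0.9, n = 200
  set.seed(9)
  n <- 200L
  z <- rnorm(n)
  x2 <- z
  y2 <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  res2 <- correlate_expression_editing(x2, y2)
  expect_lt(abs(res2$estimate - 0.9), 0.05)
  expect_lt(res2$p_value, 1e-10)
  # spearman option
  res3 <- correlate_expression_editing(x2, y2, method = "spearman")
  expect_gt(res3$estimate, 0.8)
})
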