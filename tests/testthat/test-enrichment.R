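test_that("DE threshold filtering applies strict inequalities and nests", {
  empty <- de_table(data.frame(
    gene = character(0), logFC = numeric(0), adj_p = numeric(0)
  ))
  expect_identical(filter_de_table(empty, threshold_spec(0.05, 1)), character(0))

  toy <- data.frame(
    gene = c("g1", "g2", "g3"),
    logFC = c(1.5, 0.5, 3.0),
    adj_p = c(0.04, 0.04, 0.2)
  )
  expect_identical(filter_de_table(toy, threshold_spec(0.05, 1)), "g1")
  # boundary values do not pass (strict < and >)
  edge <- data.frame(gene = c("a", "b"), logFC = c(1, 1.1), adj_p = c(0.04, 0.05))
  expect_identical(filter_de_table(edge, threshold_spec(0.05, 1)), character(0))

  set.seed(41)
  for (i in 1:10) {
    tab <- data.frame(
      gene = sprintf("g%03d", 1:100),
      logFC = rnorm(100, 0, 1.2),
      adj_p = runif(100)
    )
    loose <- filter_de_table(tab, threshold_spec(0.05, 0.5))
    strict1 <- filter_de_table(tab, threshold_spec(0.01, 0.5))
    strict2 <- filter_de_table(tab, threshold_spec(0.05, 1.5))
    expect_true(all(strict1 %in% loose))
    expect_true(all(strict2 %in% loose))
  }
})

test_that("enrichment ratio follows (g/n)/(G/N) and its monotonicity", {
  expect_equal(round(enrichment_ratio(198, 4088, 749, 20459), 2), 1.32)
  expect_equal(round(enrichment_ratio(23, 54, 749, 19834), 2), 11.28)
  expect_equal(enrichment_ratio(10, 200, 50, 1000), 1) # g/n == G/N
  expect_equal(enrichment_ratio(50, 1000, 50, 1000), 1) # whole universe
  ratios <- sapply(0:40, function(g) enrichment_ratio(g, 40, 50, 1000))
  expect_true(all(diff(ratios) > 0))
  expect_error(enrichment_ratio(1, 0, 50, 100), "must all be >= 1")
  expect_error(enrichment_ratio(60, 50, 40, 100), "min\\(n, G\\)")
  expect_error(enrichment_ratio(5, 50, 200, 100), "universe size")
})

test_that("overlap counting is a normalized set intersection", {
  expect_equal(overlap_count(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_count(c("a", "b"), c("a", "b", "c")), 2)
  expect_equal(overlap_count(c("Lyz2", "Apoe"), c("LYZ2", "APOE ", "CRYAB")), 2)
  expect_equal(overlap_count(c("a", "A", "a "), c("a")), 1) # duplicates collapse
})

test_that("matched comparison builds per-threshold rows recomputable by the ratio formula", {
  # score table ranks g01..g20; reference = {g01..g05}
  tab <- structure(
    data.frame(
      gene = sprintf("g%02d", 1:20),
      score = 20:1, W_plus = 20:1, W_minus = 0,
      stringsAsFactors = FALSE
    ),
    class = c("gene_score_table", "data.frame")
  )
  reference <- sprintf("g%02d", 1:5)
  de <- data.frame(
    gene = sprintf("g%02d", 1:20),
    logFC = c(rep(2, 4), rep(0.2, 16)),
    adj_p = c(rep(0.001, 8), rep(0.5, 12))
  )
  rep <- matched_comparison(
    tab, de,
    specs = list(threshold_spec(0.05, NULL), threshold_spec(0.05, 1)),
    reference = reference, N = 20
  )
  # FDR<0.05: n = 8, deg overlap 5, nmf top-8 overlap 5
  expect_equal(rep$rows$n, c(8L, 4L))
  expect_equal(rep$rows$g_deg, c(5L, 4L))
  expect_equal(rep$rows$g_nmf, c(5L, 4L))
  expect_equal(rep$rows$ratio_deg, c((5 / 8) / (5 / 20), (4 / 4) / (5 / 20)))
  expect_equal(rep$rows$ratio_nmf, rep$rows$ratio_deg)
  expect_equal(rep$mean_ratio_deg, mean(rep$rows$ratio_deg))
  expect_equal(rep$G, 5L)

  # identical ratio columns: the t-test degenerates to NA with a warning
  expect_warning(
    rep2 <- matched_comparison(
      tab, de,
      specs = list(threshold_spec(0.05, NULL), threshold_spec(0.05, NULL)),
      reference = reference, N = 20
    ),
    "t-test degenerate"
  )
  expect_true(is.na(rep2$t_test_p))

  # empty threshold rows are flagged and excluded from the means (with a
  # single surviving row the t-test also degenerates, a second warning)
  w <- capture_warnings(
    rep3 <- matched_comparison(
      tab, de,
      specs = list(threshold_spec(0.05, NULL), threshold_spec(0.05, 5)),
      reference = reference, N = 20
    )
  )
  expect_match(w, "selects no genes", all = FALSE)
  expect_identical(rep3$rows$included, c(TRUE, FALSE))
  expect_equal(rep3$mean_ratio_deg, rep3$rows$ratio_deg[1])
})

test_that("the convenience Welch test agrees with t.test and p.adjust gene by gene", {
  set.seed(51)
  vals <- matrix(2^rnorm(30 * 12, 5, 1), 30, 12,
    dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12))
  )
  vals[1:3, 1:6] <- vals[1:3, 1:6] * 4 # planted shift
  m <- expression_matrix(log2(vals + 1), "log2_tpm_plus1")
  labels <- setNames(rep(c("disease", "normal"), each = 6), colnames(vals))
  de <- simple_de_test(m, labels)

  expected_p <- sapply(rownames(vals), function(g) {
    stats::t.test(m$values[g, 1:6], m$values[g, 7:12])$p.value
  })
  expect_equal(de$p_value, unname(expected_p), tolerance = 1e-12)
  expect_equal(de$adj_p, unname(p.adjust(expected_p, "BH")), tolerance = 1e-12)
  expect_equal(
    de$logFC,
    unname(rowMeans(m$values[, 1:6]) - rowMeans(m$values[, 7:12]))
  )
})

test_that("the convenience Welch test flags degenerate genes and planted effects pass thresholds", {
  # duplicated columns: zero variance in both groups, equal means -> p = 1
  vals <- matrix(rep(c(1, 2, 3), 4), 3, 4,
    dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4))
  )
  m <- expression_matrix(vals, "log2_tpm_plus1")
  labels <- setNames(c("disease", "disease", "normal", "normal"), colnames(vals))
  expect_warning(de <- simple_de_test(m, labels), "zero variance")
  expect_equal(de$adj_p, rep(1, 3))
  expect_identical(
    filter_de_table(de, threshold_spec(0.05, NULL)), character(0)
  )

  # planted 4-fold change (2 on the log2 scale), n = 20 per group, low noise
  set.seed(52)
  base <- matrix(rnorm(50 * 40, 8, 0.3), 50, 40,
    dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:40))
  )
  base["g01", 1:20] <- base["g01", 1:20] + 2
  m2 <- expression_matrix(base, "log2_tpm_plus1")
  labels2 <- setNames(rep(c("disease", "normal"), each = 20), colnames(base))
  de2 <- simple_de_test(m2, labels2)
  expect_true("g01" %in% filter_de_table(de2, threshold_spec(0.01, 1)))
  expect_gt(de2$logFC[de2$gene == "g01"], 1.5)
})

test_that("the DE test's FDR adjustment matches a hand-rolled Benjamini-Hochberg", {
  # independent oracle: sort, multiply by n/rank, cummin from the largest
  bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
    pmin(adj, 1)[order(o)]
  }
  # hand-worked ladder: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(53)
  vals <- matrix(rnorm(40 * 8, 6, 1), 40, 8,
    dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:8))
  )
  m <- expression_matrix(vals - min(vals), "log2_tpm_plus1")
  labels <- setNames(rep(c("disease", "normal"), each = 4), colnames(vals))
  de <- simple_de_test(m, labels)
  expect_equal(de$adj_p, bh(de$p_value), tolerance = 1e-12)
})

test_that("threshold grid round-trips through its compact string form", {
  grid <- default_threshold_grid()
  expect_length(grid, 8)
  s <- format_threshold_specs(grid)
  expect_identical(s, "0.05:;0.05:1;0.01:;0.01:1;0.05:0.5;0.05:1.5;0.01:0.5;0.01:1.5")
  back <- parse_threshold_specs(s)
  expect_equal(back, grid)
  expect_error(threshold_spec(0), "in \\(0, 1\\]")
  expect_error(threshold_spec(0.05, -1), ">= 0")
})
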