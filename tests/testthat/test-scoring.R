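test_that("cluster labeling recovers precision from the realized composition", {
  # development-set composition: cluster 1 pure disease (11/11),
  # cluster 2 mixed (18 disease / 64)
  asg <- c(rep(1L, 11), rep(2L, 64))
  names(asg) <- sprintf("S%03d", seq_along(asg))
  labels <- setNames(
    c(rep("disease", 11), rep("disease", 18), rep("normal", 46)),
    names(asg)
  )
  lab <- label_clusters(asg, labels)
  expect_equal(lab$disease_cluster, 1)
  expect_equal(lab$precision, 1)
  expect_equal(lab$composition$n_total, c(11, 64))

  # validation-set composition: 11/32 in cluster 1 vs 11/26 in cluster 2
  asg2 <- setNames(c(rep(1L, 32), rep(2L, 26)), sprintf("V%03d", 1:58))
  labels2 <- setNames(
    c(rep("disease", 11), rep("normal", 21), rep("disease", 11), rep("normal", 15)),
    names(asg2)
  )
  lab2 <- label_clusters(asg2, labels2)
  expect_equal(lab2$disease_cluster, 2)
  expect_equal(lab2$precision, 11 / 26)
  # precision always equals n_disease(g+) / total(g+)
  comp <- lab2$composition
  expect_equal(
    lab2$precision,
    comp$n_disease[comp$cluster == lab2$disease_cluster] /
      comp$n_total[comp$cluster == lab2$disease_cluster]
  )
})

test_that("cluster labeling refuses ties, empty clusters and unlabeled samples", {
  asg <- setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d"))
  tied <- setNames(c("disease", "normal", "disease", "normal"), c("a", "b", "c", "d"))
  expect_error(label_clusters(asg, tied), "same disease fraction")

  one_cluster <- setNames(rep(1L, 4), c("a", "b", "c", "d"))
  expect_error(label_clusters(one_cluster, tied), "exactly 2 occupied clusters")

  expect_error(
    label_clusters(asg, tied[1:3]),
    "unlabeled sample\\(s\\): d"
  )
  expect_error(label_clusters(asg, tied, k = 3), "only k = 2")
})

test_that("the precision-weighted score reproduces its worked example and stays convex", {
  expect_identical(gene_score(20.64, 21.20, p = 1), 20.64)
  expect_equal(gene_score(5, 10, p = 0.8), 6)
  expect_equal(gene_score(3, 3, p = 0.37), 3)
  expect_error(gene_score(1, 1, p = 1.2), "p must lie")
  expect_error(gene_score(-1, 1, p = 0.5), "must be >= 0")

  set.seed(8)
  for (i in 1:50) {
    wp <- runif(1, 0, 10)
    wm <- runif(1, 0, 10)
    p <- runif(1)
    s <- gene_score(wp, wm, p)
    expect_gte(s, min(wp, wm))
    expect_lte(s, max(wp, wm))
  }
})

test_that("score_genes ranks by the labeled basis columns with a stable tie-break", {
  W <- rbind(
    geneB = c(5, 1),
    geneA = c(5, 9),
    geneC = c(2, 7),
    geneD = c(8, 0.5),
    geneE = c(1, 1)
  )
  colnames(W) <- c("metagene1", "metagene2")
  f <- structure(
    list(W = W, H = matrix(0, 2, 3), rank = 2L),
    class = "nmf_fit"
  )
  lab1 <- structure(
    list(disease_cluster = 1L, normal_cluster = 2L, precision = 1),
    class = "cluster_labeling"
  )
  t1 <- score_genes(f, lab1)
  # p = 1: ranking equals ranking of column 1; tie 5 vs 5 broken by id
  expect_identical(t1$gene, c("geneD", "geneA", "geneB", "geneC", "geneE"))
  expect_equal(t1$score, unname(W[t1$gene, 1]))

  lab0 <- structure(
    list(disease_cluster = 1L, normal_cluster = 2L, precision = 0),
    class = "cluster_labeling"
  )
  t0 <- score_genes(f, lab0)
  expect_identical(t0$gene, names(sort(W[, 2], decreasing = TRUE)))

  lab6 <- structure(
    list(disease_cluster = 2L, normal_cluster = 1L, precision = 0.6),
    class = "cluster_labeling"
  )
  t6 <- score_genes(f, lab6)
  # hand-computed 0.6 * W[,2] + 0.4 * W[,1]
  expected <- sort(setNames(0.6 * W[, 2] + 0.4 * W[, 1], rownames(W)), decreasing = TRUE)
  expect_equal(setNames(t6$score, t6$gene), expected)

  f3 <- structure(list(W = cbind(W, 1), H = matrix(0, 3, 3), rank = 3L), class = "nmf_fit")
  expect_error(score_genes(f3, lab1), "rank-2")
})

test_that("top_genes slices the ranked table within bounds", {
  W <- rbind(a = c(3, 1), b = c(2, 1), c = c(1, 1))
  f <- structure(list(W = W, H = matrix(0, 2, 2), rank = 2L), class = "nmf_fit")
  lab <- structure(
    list(disease_cluster = 1L, normal_cluster = 2L, precision = 1),
    class = "cluster_labeling"
  )
  tab <- score_genes(f, lab)
  expect_identical(top_genes(tab, 1), "a")
  expect_identical(top_genes(tab, 3), c("a", "b", "c"))
  expect_error(top_genes(tab, 0), "must be in \\[1, 3\\]")
  expect_error(top_genes(tab, 4), "must be in \\[1, 3\\]")
})

test_that("entropy comparator score matches hand entropy values and its invariances", {
  W <- rbind(
    pure = c(1, 0),
    uniform = c(0.5, 0.5),
    skew = c(0.75, 0.25),
    zero = c(0, 0)
  )
  expect_warning(s <- kim_entropy_score(W, k = 2), "all-zero basis rows")
  expect_equal(unname(s["pure"]), 1)
  expect_equal(unname(s["uniform"]), 0)
  # 1 - H(0.75) with H in bits
  expect_equal(
    unname(s["skew"]),
    1 + (0.75 * log2(0.75) + 0.25 * log2(0.25)),
    tolerance = 1e-12
  )
  expect_true(is.na(s["zero"]))

  set.seed(12)
  W2 <- matrix(rgamma(30, 1), 10, 3)
  s2 <- kim_entropy_score(W2)
  expect_true(all(s2 >= 0 & s2 <= 1))
  # invariant to positive rescaling of a gene's row
  s2b <- kim_entropy_score(W2 * 7.3)
  expect_equal(s2, s2b, tolerance = 1e-12)
})

test_that("correlation summary counts high-correlation pairs as defined", {
  vals <- rbind(
    a = c(1, 2, 3, 4),
    b = c(2, 4, 6, 8), # identical profile to a (r = 1)
    c = c(4, 3, 2, 1) # perfectly anti-correlated (|r| = 1)
  )
  colnames(vals) <- sprintf("s%d", 1:4)
  m <- expression_matrix(vals, "tpm")
  cs <- correlation_summary(m, c("a", "b", "c"), threshold = 0.75)
  expect_equal(cs$fraction_above, 1)
  expect_equal(cs$mean_abs_r, 1)

  # hand-computed pair: r(a, d) with d = (1, 3, 2, 4)
  vals2 <- rbind(a = c(1, 2, 3, 4), d = c(1, 3, 2, 4))
  colnames(vals2) <- sprintf("s%d", 1:4)
  m2 <- expression_matrix(vals2, "tpm")
  cs2 <- correlation_summary(m2, c("A", "D"), threshold = 0.9) # case-insensitive match
  expect_equal(cs2$mean_abs_r, 0.8)
  expect_equal(cs2$fraction_above, 0)

  noisy <- expression_matrix(
    matrix(runif(12), 3, 4, dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4))),
    "tpm"
  )
  expect_equal(correlation_summary(noisy, c("a", "b", "c"), 1)$fraction_above, 0)

  flat <- rbind(a = c(1, 2, 3, 4), e = c(5, 5, 5, 5), c = c(4, 3, 2, 1))
  colnames(flat) <- sprintf("s%d", 1:4)
  expect_warning(
    cs3 <- correlation_summary(expression_matrix(flat, "tpm"), c("a", "e", "c")),
    "zero-variance"
  )
  expect_equal(cs3$n_genes_used, 2)
})
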