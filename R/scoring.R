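# Precision-weighted gene scoring from the NMF basis matrix: label the two
# sample clusters against the known phenotype, compute the precision of
# the disease cluster, and score every gene as
#   score_i = p * W[i, g+] + (1 - p) * W[i, g-]
# where g+ / g- are the basis columns of the disease / normal clusters and
# p is the fraction of true disease samples in the disease cluster.
# Comparator scores (cluster-entropy) and a correlation summary for top
# gene lists are included as secondary diagnostics.

#' Label the two NMF clusters against known phenotypes
#'
#' The cluster holding the larger fraction of disease samples among its
#' members is labeled the disease cluster `g+`; the other becomes `g-`.
#' The precision `p` is the fraction of disease samples in `g+`. Exact
#' ties in the disease fraction are refused (manual assignment required),
#' as are empty clusters and unlabeled samples.
#'
#' @param assignments Integer cluster indices named by sample id, as from
#'   [assign_clusters()]; exactly two distinct clusters must be present.
#' @param labels Named character vector mapping sample id to `"disease"` /
#'   `"normal"` (see [sample_labels()]).
#' @param k Number of clusters; only `k = 2` (disease vs. normal) is
#'   supported.
#' @return Object of class `cluster_labeling`: `disease_cluster`,
#'   `normal_cluster`, `precision`, and `composition` (per-cluster counts
#'   of disease/normal samples).
#' @export
label_clusters <- function(assignments, labels, k = 2L) {
  if (k != 2L) {
    abort_input("only k = 2 (disease vs. normal) labeling is supported")
  }
  if (is.null(names(assignments))) abort_input("assignments must be named by sample id")
  unlabeled <- setdiff(names(assignments), names(labels))
  if (length(unlabeled)) {
    abort_input(
      "unlabeled sample(s): ", paste(utils::head(unlabeled, 5), collapse = ", "),
      "; exclude them before clustering rather than guessing"
    )
  }
  labels <- labels[names(assignments)]
  clusters <- sort(unique(as.integer(assignments)))
  if (length(clusters) != 2) {
    abort_input(
      "expected exactly 2 occupied clusters, found ", length(clusters),
      " (an empty cluster cannot be labeled)"
    )
  }
  comp <- data.frame(
    cluster = clusters,
    n_disease = vapply(clusters, function(cl) sum(labels[assignments == cl] == "disease"), numeric(1)),
    n_total = vapply(clusters, function(cl) sum(assignments == cl), numeric(1))
  )
  comp$n_normal <- comp$n_total - comp$n_disease
  comp$frac_disease <- comp$n_disease / comp$n_total
  if (comp$frac_disease[1] == comp$frac_disease[2]) {
    abort(
      "both clusters have the same disease fraction (",
      sprintf("%.4g", comp$frac_disease[1]),
      "); assign the disease cluster manually"
    )
  }
  plus <- which.max(comp$frac_disease)
  structure(
    list(
      disease_cluster = comp$cluster[plus],
      normal_cluster = comp$cluster[-plus],
      precision = comp$frac_disease[plus],
      composition = comp[, c("cluster", "n_disease", "n_normal", "n_total", "frac_disease")]
    ),
    class = "cluster_labeling"
  )
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf(
    "Cluster labeling: disease cluster %d (precision %.4f), normal cluster %d\n",
    x$disease_cluster, x$precision, x$normal_cluster
  ))
  print(x$composition, row.names = FALSE)
  invisible(x)
}

#' Precision-weighted gene score
#'
#' `p * W_plus + (1 - p) * W_minus`: a convex combination of a gene's
#' basis weights in the disease and normal metagenes, weighted by the
#' precision of the disease cluster. With a pure disease cluster (p = 1)
#' the score reduces to the disease-metagene weight alone.
#'
#' @param w_plus Basis weight(s) in the disease metagene (>= 0).
#' @param w_minus Basis weight(s) in the normal metagene (>= 0).
#' @param p Precision of the disease cluster, in \[0, 1\].
#' @return Numeric score(s).
#' @export
#' @examples
#' gene_score(20.64, 21.20, p = 1) # 20.64
gene_score <- function(w_plus, w_minus, p) {
  if (any(p < 0) || any(p > 1)) abort_input("precision p must lie in [0, 1]")
  if (any(w_plus < 0) || any(w_minus < 0)) abort_input("basis weights must be >= 0")
  p * w_plus + (1 - p) * w_minus
}

#' Score and rank all genes from a rank-2 factorization
#'
#' Applies [gene_score()] to every row of the basis matrix, using the
#' cluster labeling to pick the disease (`W_plus`) and normal (`W_minus`)
#' basis columns; cluster index c corresponds to basis column c, the same
#' index the sample assignment argmax runs over. Genes are sorted by
#' descending score; ties break by gene id ascending for reproducibility.
#'
#' @param f An `nmf_fit` with `rank == 2`.
#' @param labeling A `cluster_labeling` from [label_clusters()].
#' @return Object of class `gene_score_table`: a `data.frame` with
#'   columns `gene`, `score`, `W_plus`, `W_minus`, sorted descending by
#'   score, carrying the labeling as attribute `labeling`.
#' @export
score_genes <- function(f, labeling) {
  if (!inherits(f, "nmf_fit")) abort_input("f must be an nmf_fit")
  if (f$rank != 2L) {
    abort_input("gene scoring requires a rank-2 factorization (disease vs. normal)")
  }
  gp <- labeling$disease_cluster
  gm <- labeling$normal_cluster
  if (gp > ncol(f$W) || gm > ncol(f$W)) abort_input("labeling cluster index outside basis columns")
  w_plus <- f$W[, gp]
  w_minus <- f$W[, gm]
  score <- gene_score(w_plus, w_minus, labeling$precision)
  tab <- data.frame(
    gene = rownames(f$W),
    score = score,
    W_plus = w_plus,
    W_minus = w_minus,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  tab <- tab[order(-tab$score, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, labeling = labeling, class = c("gene_score_table", "data.frame"))
}

#' Top-ranked genes from a score table
#'
#' @param t A `gene_score_table`.
#' @param n Number of genes, `1 <= n <= nrow(t)`.
#' @return Character vector of the first `n` gene ids.
#' @export
top_genes <- function(t, n) {
  n <- as.integer(n)
  if (n < 1 || n > nrow(t)) {
    abort_input(sprintf("n must be in [1, %d], got %d", nrow(t), n))
  }
  t$gene[seq_len(n)]
}

#' Cluster-entropy comparator gene score
#'
#' The classical sparseness-style score used for subtype marker discovery:
#' each gene's basis row is normalized to a distribution `p(i, q) =
#' W[i, q] / sum_q' W[i, q']` over the k metagenes and scored as
#' `1 + (1 / log2(k)) * sum_q p(i, q) * log2(p(i, q))` (with `0 * log 0 =
#' 0`), i.e. one minus the normalized entropy. Scores lie in \[0, 1\]:
#' 1 when all mass sits in one metagene, 0 for a uniform row. Genes with
#' an all-zero row get `NA` with a warning. Unlike the precision-weighted
#' score this ignores which cluster matches the disease phenotype; it is
#' provided as a comparator, not as the primary ranking.
#'
#' @param W Non-negative basis matrix (genes x k).
#' @param k Number of metagenes (defaults to `ncol(W)`).
#' @return Named numeric vector of per-gene scores.
#' @export
kim_entropy_score <- function(W, k = ncol(W)) {
  W <- as.matrix(W)
  if (any(W < 0)) abort_input("W must be non-negative")
  if (k < 2) abort_input("k must be >= 2")
  rs <- rowSums(W)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero basis rows scored as NA")
  }
  P <- W / ifelse(rs == 0, 1, rs)
  plogp <- ifelse(P > 0, P * log2(P), 0)
  out <- 1 + rowSums(plogp) / log2(k)
  out[zero] <- NA_real_
  stats::setNames(out, rownames(W))
}

#' Pairwise-correlation summary of a gene list
#'
#' Pearson correlations across samples for every unordered pair of the
#' given genes; reports the fraction of pairs with `|r|` above the
#' threshold and the mean `|r|`. Used to compare the redundancy of
#' top-gene lists from different ranking methods. Zero-variance genes are
#' excluded with a warning.
#'
#' @param m `ExpressionMatrix` (>= 3 samples).
#' @param genes Character vector of gene ids (>= 2 present in `m`;
#'   matching is case-insensitive).
#' @param threshold Absolute-correlation threshold (default 0.75).
#' @return List with `fraction_above`, `mean_abs_r`, `n_pairs`,
#'   `n_genes_used`.
#' @export
correlation_summary <- function(m, genes, threshold = 0.75) {
  m <- as_expression_matrix(m)
  if (ncol(m$values) < 3) abort_input("need >= 3 samples for correlation")
  idx <- match(normalize_gene_ids(genes), normalize_gene_ids(m$gene_ids))
  idx <- idx[!is.na(idx)]
  X <- m$values[idx, , drop = FALSE]
  constant <- apply(X, 1, stats::sd) == 0
  if (any(constant)) {
    warning(
      "excluding zero-variance gene(s): ",
      paste(utils::head(rownames(X)[constant], 5), collapse = ", ")
    )
    X <- X[!constant, , drop = FALSE]
  }
  if (nrow(X) < 2) abort_input("need >= 2 usable genes present in the matrix")
  r <- stats::cor(t(X))
  vals <- abs(r[upper.tri(r)])
  list(
    fraction_above = mean(vals > threshold),
    mean_abs_r = mean(vals),
    n_pairs = length(vals),
    n_genes_used = nrow(X)
  )
}
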