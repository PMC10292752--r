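# Consensus clustering over independent NMF runs and the rank-selection
# diagnostics: cophenetic correlation, dispersion, silhouette, explained
# variance and residual divergence.

#' Connectivity matrix of a cluster assignment
#'
#' Binary sample-by-sample matrix with entry (i, j) = 1 iff samples i and
#' j share a cluster. Symmetric with unit diagonal.
#'
#' @param assignments Integer vector of cluster indices (length >= 2),
#'   optionally named by sample id.
#' @return Binary numeric matrix.
#' @export
#' @examples
#' connectivity_matrix(c(1, 1, 2))
connectivity_matrix <- function(assignments) {
  if (length(assignments) < 2) abort_input("need at least 2 samples")
  C <- outer(assignments, assignments, "==") * 1
  dimnames(C) <- list(names(assignments), names(assignments))
  C
}

#' Consensus clustering at a fixed rank over independent NMF runs
#'
#' Runs [nmf_fit()] `n_runs` times with seeds `base_seed`, `base_seed +
#' 1`, ..., assigns samples by [assign_clusters()], and averages the run
#' connectivity matrices into the consensus matrix, whose entry (i, j)
#' estimates the probability that samples i and j co-cluster. Entries near
#' 0 or 1 for all pairs indicate a stable clustering at this rank.
#'
#' @param A `ExpressionMatrix` or non-negative matrix.
#' @param rank Number of metagenes.
#' @param n_runs Number of independent runs (>= 2; default 100).
#' @param base_seed Seed of the first run.
#' @param ... Passed on to [nmf_fit()] (`max_iter`, `tol`, ...).
#' @return An object of class `consensus_result`: `rank`, `consensus`
#'   (M x M), `cophenetic`, `dispersion`, `silhouette`,
#'   `explained_variance` (best run), `mean_residual_D`, `best_run`
#'   (lowest final divergence [nmf_fit()]), `n_runs`, and the per-run
#'   `assignments` matrix (runs x samples).
#' @export
consensus_run <- function(A, rank, n_runs = 100L, base_seed = 1L, ...) {
  A <- as_expression_matrix(A)
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) abort_input("n_runs must be >= 2: a single-run consensus is meaningless")
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  fits <- lapply(seeds, function(s) nmf_fit(A, rank = rank, seed = s, ...))
  assignments <- do.call(rbind, lapply(fits, assign_clusters))
  rownames(assignments) <- paste0("run", seq_len(n_runs))
  C <- Reduce(`+`, lapply(seq_len(n_runs), function(i) {
    connectivity_matrix(assignments[i, ])
  })) / n_runs
  dimnames(C) <- list(A$sample_ids, A$sample_ids)
  finals <- vapply(fits, function(f) f$final_divergence, numeric(1))
  best <- fits[[which.min(finals)]]
  sil <- tryCatch(
    consensus_silhouette(C, k = rank),
    error = function(e) {
      warning("silhouette undefined at rank ", rank, ": ", conditionMessage(e))
      NA_real_
    }
  )
  structure(
    list(
      rank = as.integer(rank),
      consensus = C,
      cophenetic = cophenetic_coefficient(C),
      dispersion = dispersion_coefficient(C),
      silhouette = sil,
      explained_variance = explained_variance(A, best),
      mean_residual_D = mean(finals),
      best_run = best,
      n_runs = n_runs,
      base_seed = as.integer(base_seed),
      assignments = assignments
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Consensus over %d NMF runs at rank %d\n",
      "  cophenetic %.4f | dispersion %.4f | silhouette %.4f\n",
      "  explained variance (best run) %.4f | mean residual D %.6g\n"
    ),
    x$n_runs, x$rank, x$cophenetic, x$dispersion, x$silhouette,
    x$explained_variance, x$mean_residual_D
  ))
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Pearson correlation between the consensus distances `1 - consensus`
#' (off-diagonal pairs) and the cophenetic distances induced by
#' average-linkage hierarchical clustering of those distances. Values near
#' 1 indicate the consensus matrix is nearly ultrametric, i.e. the
#' clustering is reproducible across runs.
#'
#' @param consensus Symmetric matrix in \[0, 1\] with unit diagonal.
#' @return Correlation in \[-1, 1\], or `NA` with a warning when either
#'   distance set has zero variance (e.g. a constant consensus).
#' @export
cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  coph <- stats::cophenetic(stats::hclust(d, method = "average"))
  if (stats::sd(d) == 0 || stats::sd(coph) == 0) {
    warning("cophenetic correlation undefined: zero variance in distances")
    return(NA_real_)
  }
  stats::cor(d, coph)
}

#' Dispersion coefficient of a consensus matrix
#'
#' `mean(4 * (c_ij - 1/2)^2)` over all entries: 1 iff every entry is 0 or
#' 1 (perfectly reproducible co-clustering), 0 when all entries are 1/2.
#'
#' @param consensus Consensus matrix.
#' @return Scalar in \[0, 1\].
#' @export
dispersion_coefficient <- function(consensus) {
  mean(4 * (consensus - 0.5)^2)
}

#' Mean silhouette width of the consensus partition
#'
#' Cuts the average-linkage tree of the consensus distance `1 - consensus`
#' into `k` clusters and returns the mean silhouette width of that
#' partition under the same distance. Near 1 means dense, well-separated
#' clusters.
#'
#' @param consensus Consensus matrix.
#' @param k Number of clusters to cut (normally the NMF rank).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
consensus_silhouette <- function(consensus, k) {
  D <- 1 - consensus
  part <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"), k = k)
  if (length(unique(part)) < 2) {
    abort("consensus partition has a single cluster; silhouette undefined")
  }
  sil <- cluster::silhouette(part, dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Survey NMF ranks by consensus diagnostics
#'
#' Runs [consensus_run()] for each rank and collects the rank-selection
#' metrics. The default selection rule picks the smallest rank attaining
#' the maximum cophenetic coefficient; all metrics are reported so a
#' multi-metric judgment can override it.
#'
#' @param A `ExpressionMatrix` or matrix.
#' @param ranks Increasing integer vector of ranks, each within
#'   `[2, min(dim(A)) - 1]`.
#' @param n_runs Independent runs per rank.
#' @param base_seed Seed of the first run at every rank (runs across ranks
#'   reuse the same seed sequence so ranks are compared on equal footing).
#' @param ... Passed to [nmf_fit()].
#' @return Object of class `rank_survey`: list with `results` (one
#'   `consensus_result` per rank), `metrics` (data frame), and
#'   `selected_rank`.
#' @export
rank_survey <- function(A, ranks = 2:5, n_runs = 100L, base_seed = 1L, ...) {
  ranks <- as.integer(ranks)
  if (is.unsorted(ranks, strictly = TRUE)) abort_input("ranks must be strictly increasing")
  results <- lapply(ranks, function(k) {
    consensus_run(A, rank = k, n_runs = n_runs, base_seed = base_seed, ...)
  })
  metrics <- data.frame(
    rank = ranks,
    cophenetic = vapply(results, `[[`, numeric(1), "cophenetic"),
    dispersion = vapply(results, `[[`, numeric(1), "dispersion"),
    silhouette = vapply(results, `[[`, numeric(1), "silhouette"),
    explained_variance = vapply(results, `[[`, numeric(1), "explained_variance"),
    mean_residual_D = vapply(results, `[[`, numeric(1), "mean_residual_D")
  )
  coph <- metrics$cophenetic
  coph[is.na(coph)] <- -Inf
  selected <- ranks[which(coph == max(coph))[1]]
  structure(
    list(results = results, metrics = metrics, selected_rank = selected),
    class = "rank_survey"
  )
}

#' @export
print.rank_survey <- function(x, ...) {
  cat("NMF rank survey\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  cat("selected rank (max cophenetic, smallest):", x$selected_rank, "\n")
  invisible(x)
}
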