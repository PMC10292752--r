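# Kullback-Leibler NMF by multiplicative updates (the classic scheme used
# for metagene discovery in expression data), plus the derived quantities
# needed downstream: sample cluster assignment and explained variance.

#' Generalized Kullback-Leibler divergence between a matrix and its
#' factorization
#'
#' Computes `D(A || WH) = sum_ij [ A_ij * log(A_ij / (WH)_ij) - A_ij +
#' (WH)_ij ]` with natural logarithms and the convention `0 * log(0/x) =
#' 0`. `D >= 0` with equality iff `WH == A` elementwise.
#'
#' @param A Non-negative numeric matrix (or `ExpressionMatrix`).
#' @param W Non-negative basis matrix, `nrow(A) x k`.
#' @param H Non-negative coefficient matrix, `k x ncol(A)`.
#' @return The divergence, a non-negative scalar.
#' @export
#' @examples
#' kl_divergence(matrix(2), matrix(1), matrix(1)) # 2*log(2) - 1
kl_divergence <- function(A, W, H) {
  A <- em_values(A)
  WH <- W %*% H
  if (any(dim(A) != dim(WH))) abort_input("non-conforming shapes in kl_divergence")
  if (any(A < 0) || any(W < 0) || any(H < 0)) {
    abort_input("kl_divergence requires non-negative A, W, H")
  }
  pos <- A > 0
  if (any(WH[pos] == 0)) {
    abort("(WH)_ij is zero where A_ij > 0; divergence undefined")
  }
  sum(A[pos] * log(A[pos] / WH[pos])) - sum(A) + sum(WH)
}

#' Fit a KL-divergence NMF by multiplicative updates
#'
#' Factorizes a non-negative gene-by-sample matrix `A ~ W %*% H` where `W`
#' (genes x rank) holds the metagene basis and `H` (rank x samples) the
#' per-sample metagene expression. `W` and `H` are initialized with
#' i.i.d. uniform draws scaled by `mean(A)` and refined with the standard
#' multiplicative updates for the generalized KL objective:
#' `H <- H * (t(W) %*% (A/WH)) / colSums(W)` and symmetrically for `W`.
#' These updates never increase the divergence, so the recorded trace is
#' non-increasing up to floating-point tolerance.
#'
#' Iteration stops at `max_iter` or once the relative change in divergence
#' has stayed below `tol` for `n_stable` consecutive checks (checked every
#' `check_every` iterations). Entries of `W`, `H` and the reconstruction
#' are floored at `eps` to keep logarithms and divisions defined.
#'
#' @param A `ExpressionMatrix` or non-negative numeric matrix with
#'   dimnames; must not be all zero.
#' @param rank Number of metagenes `k`; requires `2 <= rank < min(dim(A))`.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param max_iter Maximum number of update sweeps (default 2000).
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param check_every,n_stable Convergence check cadence and the number of
#'   consecutive quiet checks required to stop.
#' @param eps Positivity floor (default 1e-12).
#' @return An object of class `nmf_fit`: list with `W`, `H`, `rank`,
#'   `divergence_trace`, `final_divergence`, `seed`, `n_iter`,
#'   `converged`.
#' @export
nmf_fit <- function(A, rank, seed = 1L, max_iter = 2000L, tol = 1e-6,
                    check_every = 10L, n_stable = 10L, eps = 1e-12) {
  A <- as_expression_matrix(A)
  X <- A$values
  N <- nrow(X)
  M <- ncol(X)
  rank <- as.integer(rank)
  if (rank < 2L) abort_input("rank must be >= 2")
  if (rank >= min(N, M)) {
    abort_input(sprintf("rank (%d) must be < min(dim(A)) = %d", rank, min(N, M)))
  }
  if (all(X == 0)) abort_input("cannot factorize an all-zero matrix")

  scale0 <- mean(X)
  init <- with_seed(seed, list(
    W = matrix(stats::runif(N * rank), N, rank) * scale0,
    H = matrix(stats::runif(rank * M), rank, M) * scale0
  ))
  W <- pmax(init$W, eps)
  H <- pmax(init$H, eps)

  d_last <- kl_divergence(X, W, H)
  trace <- d_last
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WH <- pmax(W %*% H, eps)
    # H update: rows of t(W) %*% (X/WH) divided by column sums of W
    H <- H * (crossprod(W, X / WH) / pmax(colSums(W), eps))
    H <- pmax(H, eps)
    WH <- pmax(W %*% H, eps)
    # W update: columns of (X/WH) %*% t(H) divided by row sums of H
    W <- W * sweep((X / WH) %*% t(H), 2, pmax(rowSums(H), eps), "/")
    W <- pmax(W, eps)
    if (it %% check_every == 0L || it == max_iter) {
      d <- kl_divergence(X, W, H)
      trace <- c(trace, d)
      rel <- abs(d_last - d) / max(abs(d_last), eps)
      d_last <- d
      if (rel < tol) {
        stable <- stable + 1L
        if (stable >= n_stable) {
          converged <- TRUE
          break
        }
      } else {
        stable <- 0L
      }
    }
  }
  dimnames(W) <- list(A$gene_ids, paste0("metagene", seq_len(rank)))
  dimnames(H) <- list(paste0("metagene", seq_len(rank)), A$sample_ids)
  structure(
    list(
      W = W, H = H, rank = rank,
      divergence_trace = trace,
      final_divergence = d_last,
      seed = as.integer(seed), n_iter = it, converged = converged
    ),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "KL-NMF fit: %d genes x %d samples, rank %d\n", nrow(x$W), ncol(x$H), x$rank
  ))
  cat(sprintf(
    "  final divergence %.6g after %d iterations (%s), seed %d\n",
    x$final_divergence, x$n_iter,
    if (x$converged) "converged" else "max_iter reached", x$seed
  ))
  invisible(x)
}

#' Assign samples to clusters from the coefficient matrix
#'
#' Sample `j` is placed in cluster `i` when `H[i, j]` is the largest entry
#' of column `j` of the coefficient matrix. Ties are broken toward the
#' lowest metagene index.
#'
#' @param f An `nmf_fit` (or a coefficient matrix `H`).
#' @return Integer vector of cluster indices, named by sample id.
#' @export
assign_clusters <- function(f) {
  H <- if (inherits(f, "nmf_fit")) f$H else as.matrix(f)
  out <- apply(H, 2, which.max) # which.max takes the first maximum: tie rule
  stats::setNames(as.integer(out), colnames(H))
}

#' Fraction of total variation explained by the reconstruction
#'
#' `1 - sum((A - WH)^2) / sum(A^2)`; equals 1 iff the reconstruction is
#' exact and 0 when `WH` is identically zero.
#'
#' @param A The factorized matrix (`ExpressionMatrix` or matrix).
#' @param f An `nmf_fit` for `A`.
#' @return A scalar in `(-Inf, 1]`.
#' @export
explained_variance <- function(A, f) {
  X <- em_values(A)
  WH <- f$W %*% f$H
  if (any(dim(X) != dim(WH))) abort_input("fit does not match matrix dimensions")
  1 - sum((X - WH)^2) / sum(X^2)
}
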