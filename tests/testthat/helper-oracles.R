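# Independent oracles and small fixture builders used across the tests.
# These deliberately re-derive quantities from first principles (naive
# loops, explicit agglomeration) so they share no code with the package
# implementations they check.

# Exact rank-2 matrix with two well-separated sample blocks.
planted_rank2 <- function(n_genes = 6, n_samples = 4, seed = 99, eps = 0.02) {
  set.seed(seed)
  W0 <- matrix(runif(n_genes * 2, 0.5, 2), n_genes, 2)
  half <- floor(n_samples / 2)
  H0 <- matrix(eps, 2, n_samples)
  H0[1, seq_len(half)] <- 1
  H0[2, seq(half + 1, n_samples)] <- 1
  A <- W0 %*% H0
  dimnames(A) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n_samples))
  list(A = A, W = W0, H = H0, partition = rep(1:2, c(half, n_samples - half)))
}

# Naive average-linkage agglomeration returning the full ultrametric
# cophenetic distance matrix. O(n^3) but independent of stats::hclust.
brute_ultrametric <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, length(members))
  dist_cl <- function(a, b) mean(D[members[[a]], members[[b]], drop = FALSE])
  U <- matrix(0, n, n)
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in idx) {
      for (j in idx) {
        if (i < j) {
          d <- dist_cl(i, j)
          if (d < best_d) {
            best_d <- d
            best <- c(i, j)
          }
        }
      }
    }
    a <- best[1]
    b <- best[2]
    U[members[[a]], members[[b]]] <- best_d
    U[members[[b]], members[[a]]] <- best_d
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
  }
  U
}

# Silhouette widths computed directly from the definition.
brute_silhouette <- function(D, part) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(part == part[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(
      setdiff(unique(part), part[i]),
      function(cl) mean(D[i, part == cl]),
      numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Adjusted Rand index between two partitions (contingency formula).
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c2 / choose(n, 2)
  (a - expected) / ((b + c2) / 2 - expected)
}

# Small labeled ExpressionMatrix for I/O round trips.
toy_matrix <- function() {
  m <- matrix(
    c(1.5, 0, 3, 2, 4.25, 0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("Lyz2", "Apoe", "Cryab"), c("s1", "s2"))
  )
  expression_matrix(m, "tpm")
}
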