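# Enrichment-ratio benchmarking: DEG threshold filtering, the reference-set
# enrichment ratio (g/n)/(G/N), and the matched top-n comparison of
# NMF-ranked genes against DEG lists with a Welch t-test on mean ratios.

#' Differential-expression significance threshold
#'
#' @param max_adjusted_p Upper bound (strict) on the adjusted p-value, in
#'   (0, 1\].
#' @param min_abs_logfc Optional lower bound (strict) on `|log2 FC|`.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(max_adjusted_p, min_abs_logfc = NULL) {
  if (max_adjusted_p <= 0 || max_adjusted_p > 1) {
    abort_input("max_adjusted_p must lie in (0, 1]")
  }
  if (!is.null(min_abs_logfc) && min_abs_logfc < 0) {
    abort_input("min_abs_logfc must be >= 0")
  }
  structure(
    list(max_adjusted_p = max_adjusted_p, min_abs_logfc = min_abs_logfc),
    class = "threshold_spec"
  )
}

#' @export
format.threshold_spec <- function(x, ...) {
  if (is.null(x$min_abs_logfc)) {
    sprintf("FDR<%g", x$max_adjusted_p)
  } else {
    sprintf("FDR<%g & |logFC|>%g", x$max_adjusted_p, x$min_abs_logfc)
  }
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' The default 8-threshold significance grid
#'
#' Adjusted-p cutoffs 0.05 and 0.01 crossed with no fold-change filter and
#' `|log2 FC|` above 0.5, 1 and 1.5.
#'
#' @return List of [threshold_spec()] objects.
#' @export
default_threshold_grid <- function() {
  list(
    threshold_spec(0.05, NULL),
    threshold_spec(0.05, 1),
    threshold_spec(0.01, NULL),
    threshold_spec(0.01, 1),
    threshold_spec(0.05, 0.5),
    threshold_spec(0.05, 1.5),
    threshold_spec(0.01, 0.5),
    threshold_spec(0.01, 1.5)
  )
}

#' Parse a threshold grid from its compact string form
#'
#' Format: semicolon-separated `p:fc` pairs where `fc` may be empty, e.g.
#' `"0.05:;0.05:1"` for FDR<0.05 and FDR<0.05 & |logFC|>1.
#'
#' @param s Specification string.
#' @return List of [threshold_spec()] objects.
#' @export
parse_threshold_specs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    fc <- if (length(bits) < 2 || !nzchar(bits[2])) NULL else as.numeric(bits[2])
    threshold_spec(as.numeric(bits[1]), fc)
  })
}

#' Serialize a threshold grid to its compact string form
#'
#' @param specs List of [threshold_spec()] objects.
#' @return Specification string accepted by [parse_threshold_specs()].
#' @export
format_threshold_specs <- function(specs) {
  paste(vapply(specs, function(sp) {
    sprintf("%g:%s", sp$max_adjusted_p,
            if (is.null(sp$min_abs_logfc)) "" else sprintf("%g", sp$min_abs_logfc))
  }, character(1)), collapse = ";")
}

#' Filter a DE table by a significance threshold
#'
#' Keeps genes with `adj_p < max_adjusted_p` and, when the spec sets a
#' fold-change bound, `|logFC| > min_abs_logfc`. Both inequalities are
#' strict.
#'
#' @param t DE table (`data.frame` with `gene`, `logFC`, `adj_p`).
#' @param spec A [threshold_spec()].
#' @return Character vector of passing gene ids.
#' @export
filter_de_table <- function(t, spec) {
  t <- de_table(t)
  keep <- t$adj_p < spec$max_adjusted_p
  if (!is.null(spec$min_abs_logfc)) {
    keep <- keep & abs(t$logFC) > spec$min_abs_logfc
  }
  t$gene[keep]
}

#' Reference-set enrichment ratio
#'
#' `(g/n) / (G/N)`: the over-representation of a `G`-gene reference set
#' within an `n`-gene selected list (of which `g` overlap the reference)
#' relative to an `N`-gene universe. 1 means no enrichment.
#'
#' @param g Overlap between the selected list and the reference set.
#' @param n Size of the selected list (>= 1).
#' @param G Size of the reference set (>= 1).
#' @param N Size of the gene universe (>= 1).
#' @return The enrichment ratio.
#' @export
#' @examples
#' enrichment_ratio(198, 4088, 749, 20459) # ~1.32
enrichment_ratio <- function(g, n, G, N) {
  if (n < 1 || G < 1 || N < 1) abort_input("n, G and N must all be >= 1")
  if (g < 0 || g > min(n, G)) abort_input("g must lie in [0, min(n, G)]")
  if (n > N || G > N) abort_input("n and G cannot exceed the universe size N")
  (g / n) / (G / N)
}

#' Overlap between two gene lists
#'
#' Size of the intersection after identifier normalization
#' (case-insensitive, whitespace-trimmed).
#'
#' @param list_a,reference Character vectors of gene ids.
#' @return Integer overlap count.
#' @export
overlap_count <- function(list_a, reference) {
  length(intersect(
    unique(normalize_gene_ids(list_a)),
    unique(normalize_gene_ids(reference))
  ))
}

#' Matched comparison of NMF-ranked genes against DEG lists
#'
#' For each significance threshold the DEG list is computed from the DE
#' table; an equal number `n` of top-ranked genes is then taken from the
#' NMF score table so both methods are compared at matched list sizes.
#' Both lists are intersected with the reference set and converted to
#' enrichment ratios via [enrichment_ratio()]. The two ratio columns are
#' averaged (unrounded) and compared with Welch's unequal-variance
#' two-sample t-test. Thresholds yielding an empty DEG list are flagged
#' and excluded from the means with a warning.
#'
#' @param score_table A `gene_score_table` from [score_genes()].
#' @param de_tab DE table (`gene`, `logFC`, `adj_p`).
#' @param specs List of [threshold_spec()]; defaults to
#'   [default_threshold_grid()].
#' @param reference Character vector: the disease reference gene set.
#' @param N Universe size; defaults to the number of genes in the score
#'   table (the genes surviving the expression filter).
#' @param G Reference-set size; defaults to `length(unique(reference))`
#'   after normalization.
#' @return Object of class `enrichment_report`: `rows` (one line per
#'   threshold: `threshold`, `n`, `g_deg`, `ratio_deg`, `g_nmf`,
#'   `ratio_nmf`, `included`), `G`, `N`, `mean_ratio_deg`,
#'   `mean_ratio_nmf`, `t_test_p`.
#' @export
matched_comparison <- function(score_table, de_tab,
                               specs = default_threshold_grid(),
                               reference, N = nrow(score_table),
                               G = length(unique(normalize_gene_ids(reference)))) {
  de_tab <- de_table(de_tab)
  rows <- lapply(specs, function(sp) {
    deg <- filter_de_table(de_tab, sp)
    n <- length(deg)
    if (n == 0) {
      warning("threshold ", format(sp), " selects no genes; excluded from means")
      return(data.frame(
        threshold = format(sp), n = 0L, g_deg = NA_integer_, ratio_deg = NA_real_,
        g_nmf = NA_integer_, ratio_nmf = NA_real_, included = FALSE,
        stringsAsFactors = FALSE
      ))
    }
    if (n > nrow(score_table)) {
      warning(
        "threshold ", format(sp), " selects more genes (", n,
        ") than the score table holds; capping at ", nrow(score_table)
      )
      n <- nrow(score_table)
    }
    g_deg <- overlap_count(deg, reference)
    nmf_genes <- top_genes(score_table, n)
    g_nmf <- overlap_count(nmf_genes, reference)
    data.frame(
      threshold = format(sp), n = as.integer(n),
      g_deg = as.integer(g_deg), ratio_deg = enrichment_ratio(g_deg, n, G, N),
      g_nmf = as.integer(g_nmf), ratio_nmf = enrichment_ratio(g_nmf, n, G, N),
      included = TRUE, stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows)
  used <- rows[rows$included, , drop = FALSE]
  if (nrow(used) == 0) abort("every threshold produced an empty DEG list")
  t_p <- tryCatch(
    stats::t.test(used$ratio_deg, used$ratio_nmf, var.equal = FALSE)$p.value,
    error = function(e) {
      warning("t-test degenerate (", conditionMessage(e), "); p set to NA")
      NA_real_
    }
  )
  structure(
    list(
      rows = rows, G = as.integer(G), N = as.integer(N),
      mean_ratio_deg = mean(used$ratio_deg),
      mean_ratio_nmf = mean(used$ratio_nmf),
      t_test_p = t_p
    ),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "Enrichment comparison (reference G = %d, universe N = %d)\n", x$G, x$N
  ))
  out <- x$rows
  out$ratio_deg <- round(out$ratio_deg, 2)
  out$ratio_nmf <- round(out$ratio_nmf, 2)
  print(out[, c("threshold", "n", "g_deg", "ratio_deg", "g_nmf", "ratio_nmf")],
        row.names = FALSE)
  cat(sprintf(
    "mean enrichment ratio: DEG %.2f vs NMF %.2f (Welch t-test p = %.3g)\n",
    x$mean_ratio_deg, x$mean_ratio_nmf, x$t_test_p
  ))
  invisible(x)
}

#' Per-gene two-group Welch test (convenience DE)
#'
#' A simple per-gene differential-expression test: for each gene, the
#' difference in group means (disease minus normal, interpreted as log2
#' fold change when the matrix is on a log2 scale), a Welch two-sample
#' t-test, and Benjamini-Hochberg adjustment across genes. This is a
#' lightweight convenience for synthetic and exploratory data, not a
#' replacement for a moderated pipeline such as limma-voom; tables from
#' such tools can be supplied directly via [read_de_table()].
#'
#' Genes with zero variance in both groups get `p = 1` when the group
#' means agree (and 0 otherwise) and are counted in a warning.
#'
#' @param m `ExpressionMatrix`, normally on the log2 scale.
#' @param labels Sample label map (`"disease"` / `"normal"`); every
#'   labeled sample must exist in `m`, and each group needs >= 2 samples.
#' @return DE table `data.frame` with `gene`, `logFC`, `adj_p`, plus the
#'   raw `p_value`.
#' @export
simple_de_test <- function(m, labels) {
  m <- as_expression_matrix(m)
  labels <- labels[intersect(names(labels), m$sample_ids)]
  d_ids <- names(labels)[labels == "disease"]
  n_ids <- names(labels)[labels == "normal"]
  if (length(d_ids) < 2 || length(n_ids) < 2) {
    abort_input("need >= 2 samples per group for the two-group test")
  }
  X1 <- m$values[, d_ids, drop = FALSE]
  X2 <- m$values[, n_ids, drop = FALSE]
  n1 <- ncol(X1)
  n2 <- ncol(X2)
  m1 <- rowMeans(X1)
  m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero variance in both groups")
  }
  tstat <- (m1 - m2) / sqrt(ifelse(degenerate, 1, se2))
  # Welch-Satterthwaite: df = se2^2 / ((v1/n1)^2/(n1-1) + (v2/n2)^2/(n2-1))
  denom <- (v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)
  df <- ifelse(degenerate | denom == 0, Inf, se2^2 / denom)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  de_tab <- data.frame(
    gene = m$gene_ids,
    logFC = m1 - m2,
    adj_p = stats::p.adjust(p, method = "BH"),
    p_value = p,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  de_tab
}
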