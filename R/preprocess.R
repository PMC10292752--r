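# Preprocessing: TPM normalization, log2(TPM + 1) rescaling, and the
# expressed-in-at-least-k-samples filter applied before factorization.

#' Convert read counts to transcripts per million (TPM)
#'
#' Per sample, counts are first divided by gene length in kilobases
#' (reads per kilobase), then scaled so the column sums to one million:
#' `TPM_i = rate_i / sum_j(rate_j) * 1e6` with `rate_i = count_i /
#' (length_i / 1000)`.
#'
#' @param counts An `ExpressionMatrix` with `scale_tag == "counts"`.
#' @param gene_lengths Named numeric vector of gene lengths in bases; every
#'   gene in `counts` must be present with a positive length.
#' @return An `ExpressionMatrix` with `scale_tag == "tpm"`. All-zero sample
#'   columns are left all-zero with a warning.
#' @export
tpm_transform <- function(counts, gene_lengths) {
  counts <- as_expression_matrix(counts, "counts")
  if (counts$scale_tag != "counts") {
    abort_input("tpm_transform expects a counts matrix, got scale '", counts$scale_tag, "'")
  }
  missing_len <- setdiff(counts$gene_ids, names(gene_lengths))
  if (length(missing_len)) {
    abort_input(
      "missing gene length for: ",
      paste(utils::head(missing_len, 10), collapse = ", "),
      if (length(missing_len) > 10) sprintf(" (and %d more)", length(missing_len) - 10) else ""
    )
  }
  len <- as.numeric(gene_lengths[counts$gene_ids])
  if (any(!is.finite(len)) || any(len <= 0)) {
    abort_input("gene lengths must be positive and finite")
  }
  rate <- counts$values / (len / 1000)
  tot <- colSums(rate)
  zero_cols <- tot == 0
  if (any(zero_cols)) {
    warning(
      "all-zero sample column(s) left all-zero: ",
      paste(counts$sample_ids[zero_cols], collapse = ", ")
    )
    tot[zero_cols] <- 1 # keeps the column zero instead of NaN
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(tpm, "tpm")
}

#' Rescale TPM values to log2(TPM + 1)
#'
#' @param m An `ExpressionMatrix` with `scale_tag == "tpm"`.
#' @return An `ExpressionMatrix` with entries `log2(x + 1)` and
#'   `scale_tag == "log2_tpm_plus1"`.
#' @export
log2_rescale <- function(m) {
  m <- as_expression_matrix(m)
  if (m$scale_tag != "tpm") {
    abort_input("log2_rescale expects a TPM matrix, got scale '", m$scale_tag, "'")
  }
  expression_matrix(log2(m$values + 1), "log2_tpm_plus1")
}

#' Drop genes expressed in too few samples
#'
#' A gene is "expressed" in a sample when its value is strictly positive.
#' Genes expressed in fewer than `min_samples` samples are removed; the
#' sample set is unchanged. The number of removed genes is reported via
#' `message()` and attached as attribute `n_removed`.
#'
#' @param m An `ExpressionMatrix`.
#' @param min_samples Minimum number of samples with positive expression a
#'   gene must reach to be kept (default 5).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_low_expression <- function(m, min_samples = 5L) {
  m <- as_expression_matrix(m)
  if (min_samples < 0) abort_input("min_samples must be >= 0")
  keep <- rowSums(m$values > 0) >= min_samples
  n_removed <- sum(!keep)
  if (all(!keep)) abort_input("no genes survive the expression filter")
  message(sprintf(
    "filter_low_expression: removed %d of %d genes (expressed in < %d samples)",
    n_removed, length(keep), min_samples
  ))
  out <- expression_matrix(m$values[keep, , drop = FALSE], m$scale_tag)
  attr(out, "n_removed") <- n_removed
  out
}
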