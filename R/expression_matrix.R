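# ExpressionMatrix: the gene-by-sample container consumed by every stage.

#' Construct an expression matrix
#'
#' A light container for a non-negative gene-by-sample matrix `A` (N genes
#' by M samples) together with a tag recording the measurement scale. The
#' factorization, scoring and benchmarking functions all consume this type.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names. All entries must be finite and `>= 0`.
#' @param scale_tag One of `"counts"`, `"tpm"`, `"log2_tpm_plus1"`.
#' @return An object of class `ExpressionMatrix` with fields `values`,
#'   `gene_ids`, `sample_ids` and `scale_tag`.
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' expression_matrix(m, "counts")
expression_matrix <- function(values,
                              scale_tag = c("counts", "tpm", "log2_tpm_plus1")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    abort_input("expression matrix entries must be numeric")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_input("expression matrix requires gene row names and sample column names")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values) | is.na(values), arr.ind = TRUE)[1, ]
    abort_input(sprintf(
      "missing or non-finite entry at gene '%s', sample '%s'",
      rownames(values)[bad[1]], colnames(values)[bad[2]]
    ))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort_input(sprintf(
      "negative entry %.6g at gene '%s', sample '%s'",
      values[bad[1], bad[2]], rownames(values)[bad[1]], colnames(values)[bad[2]]
    ))
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    abort_input("duplicate gene ids: ", paste(utils::head(dup_g, 5), collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    abort_input("duplicate sample ids: ", paste(utils::head(dup_s, 5), collapse = ", "))
  }
  structure(
    list(
      values = values,
      gene_ids = rownames(values),
      sample_ids = colnames(values),
      scale_tag = scale_tag
    ),
    class = "ExpressionMatrix"
  )
}

#' Coerce to an expression matrix
#'
#' @param x A numeric matrix with dimnames, or an `ExpressionMatrix`.
#' @param scale_tag Scale tag used when `x` is a plain matrix.
#' @return An `ExpressionMatrix`.
#' @export
as_expression_matrix <- function(x, scale_tag = "tpm") {
  if (inherits(x, "ExpressionMatrix")) return(x)
  expression_matrix(x, scale_tag)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Extract the numeric matrix from an ExpressionMatrix
#'
#' @param x An `ExpressionMatrix` or plain numeric matrix.
#' @return The underlying numeric matrix.
#' @export
em_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
    nrow(x$values), ncol(x$values), x$scale_tag
  ))
  cat(
    "genes:  ", paste(utils::head(x$gene_ids, 4), collapse = ", "),
    if (length(x$gene_ids) > 4) ", ..." else "", "\n",
    sep = ""
  )
  cat(
    "samples:", paste(utils::head(x$sample_ids, 4), collapse = ", "),
    if (length(x$sample_ids) > 4) ", ..." else "", "\n"
  )
  invisible(x)
}
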