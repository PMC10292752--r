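# Readers and writers for the tabular interchange formats: expression
# matrices (TSV/CSV, genes as rows), sample label maps, plain-text gene
# lists, and differential-expression result tables.

#' Read a gene-by-sample expression matrix from delimited text
#'
#' The first column must hold gene identifiers and the header row sample
#' identifiers. The delimiter is auto-detected between tab and comma unless
#' `sep` is given. Negative, missing or non-numeric cells are rejected.
#'
#' @param path Path to a TSV/CSV file.
#' @param scale_tag Measurement scale of the stored values; see
#'   [expression_matrix()].
#' @param sep Optional explicit field separator (`"\t"` or `","`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale_tag = "tpm", sep = NULL) {
  if (!file.exists(path)) abort_input("expression matrix file not found: ", path)
  dt <- if (is.null(sep)) {
    data.table::fread(path, header = TRUE, data.table = FALSE)
  } else {
    data.table::fread(path, header = TRUE, sep = sep, data.table = FALSE)
  }
  if (ncol(dt) < 2) abort_input("expression matrix needs a gene column plus >= 1 sample column")
  genes <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num)) {
    abort_input("non-numeric expression column(s): ", paste(non_num, collapse = ", "))
  }
  values <- as.matrix(vals)
  rownames(values) <- genes
  expression_matrix(values, scale_tag = scale_tag)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips values and
#' identifiers exactly (up to 15 significant digits).
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  m <- as_expression_matrix(m)
  df <- data.frame(gene = m$gene_ids, m$values, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read sample group labels
#'
#' Two-column delimited file mapping `sample_id` to a group name. Group
#' names are mapped onto the internal labels `disease` / `normal`.
#'
#' @param path Path to a two-column TSV/CSV (header optional; detected by
#'   whether the second field of the first line is a known group name).
#' @param disease_label,normal_label Group names used in the file.
#' @return Named character vector with values `"disease"` or `"normal"`,
#'   names being sample ids.
#' @export
read_sample_labels <- function(path, disease_label = "glaucoma",
                               normal_label = "normal") {
  if (!file.exists(path)) abort_input("labels file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 2) abort_input("labels file needs two columns: sample_id, group")
  # tolerate an optional header row: drop it when its group field is unknown
  if (nrow(dt) > 1 && !(dt[1, 2] %in% c(disease_label, normal_label))) {
    dt <- dt[-1, , drop = FALSE]
  }
  sample_labels(
    stats::setNames(as.character(dt[[2]]), as.character(dt[[1]])),
    disease_label = disease_label, normal_label = normal_label
  )
}

#' Construct a sample label map
#'
#' @param x Named character vector mapping sample id to group name.
#' @param disease_label,normal_label Group names in `x` corresponding to
#'   the disease and normal groups.
#' @return Named character vector with values `"disease"` / `"normal"`.
#' @export
sample_labels <- function(x, disease_label = "disease", normal_label = "normal") {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort_input("sample labels must be named by sample id")
  }
  known <- c(disease_label, normal_label)
  bad <- setdiff(unique(x), known)
  if (length(bad)) {
    abort_input(
      "unknown group name(s): ", paste(bad, collapse = ", "),
      " (expected '", disease_label, "' or '", normal_label, "')"
    )
  }
  out <- ifelse(x == disease_label, "disease", "normal")
  names(out) <- names(x)
  if (!any(out == "disease") || !any(out == "normal")) {
    abort_input("need at least one sample in each group")
  }
  out
}

#' Read a plain-text gene list
#'
#' One identifier per line; `#` starts a comment; blank lines are skipped.
#' Entries that collide after identifier normalization (case-folding,
#' whitespace trimming) are de-duplicated keeping the first spelling.
#'
#' @param path Path to the gene list file.
#' @return Character vector of gene identifiers (original spellings).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort_input("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines[!duplicated(normalize_gene_ids(lines))]
}

#' Write a plain-text gene list
#'
#' @param genes Character vector of gene identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' Expects columns for the gene id, the log2 fold change, and the adjusted
#' p-value. Column names can be remapped for tables produced by other
#' tools (e.g. limma's `logFC` / `adj.P.Val`).
#'
#' @param path Path to a delimited table.
#' @param gene_col,logfc_col,p_col Column names holding the gene id, log2
#'   fold change and adjusted p-value.
#' @return A `data.frame` with columns `gene`, `logFC`, `adj_p` (a
#'   "DE table"), validated for unique genes and `adj_p` in \[0, 1\].
#' @export
read_de_table <- function(path, gene_col = "gene", logfc_col = "logFC",
                          p_col = "adj_p") {
  if (!file.exists(path)) abort_input("DE table file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c(gene_col, logfc_col, p_col)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    abort_input("DE table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  de_table(data.frame(
    gene = as.character(dt[[gene_col]]),
    logFC = as.numeric(dt[[logfc_col]]),
    adj_p = as.numeric(dt[[p_col]]),
    stringsAsFactors = FALSE
  ))
}

#' Validate a differential-expression table
#'
#' @param df Data frame with columns `gene`, `logFC`, `adj_p`.
#' @return The validated data frame.
#' @export
de_table <- function(df) {
  need <- c("gene", "logFC", "adj_p")
  if (!all(need %in% names(df))) {
    abort_input("DE table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene)) {
    dup <- unique(df$gene[duplicated(df$gene)])
    abort_input("duplicate genes in DE table: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyNA(df$adj_p) || any(df$adj_p < 0 | df$adj_p > 1)) {
    abort_input("adjusted p-values must lie in [0, 1]")
  }
  df[, need]
}
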