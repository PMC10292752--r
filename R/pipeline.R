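# End-to-end pipeline: (simulated or file) inputs -> expression filter ->
# rank survey -> cluster labeling -> gene scoring -> matched enrichment
# comparison, with all artifacts written to a run directory.

#' Pipeline run configuration
#'
#' All paths may be `NULL` when `simulate` is given. The configuration
#' round-trips losslessly through [write_run_config()] /
#' [read_run_config()].
#'
#' @param matrix_path,labels_path,reference_path,de_table_path Input file
#'   paths ([read_expression_matrix()], [read_sample_labels()],
#'   [read_gene_list()], [read_de_table()]). When `de_table_path` is
#'   `NULL`, the convenience [simple_de_test()] is used on the log2 scale.
#' @param scale_tag Scale of the stored matrix.
#' @param nmf_scale Matrix scale fed to the factorization: `"as-is"`
#'   (default, TPM in the standard workflow) or `"log2"` to rescale first.
#' @param ranks Integer vector of candidate ranks.
#' @param n_runs NMF runs per rank for the consensus.
#' @param seed Top-level seed; per-stage seeds derive from it.
#' @param min_samples Expression-filter threshold.
#' @param specs Threshold grid (list of [threshold_spec()]).
#' @param universe_size Optional override of the enrichment universe `N`
#'   (defaults to the number of genes surviving the filter).
#' @param simulate Optional [synthetic_spec()]; when set, inputs are
#'   generated instead of read and the planted markers become the
#'   reference set.
#' @param out_dir Output directory for artifacts.
#' @param max_iter Per-fit iteration cap passed to [nmf_fit()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(matrix_path = NULL, labels_path = NULL,
                       reference_path = NULL, de_table_path = NULL,
                       scale_tag = "tpm", nmf_scale = c("as-is", "log2"),
                       ranks = 2:5, n_runs = 100L, seed = 42L,
                       min_samples = 5L, specs = default_threshold_grid(),
                       universe_size = NULL, simulate = NULL,
                       out_dir = "nmfmarker_run", max_iter = 2000L) {
  nmf_scale <- match.arg(nmf_scale)
  structure(
    list(
      matrix_path = matrix_path, labels_path = labels_path,
      reference_path = reference_path, de_table_path = de_table_path,
      scale_tag = scale_tag, nmf_scale = nmf_scale,
      ranks = as.integer(ranks), n_runs = as.integer(n_runs),
      seed = as.integer(seed), min_samples = as.integer(min_samples),
      specs = specs, universe_size = universe_size,
      simulate = simulate, out_dir = out_dir, max_iter = as.integer(max_iter)
    ),
    class = "run_config"
  )
}

#' Write a run configuration as flat key-value text
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  kv <- c(
    matrix_path = config$matrix_path %||% "",
    labels_path = config$labels_path %||% "",
    reference_path = config$reference_path %||% "",
    de_table_path = config$de_table_path %||% "",
    scale_tag = config$scale_tag,
    nmf_scale = config$nmf_scale,
    ranks = paste(range(config$ranks), collapse = ":"),
    n_runs = as.character(config$n_runs),
    seed = as.character(config$seed),
    min_samples = as.character(config$min_samples),
    specs = format_threshold_specs(config$specs),
    universe_size = if (is.null(config$universe_size)) "" else as.character(config$universe_size),
    out_dir = config$out_dir,
    max_iter = as.character(config$max_iter)
  )
  writeLines(paste0(names(kv), "=", unname(kv)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from flat key-value text
#'
#' @param path Path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  blank_null <- function(x) if (is.null(x) || !nzchar(x)) NULL else x
  rr <- as.integer(strsplit(vals[["ranks"]], ":", fixed = TRUE)[[1]])
  run_config(
    matrix_path = blank_null(vals[["matrix_path"]]),
    labels_path = blank_null(vals[["labels_path"]]),
    reference_path = blank_null(vals[["reference_path"]]),
    de_table_path = blank_null(vals[["de_table_path"]]),
    scale_tag = vals[["scale_tag"]],
    nmf_scale = vals[["nmf_scale"]],
    ranks = rr[1]:rr[2],
    n_runs = as.integer(vals[["n_runs"]]),
    seed = as.integer(vals[["seed"]]),
    min_samples = as.integer(vals[["min_samples"]]),
    specs = parse_threshold_specs(vals[["specs"]]),
    universe_size = if (nzchar(vals[["universe_size"]])) as.integer(vals[["universe_size"]]) else NULL,
    out_dir = vals[["out_dir"]],
    max_iter = as.integer(vals[["max_iter"]])
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full marker-discovery pipeline
#'
#' Stages: load (or simulate) inputs; filter low-expression genes; survey
#' ranks by consensus diagnostics; label the clusters of the selected
#' rank's best run against the phenotype; score and rank genes; build (or
#' load) a DE table; and compare NMF-ranked genes against DEG lists over
#' the threshold grid. Artifacts written under `config$out_dir`:
#' `gene_scores.tsv`, `rank_metrics.tsv`, `consensus_rank<k>.tsv` per
#' rank, `labeling.json`, `enrichment_table.tsv`, `summary.json`,
#' `run.log`.
#'
#' @param config A [run_config()].
#' @return The `enrichment_report`, invisibly, with attribute `artifacts`
#'   (named vector of output paths) and `survey` (the rank survey).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      note("simulating dataset (seed ", config$simulate$seed, ")")
      ds <- generate_dataset(config$simulate)
      list(
        m = ds$matrix, labels = ds$labels, reference = ds$markers,
        de_tab = NULL
      )
    } else {
      if (is.null(config$matrix_path)) abort_input("no matrix_path and no simulate spec")
      if (is.null(config$labels_path)) abort_input("labels_path is required")
      if (is.null(config$reference_path)) abort_input("reference_path is required")
      list(
        m = read_expression_matrix(config$matrix_path, config$scale_tag),
        labels = read_sample_labels(config$labels_path),
        reference = read_gene_list(config$reference_path),
        de_tab = if (!is.null(config$de_table_path)) read_de_table(config$de_table_path) else NULL
      )
    }
  })

  m <- inputs$m
  labeled <- intersect(m$sample_ids, names(inputs$labels))
  if (length(labeled) < length(m$sample_ids)) {
    note("dropping ", length(m$sample_ids) - length(labeled), " unlabeled sample(s)")
    m <- expression_matrix(m$values[, labeled, drop = FALSE], m$scale_tag)
  }

  m <- stage("filter", filter_low_expression(m, config$min_samples))
  note("matrix after filter: ", nrow(m$values), " genes x ", ncol(m$values), " samples")

  nmf_input <- if (config$nmf_scale == "log2") {
    stage("rescale", log2_rescale(m))
  } else {
    m
  }

  survey <- stage("rank_survey", rank_survey(
    nmf_input,
    ranks = config$ranks, n_runs = config$n_runs,
    base_seed = config$seed, max_iter = config$max_iter
  ))
  note("selected rank: ", survey$selected_rank)
  utils::write.table(
    survey$metrics, file.path(out, "rank_metrics.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (res in survey$results) {
    utils::write.table(
      data.frame(sample = rownames(res$consensus), res$consensus, check.names = FALSE),
      file.path(out, sprintf("consensus_rank%d.tsv", res$rank)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  best <- survey$results[[match(survey$selected_rank, survey$metrics$rank)]]
  labeling <- stage("label", label_clusters(
    assign_clusters(best$best_run), inputs$labels
  ))
  note("disease cluster ", labeling$disease_cluster,
       ", precision ", sprintf("%.4f", labeling$precision))
  jsonlite::write_json(
    list(
      disease_cluster = labeling$disease_cluster,
      normal_cluster = labeling$normal_cluster,
      precision = labeling$precision,
      composition = labeling$composition
    ),
    file.path(out, "labeling.json"),
    auto_unbox = TRUE, digits = NA
  )

  scores <- stage("score", score_genes(best$best_run, labeling))
  utils::write.table(
    scores, file.path(out, "gene_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  de_tab <- stage("de", {
    if (!is.null(inputs$de_tab)) {
      inputs$de_tab
    } else {
      note("no DE table supplied; using the convenience two-group Welch test")
      logm <- if (m$scale_tag == "log2_tpm_plus1") {
        m
      } else {
        expression_matrix(log2(m$values + 1), "log2_tpm_plus1")
      }
      simple_de_test(logm, inputs$labels)
    }
  })

  report <- stage("compare", matched_comparison(
    scores, de_tab,
    specs = config$specs, reference = inputs$reference,
    N = config$universe_size %||% nrow(scores)
  ))
  utils::write.table(
    report$rows, file.path(out, "enrichment_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(
      selected_rank = survey$selected_rank,
      precision = labeling$precision,
      n_genes = nrow(scores),
      universe_size = report$N,
      reference_size = report$G,
      mean_ratio_deg = report$mean_ratio_deg,
      mean_ratio_nmf = report$mean_ratio_nmf,
      t_test_p = report$t_test_p
    ),
    file.path(out, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  note("done; artifacts in ", out)
  writeLines(log_lines, log_path)

  artifacts <- c(
    gene_scores = file.path(out, "gene_scores.tsv"),
    rank_metrics = file.path(out, "rank_metrics.tsv"),
    labeling = file.path(out, "labeling.json"),
    enrichment_table = file.path(out, "enrichment_table.tsv"),
    summary = file.path(out, "summary.json"),
    log = log_path
  )
  attr(report, "artifacts") <- artifacts
  attr(report, "survey") <- survey
  invisible(report)
}
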