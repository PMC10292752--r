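# Internal helpers shared across modules.

#' Normalize gene identifiers for cross-file matching
#'
#' Gene symbols arrive with inconsistent casing across sources (mouse `Lyz2`
#' vs. `LYZ2` in human-centric lists). All set operations in the package
#' compare identifiers after trimming whitespace and case-folding to lower
#' case; the original spelling is preserved everywhere it is reported.
#'
#' @param x Character vector of gene identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_gene_ids(c(" Lyz2", "LYZ2"))
normalize_gene_ids <- function(x) {
  tolower(trimws(as.character(x)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() without the call, used for user-facing contract errors
abort <- function(..., class = "nmfmarker_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

abort_input <- function(...) abort(..., class = "nmfmarker_input_error")
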