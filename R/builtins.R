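# Registry of the canonical published filters, shipped verbatim as numbered-
# line strategy files under inst/strategies/. Line numbering follows the
# published 18-line program, so composite filters keep their original
# reference structure (e.g. the highest-precision filter ends "18. 16 AND 5").

builtin_registry <- function() {
  data.frame(
    name = c("rct_pt", "cluster_terms", "broad_terms", "combined_terms",
             "highest_sensitivity", "highest_precision"),
    file = c("rct_pt.txt", "cluster_terms.txt", "broad_terms.txt",
             "combined_terms.txt", "highest_sensitivity.txt",
             "highest_precision.txt"),
    description = c(
      "Existing RCT publication-type filter with animal-only exclusion (lines 1-5)",
      "Cluster design-related textword terms (lines 6-9)",
      "Broad intervention/health-promotion terms and MeSH headings (lines 10-15)",
      "Union of cluster design-related and broad terms (lines 6-16)",
      "Highest sensitivity: combined terms OR the RCT publication-type filter (line 17)",
      "Highest precision: combined terms AND the RCT publication-type filter (line 18)"
    ),
    stringsAsFactors = FALSE
  )
}

#' Retrieve a built-in search filter
#'
#' The package ships the canonical cluster-randomized-trial filters as
#' named, versioned strategy files. The parsed strategy's line text equals
#' the packaged file byte for byte.
#'
#' @param name One of `rct_pt`, `cluster_terms`, `broad_terms`,
#'   `combined_terms`, `highest_sensitivity`, `highest_precision`.
#' @return A `search_strategy` (see [parse_strategy()]).
#' @examples
#' builtin_strategy("highest_precision")
#' @export
builtin_strategy <- function(name) {
  reg <- builtin_registry()
  i <- match(name, reg$name)
  if (is.na(i))
    stop_hedge("unknown built-in strategy '", name, "'; available: ",
               paste(reg$name, collapse = ", "))
  path <- system.file("strategies", reg$file[i], package = "crthedges",
                      mustWork = TRUE)
  parse_strategy(path, name = name)
}

#' List the built-in search filters
#'
#' @return A data frame with columns `name` and `description`, in stable
#'   registry order.
#' @export
list_builtins <- function() {
  builtin_registry()[, c("name", "description")]
}

# Path to the packaged strategy file (used by tests and the CLI).
builtin_strategy_path <- function(name) {
  reg <- builtin_registry()
  i <- match(name, reg$name)
  if (is.na(i)) stop_hedge("unknown built-in strategy '", name, "'")
  system.file("strategies", reg$file[i], package = "crthedges", mustWork = TRUE)
}
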