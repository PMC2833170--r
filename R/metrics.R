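# Diagnostic-accuracy metrics for retrieval, derived from the standard 2x2
# contingency layout:
#
#                        eligible   ineligible
#   retrieved                a          b        a+b
#   not retrieved            c          d        c+d
#                           a+c        b+d        N

#' Build a retrieval contingency table
#'
#' @param retrieved Character vector (or set) of retrieved uids, or a
#'   `result_set` from [evaluate_strategy()].
#' @param relevant Character vector of eligible (relevant) uids.
#' @param corpus_size Total number of articles N.
#' @return An object of class `contingency_table` with counts `a`, `b`, `c`,
#'   `d`, `N`.
#' @examples
#' make_contingency(retrieved = as.character(1:10),
#'                  relevant = as.character(8:12), corpus_size = 100)
#' @export
make_contingency <- function(retrieved, relevant, corpus_size) {
  if (inherits(retrieved, "result_set")) retrieved <- retrieved$retrieved
  retrieved <- unique(as.character(retrieved))
  relevant <- unique(as.character(relevant))
  a <- length(intersect(retrieved, relevant))
  b <- length(setdiff(retrieved, relevant))
  c <- length(setdiff(relevant, retrieved))
  d <- corpus_size - a - b - c
  if (d < 0)
    stop_hedge("inconsistent inputs: corpus_size ", corpus_size,
               " smaller than |retrieved union relevant| = ", a + b + c)
  structure(list(a = a, b = b, c = c, d = d, N = as.integer(corpus_size)),
            class = "contingency_table")
}

#' Construct a contingency table from raw counts
#' @param a,b,c,d Non-negative cell counts (see [make_contingency()]).
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop_hedge("contingency cells must be non-negative")
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("retrieved", "not retrieved"),
                              c("eligible", "ineligible")))
  print(m)
  cat("N =", x$N, "\n")
  invisible(x)
}

#' Compute retrieval performance metrics
#'
#' Sensitivity (recall) `a/(a+c)`, fall-out (1-specificity) `b/(b+d)`,
#' precision `a/(a+b)` and number needed to read `(a+b)/a`. A metric whose
#' denominator is zero is reported as an explicit undefined marker (`NA`)
#' and named in `$undefined`, never silently zero. Two NNR conventions are
#' exposed: `nnr` from raw counts (default) and `nnr_from_rounded_precision`,
#' the reciprocal of the precision rounded to one decimal percentage point,
#' the convention sometimes seen in published summaries.
#'
#' @param t A `contingency_table`.
#' @return An object of class `metrics_report`.
#' @examples
#' compute_metrics(contingency_table(152, 1545, 10, 24000))
#' @export
compute_metrics <- function(t) {
  if (!inherits(t, "contingency_table")) stop_hedge("not a contingency_table")
  undef <- character(0)
  sens <- if (t$a + t$c > 0) t$a / (t$a + t$c) else { undef <- c(undef, "sensitivity"); NA_real_ }
  fall <- if (t$b + t$d > 0) t$b / (t$b + t$d) else { undef <- c(undef, "one_minus_specificity"); NA_real_ }
  prec <- if (t$a + t$b > 0) t$a / (t$a + t$b) else { undef <- c(undef, "precision"); NA_real_ }
  nnr <- if (!is.na(prec) && t$a > 0) (t$a + t$b) / t$a else { undef <- c(undef, "nnr"); NA_real_ }
  nnr_disp <- if (!is.na(prec) && round(prec * 100, 1) > 0)
    1 / (round(prec * 100, 1) / 100) else NA_real_
  structure(list(
    counts = t,
    sensitivity = sens,
    one_minus_specificity = fall,
    precision = prec,
    nnr = nnr,
    nnr_from_rounded_precision = nnr_disp,
    undefined = undef
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(p) if (is.na(p)) "undefined" else sprintf("%.1f%%", 100 * p)
  cat("<metrics_report>\n")
  cat("  sensitivity:     ", pct(x$sensitivity), "\n", sep = "")
  cat("  1 - specificity: ", pct(x$one_minus_specificity), "\n", sep = "")
  cat("  precision:       ", pct(x$precision), "\n", sep = "")
  cat("  NNR:             ",
      if (is.na(x$nnr)) "undefined" else sprintf("%.1f", x$nnr), "\n", sep = "")
  cat("  counts: a=", x$counts$a, " b=", x$counts$b, " c=", x$counts$c,
      " d=", x$counts$d, " N=", x$counts$N, "\n", sep = "")
  invisible(x)
}

#' Relative recall against an independent reference set
#'
#' The fraction of an independently assembled set of relevant articles that
#' a search retrieves.
#'
#' @param retrieved Character vector of retrieved uids or a `result_set`.
#' @param reference_trials Non-empty character vector of reference uids.
#' @return List with `recall` (proportion), `n_retrieved` (intersection
#'   count) and `n_reference`.
#' @export
relative_recall <- function(retrieved, reference_trials) {
  if (inherits(retrieved, "result_set")) retrieved <- retrieved$retrieved
  reference_trials <- unique(as.character(reference_trials))
  if (!length(reference_trials)) stop_hedge("reference set must be non-empty")
  n <- length(intersect(unique(as.character(retrieved)), reference_trials))
  list(recall = n / length(reference_trials),
       n_retrieved = n, n_reference = length(reference_trials))
}

#' Estimate screening workload in hours
#'
#' Screening workload for assembling a target number of relevant trials with
#' a filter of known number needed to read: `target * NNR * minutes / 60`.
#' NNR is taken from raw counts.
#'
#' @param x A `metrics_report`, or a numeric NNR.
#' @param target_crt_count Number of relevant trials sought (> 0).
#' @param minutes_per_article Screening minutes per retrieved article (> 0).
#' @return Hours of screening work (numeric).
#' @examples
#' workload_hours(794 / 146, target_crt_count = 300, minutes_per_article = 3)
#' @export
workload_hours <- function(x, target_crt_count, minutes_per_article) {
  nnr <- if (inherits(x, "metrics_report")) x$nnr else as.numeric(x)
  if (is.na(nnr) || nnr < 1)
    stop_hedge("NNR undefined or < 1; precision must be defined and positive")
  if (target_crt_count <= 0 || minutes_per_article <= 0)
    stop_hedge("target_crt_count and minutes_per_article must be positive")
  target_crt_count * nnr * minutes_per_article / 60
}
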