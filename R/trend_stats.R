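# Reporting-trend and agreement statistics.

#' Construct a yearly reporting-trend table
#'
#' Ordered rows of (year, identified count, total count), e.g. trials whose
#' clustered design is clearly identified in the title or abstract among all
#' gold-standard trials published that year.
#'
#' @param year Strictly increasing integer years.
#' @param identified Count identified per year.
#' @param total Total count per year (`identified <= total`).
#' @return A data frame of class `trend_table`.
#' @export
trend_table <- function(year, identified, total) {
  year <- as.integer(year); identified <- as.integer(identified)
  total <- as.integer(total)
  if (any(diff(year) <= 0)) stop_hedge("years must be strictly increasing")
  if (any(identified > total)) stop_hedge("identified must be <= total")
  if (any(identified < 0 | total < 0)) stop_hedge("counts must be non-negative")
  df <- data.frame(year = year, identified = identified, total = total,
                   proportion = ifelse(total > 0, identified / total, NA_real_))
  class(df) <- c("trend_table", "data.frame")
  df
}

#' Test for a temporal trend in a proportion
#'
#' Two methods are offered, both returning a signed normal-deviate statistic
#' and a two-sided normal p-value:
#'
#' * `"ls_proportions"` (default): unweighted least-squares regression of the
#'   yearly proportions on calendar year; the statistic is the slope t-ratio
#'   referred to the standard normal. This is the convention under which the
#'   published headline trend results for CRT reporting are reproduced.
#' * `"cochran_armitage"`: the Cochran-Armitage trend test with equally
#'   spaced integer year scores (equivalent to `stats::prop.trend.test`,
#'   with the sign of the trend retained).
#'
#' The statistic is invariant to adding a constant to all year scores.
#'
#' @param t A [trend_table()].
#' @param method `"ls_proportions"` or `"cochran_armitage"`.
#' @param exclude_years Optional years to drop before testing (e.g. a year
#'   known to be sampled differently).
#' @return List with `statistic` (signed z), `p_value` (two-sided) and
#'   `method`.
#' @export
trend_test <- function(t, method = c("ls_proportions", "cochran_armitage"),
                       exclude_years = NULL) {
  method <- match.arg(method)
  if (!inherits(t, "trend_table")) stop_hedge("not a trend_table")
  if (!is.null(exclude_years)) t <- t[!t$year %in% exclude_years, , drop = FALSE]
  t <- t[t$total > 0, , drop = FALSE]
  if (nrow(t) < 2) stop_hedge("need at least 2 rows with positive totals")
  if (method == "ls_proportions") {
    if (nrow(t) < 3)
      stop_hedge("ls_proportions needs at least 3 rows; use cochran_armitage")
    fit <- stats::lm(proportion ~ year, data = t)
    co <- summary(fit)$coefficients
    slope <- co["year", "Estimate"]; se <- co["year", "Std. Error"]
    # a perfectly flat series fits exactly: no evidence of trend
    z <- if (!is.finite(se) || se == 0) {
      if (abs(slope) < 1e-12) 0 else sign(slope) * Inf
    } else slope / se
  } else {
    s <- t$year; x <- t$identified; n <- t$total
    N <- sum(n); p <- sum(x) / N
    num <- sum(s * (x - n * p))
    v <- p * (1 - p) * (sum(n * s^2) - sum(n * s)^2 / N)
    if (v <= 0) stop_hedge("degenerate trend table: zero variance")
    z <- num / sqrt(v)
  }
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)), method = method)
}

#' Wald confidence interval for a difference of two proportions
#'
#' Difference `p2 - p1` with the Wald interval
#' `(p2-p1) +/- z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`, no continuity
#' correction, reported in percentage points.
#'
#' @param x1,n1 Successes and trials in the first (earlier) group.
#' @param x2,n2 Successes and trials in the second (later) group.
#' @param confidence Confidence level (default 0.95).
#' @return List with `difference`, `lower`, `upper` (percentage points) and
#'   the two proportions.
#' @examples
#' diff_proportions_ci(16, 58, 62, 104)
#' @export
diff_proportions_ci <- function(x1, n1, x2, n2, confidence = 0.95) {
  if (n1 <= 0 || n2 <= 0) stop_hedge("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop_hedge("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  d <- p2 - p1
  list(difference = 100 * d, lower = 100 * (d - z * se),
       upper = 100 * (d + z * se), p1 = p1, p2 = p2,
       confidence = confidence)
}

#' Cohen's kappa for a 2x2 inter-rater inclusion table
#'
#' `kappa = (po - pe) / (1 - pe)` with the large-sample standard error
#' `sqrt(po (1 - po)) / ((1 - pe) sqrt(n))` and a normal confidence
#' interval, truncated to `[-1, 1]`.
#'
#' @param agreement A 2x2 matrix of counts; rows are reviewer 1's
#'   include/exclude decisions, columns reviewer 2's.
#' @param confidence Confidence level (default 0.95).
#' @return List with `kappa`, `lower`, `upper`, `po`, `pe`. If chance
#'   agreement `pe` is 1, kappa is an explicit undefined marker (`NA`).
#' @export
cohen_kappa <- function(agreement, confidence = 0.95) {
  m <- as.matrix(agreement)
  if (!all(dim(m) == c(2, 2))) stop_hedge("agreement must be a 2x2 table")
  if (any(m < 0)) stop_hedge("cell counts must be non-negative")
  n <- sum(m)
  if (n <= 0) stop_hedge("agreement table must have a positive total")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    return(list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
                po = po, pe = pe))
  }
  k <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / n) / (1 - pe)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(kappa = k, lower = max(-1, k - z * se), upper = min(1, k + z * se),
       po = po, pe = pe)
}

#' Aggregate identifiability labels into a yearly trend table
#'
#' Counts, per publication year, the CRTs in a given identifiability class
#' over all CRTs published that year. Rows with missing year are excluded
#' with a warning. The overall totals are attached as attributes.
#'
#' @param labels A [gold_labels()] data frame.
#' @param class Identifiability class to count (default `"CLEAR"`).
#' @return A [trend_table()] with attributes `total_identified` and
#'   `total_crts`.
#' @export
aggregate_trend <- function(labels, class = "CLEAR") {
  crts <- labels[labels$is_crt, , drop = FALSE]
  if (anyNA(crts$year)) {
    warning(sum(is.na(crts$year)), " CRT(s) with missing year excluded",
            call. = FALSE)
    crts <- crts[!is.na(crts$year), , drop = FALSE]
  }
  if (!nrow(crts)) stop_hedge("no CRTs with year information")
  years <- sort(unique(crts$year))
  ident <- vapply(years, function(y)
    sum(crts$year == y & !is.na(crts$identifiability) &
          crts$identifiability == class), integer(1))
  tot <- vapply(years, function(y) sum(crts$year == y), integer(1))
  out <- trend_table(years, ident, tot)
  attr(out, "total_identified") <- sum(ident)
  attr(out, "total_crts") <- sum(tot)
  out
}
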