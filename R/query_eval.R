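# Query evaluation engine.
#
# Matching semantics (fixed contract, documented in the methods vignette):
#  * `.tw.`  : a match must occur entirely within the tokenized title or
#              entirely within the tokenized abstract (no cross-field spans).
#  * `.pt.`  : case-insensitive whole-value equality against any
#              publication-type entry.
#  * MeSH `/`: descriptor equality after stripping the leading major-topic
#              `*` and any `/subheading` suffix (unexploded: no tree
#              expansion).
#  * phrase  : consecutive in-order token matches.
#  * adjN    : some match positions p, q of the two operands in the same
#              field satisfy |p - q| <= N, in either order.
#  * `term$` : prefix match; `term?`: stem or stem plus exactly one extra
#              character.

# strip "*Heading/subheading" -> "heading"
normalize_mesh <- function(x) {
  x <- sub("^\\*", "", x)
  x <- sub("/.*$", "", x)
  tolower(squish(x))
}

# Precomputed per-citation fields used by the engine.
corpus_index <- function(corpus) {
  cits <- corpus$citations
  list(
    n = length(cits),
    uid = vapply(cits, `[[`, character(1), "uid"),
    title = lapply(cits, function(c) tokenize(c$title)),
    abstract = lapply(cits, function(c) tokenize(c$abstract)),
    pt = lapply(cits, function(c) tolower(squish(c$pub_types))),
    mesh = lapply(cits, function(c) normalize_mesh(c$mesh_terms))
  )
}

term_hits <- function(tokens, stem, trunc) {
  if (!length(tokens)) return(integer(0))
  hit <- switch(trunc,
    none = tokens == stem,
    unlimited = startsWith(tokens, stem),
    optional_one = tokens == stem |
      (startsWith(tokens, stem) & nchar(tokens) == nchar(stem) + 1L)
  )
  which(hit)
}

# Positions at which a term-level expression matches within one token field.
match_positions <- function(node, tokens) {
  switch(node$kind,
    term = term_hits(tokens, node$stem, node$trunc),
    phrase = {
      k <- length(node$terms)
      starts <- term_hits(tokens, node$terms[[1]]$stem, node$terms[[1]]$trunc)
      starts <- starts[starts + k - 1L <= length(tokens)]
      if (k > 1L && length(starts)) {
        for (j in 2:k) {
          t_j <- node$terms[[j]]
          ok <- vapply(starts, function(s)
            length(term_hits(tokens[s + j - 1L], t_j$stem, t_j$trunc)) > 0L,
            logical(1))
          starts <- starts[ok]
          if (!length(starts)) break
        }
      }
      starts
    },
    adj = {
      pa <- match_positions(node$lhs, tokens)
      pb <- match_positions(node$rhs, tokens)
      if (!length(pa) || !length(pb)) return(integer(0))
      d <- abs(outer(pa, pb, `-`)) <= node$n
      sort(unique(c(pa[rowSums(d) > 0], pb[colSums(d) > 0])))
    },
    or = sort(unique(c(match_positions(node$lhs, tokens),
                       match_positions(node$rhs, tokens)))),
    and = {
      pa <- match_positions(node$lhs, tokens)
      pb <- match_positions(node$rhs, tokens)
      if (length(pa) && length(pb)) sort(unique(c(pa, pb))) else integer(0)
    },
    not = {
      pa <- match_positions(node$lhs, tokens)
      if (length(match_positions(node$rhs, tokens))) integer(0) else pa
    },
    stop_hedge("unexpected node kind inside field scope: ", node$kind)
  )
}

# Evaluate one strategy line over the whole corpus -> logical vector.
eval_node <- function(node, idx, prior) {
  switch(node$kind,
    ref = {
      key <- as.character(node$n)
      if (is.null(prior[[key]])) stop_hedge("unresolved line reference ", node$n)
      prior[[key]]
    },
    and = eval_node(node$lhs, idx, prior) & eval_node(node$rhs, idx, prior),
    or = eval_node(node$lhs, idx, prior) | eval_node(node$rhs, idx, prior),
    not = eval_node(node$lhs, idx, prior) & !eval_node(node$rhs, idx, prior),
    mesh = vapply(idx$mesh, function(m) node$heading %in% m, logical(1)),
    field = {
      if (node$field == "pt") {
        vapply(idx$pt, function(p) node$value %in% p, logical(1))
      } else {
        ex <- node$expr
        vapply(seq_len(idx$n), function(i)
          length(match_positions(ex, idx$title[[i]])) > 0L ||
            length(match_positions(ex, idx$abstract[[i]])) > 0L,
          logical(1))
      }
    },
    stop_hedge("cannot evaluate node kind '", node$kind, "' at line level")
  )
}

#' Evaluate a single query expression against one citation
#'
#' Low-level entry point mirroring the engine's per-citation semantics;
#' useful for inspecting why a record does or does not match.
#'
#' @param expr A parsed query expression (one element of
#'   `strategy$lines[[i]]$expr`).
#' @param citation A [citation_record()].
#' @param prior A named list mapping earlier line numbers (as character) to
#'   character vectors of retrieved uids, used to resolve line references.
#' @return `TRUE` if the citation matches.
#' @export
evaluate_expression <- function(expr, citation, prior = list()) {
  idx <- corpus_index(medline_corpus(list(citation)))
  prior_lgl <- lapply(prior, function(uids) citation$uid %in% uids)
  eval_node(expr, idx, prior_lgl)[[1]]
}

#' Evaluate a strategy over a corpus
#'
#' Lines are evaluated in ascending order with each line's result cached, so
#' later lines can combine earlier ones by number. The strategy's result is
#' the final line's set.
#'
#' @param strategy A [parse_strategy()] result or built-in name (see
#'   [builtin_strategy()]).
#' @param corpus A [medline_corpus()].
#' @return An object of class `result_set`: list with `retrieved` (uids for
#'   the final line), `per_line` (named list of uid vectors), `line_counts`,
#'   and the strategy name.
#' @export
evaluate_strategy <- function(strategy, corpus) {
  if (is.character(strategy)) strategy <- builtin_strategy(strategy)
  if (!inherits(strategy, "search_strategy")) stop_hedge("not a search_strategy")
  idx <- corpus_index(corpus)
  prior <- list()
  per_line <- list()
  for (ln in strategy$lines) {
    v <- eval_node(ln$expr, idx, prior)
    prior[[as.character(ln$number)]] <- v
    per_line[[as.character(ln$number)]] <- idx$uid[v]
  }
  final <- strategy$lines[[length(strategy$lines)]]$number
  structure(list(
    strategy = strategy$name,
    retrieved = per_line[[as.character(final)]],
    final_line = final,
    per_line = per_line,
    line_counts = vapply(per_line, length, integer(1)),
    corpus_size = idx$n
  ), class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat("<result_set> strategy '", x$strategy, "': ", length(x$retrieved),
      " of ", x$corpus_size, " citations retrieved (final line ",
      x$final_line, ")\n", sep = "")
  invisible(x)
}
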