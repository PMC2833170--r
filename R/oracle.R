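# Brute-force reference matcher: a deliberately naive, loop-based
# re-implementation of the strategy semantics, kept free of the engine's
# vectorization and position-set algebra. Used to verify the engine on
# randomized instances; do not optimize.

o_term_match <- function(token, stem, trunc) {
  nt <- nchar(token); ns <- nchar(stem)
  if (trunc == "none") return(identical(token, stem))
  if (trunc == "unlimited")
    return(nt >= ns && identical(substr(token, 1, ns), stem))
  # optional_one
  (nt == ns || nt == ns + 1L) && identical(substr(token, 1, ns), stem)
}

o_positions <- function(node, tokens) {
  pos <- integer(0)
  if (node$kind == "term") {
    for (i in seq_along(tokens))
      if (o_term_match(tokens[[i]], node$stem, node$trunc)) pos <- c(pos, i)
  } else if (node$kind == "phrase") {
    k <- length(node$terms)
    if (length(tokens) >= k) {
      for (s in seq_len(length(tokens) - k + 1L)) {
        all_ok <- TRUE
        for (j in seq_len(k)) {
          t_j <- node$terms[[j]]
          if (!o_term_match(tokens[[s + j - 1L]], t_j$stem, t_j$trunc)) {
            all_ok <- FALSE; break
          }
        }
        if (all_ok) pos <- c(pos, s)
      }
    }
  } else if (node$kind == "adj") {
    pa <- o_positions(node$lhs, tokens)
    pb <- o_positions(node$rhs, tokens)
    for (p in pa) for (q in pb)
      if (abs(p - q) <= node$n) pos <- c(pos, p, q)
    pos <- sort(unique(pos))
  } else if (node$kind == "or") {
    pos <- sort(unique(c(o_positions(node$lhs, tokens),
                         o_positions(node$rhs, tokens))))
  } else if (node$kind == "and") {
    pa <- o_positions(node$lhs, tokens)
    pb <- o_positions(node$rhs, tokens)
    if (length(pa) > 0 && length(pb) > 0) pos <- sort(unique(c(pa, pb)))
  } else if (node$kind == "not") {
    pa <- o_positions(node$lhs, tokens)
    pb <- o_positions(node$rhs, tokens)
    if (length(pb) == 0) pos <- pa
  } else {
    stop_hedge("oracle: unexpected node kind in field scope: ", node$kind)
  }
  pos
}

o_eval <- function(node, citation, prior_uids) {
  if (node$kind == "ref") {
    uids <- prior_uids[[as.character(node$n)]]
    if (is.null(uids)) stop_hedge("oracle: unresolved line reference ", node$n)
    return(citation$uid %in% uids)
  }
  if (node$kind == "and")
    return(o_eval(node$lhs, citation, prior_uids) &&
             o_eval(node$rhs, citation, prior_uids))
  if (node$kind == "or")
    return(o_eval(node$lhs, citation, prior_uids) ||
             o_eval(node$rhs, citation, prior_uids))
  if (node$kind == "not")
    return(o_eval(node$lhs, citation, prior_uids) &&
             !o_eval(node$rhs, citation, prior_uids))
  if (node$kind == "mesh") {
    for (m in citation$mesh_terms) {
      h <- m
      if (substr(h, 1, 1) == "*") h <- substr(h, 2, nchar(h))
      slash <- regexpr("/", h, fixed = TRUE)
      if (slash > 0) h <- substr(h, 1, slash - 1L)
      if (identical(tolower(squish(h)), node$heading)) return(TRUE)
    }
    return(FALSE)
  }
  if (node$kind == "field") {
    if (node$field == "pt") {
      for (p in citation$pub_types)
        if (identical(tolower(squish(p)), node$value)) return(TRUE)
      return(FALSE)
    }
    for (txt in list(citation$title, citation$abstract)) {
      if (length(o_positions(node$expr, tokenize(txt))) > 0) return(TRUE)
    }
    return(FALSE)
  }
  stop_hedge("oracle: cannot evaluate node kind '", node$kind, "'")
}

#' Brute-force reference evaluation of a strategy
#'
#' An exhaustive per-citation scan with the same contract as
#' [evaluate_strategy()], implemented independently (plain loops, no shared
#' matching code). Intended for verification; quadratic in places and slow on
#' large corpora.
#'
#' @inheritParams evaluate_strategy
#' @return A `result_set`, as for [evaluate_strategy()].
#' @export
oracle_match <- function(strategy, corpus) {
  if (is.character(strategy)) strategy <- builtin_strategy(strategy)
  per_line <- list()
  for (ln in strategy$lines) {
    hits <- character(0)
    for (cit in corpus$citations)
      if (o_eval(ln$expr, cit, per_line)) hits <- c(hits, cit$uid)
    per_line[[as.character(ln$number)]] <- hits
  }
  final <- strategy$lines[[length(strategy$lines)]]$number
  structure(list(
    strategy = strategy$name,
    retrieved = per_line[[as.character(final)]],
    final_line = final,
    per_line = per_line,
    line_counts = vapply(per_line, length, integer(1)),
    corpus_size = corpus_size(corpus)
  ), class = "result_set")
}
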