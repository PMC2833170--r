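# Parser for the Ovid-style numbered-line strategy dialect:
#
#   1. randomized controlled trial.pt.
#   2. animals/
#   6. cluster$ adj2 randomi$.tw.
#   7. ((communit$ adj2 intervention$) OR (communit$ adj2 randomi$)).tw.
#   9. 6 OR 7 OR 8
#  18. 16 AND 5
#
# Operators AND/OR/NOT/adjN are case-insensitive; `$` is unlimited right
# truncation, `?` permits at most one extra trailing character; `.tw.` scopes
# to title + abstract textwords, `.pt.` to publication type; a trailing `/`
# marks a MeSH heading line; bare integers reference earlier lines.
# Operator precedence, loosest first: OR, AND, NOT, adjN, juxtaposition
# (phrase). A field suffix binds to the whole preceding expression at its
# parenthesis level.

q_node <- function(kind, ...) structure(list(kind = kind, ...), class = "query_node")

lex_query <- function(text, lineno = NA) {
  pat <- "\\.(tw|pt)\\.|[()/]|[A-Za-z][A-Za-z0-9]*[$?]?|[0-9]+"
  ms <- gregexpr(pat, text, ignore.case = TRUE)[[1]]
  toks <- if (ms[1] == -1L) character(0) else
    regmatches(text, gregexpr(pat, text, ignore.case = TRUE))[[1]]
  # everything not matched must be whitespace
  resid <- text
  if (length(toks)) {
    r <- regmatches(resid, gregexpr(pat, resid, ignore.case = TRUE))
    regmatches(resid, gregexpr(pat, resid, ignore.case = TRUE)) <-
      list(rep("", length(r[[1]])))
  }
  if (nzchar(gsub("[[:space:]]", "", resid)))
    stop_hedge("line ", lineno, ": unrecognized character(s) near '",
               trimws(resid), "'")
  out <- lapply(toks, function(tk) {
    lo <- tolower(tk)
    if (tk == "(") list(type = "lparen")
    else if (tk == ")") list(type = "rparen")
    else if (tk == "/") list(type = "slash")
    else if (grepl("^\\.(tw|pt)\\.$", lo)) list(type = "field", field = gsub("\\.", "", lo))
    else if (grepl("^[0-9]+$", tk)) list(type = "number", value = as.integer(tk))
    else if (lo %in% c("and", "or", "not")) list(type = lo)
    else if (grepl("^adj[0-9]*$", lo)) {
      n <- sub("^adj", "", lo)
      list(type = "adj", n = if (nzchar(n)) as.integer(n) else 1L)
    } else {
      trunc <- if (endsWith(tk, "$")) "unlimited"
               else if (endsWith(tk, "?")) "optional_one" else "none"
      stem <- tolower(sub("[$?]$", "", tk))
      if (!nzchar(stem)) stop_hedge("line ", lineno, ": bare wildcard")
      list(type = "word", stem = stem, trunc = trunc)
    }
  })
  out
}

new_parser <- function(tokens, lineno) {
  env <- new.env(parent = emptyenv())
  env$toks <- tokens; env$pos <- 1L; env$lineno <- lineno
  env
}
p_peek <- function(p) if (p$pos <= length(p$toks)) p$toks[[p$pos]]$type else "eof"
p_next <- function(p) { tk <- p$toks[[p$pos]]; p$pos <- p$pos + 1L; tk }
p_fail <- function(p, ...) stop_hedge("line ", p$lineno, ": ", ...)

p_scope <- function(p) {
  e <- p_or(p)
  if (p_peek(p) == "field") {
    tk <- p_next(p)
    e <- make_field(p, tk$field, e)
  }
  e
}
p_or <- function(p) {
  e <- p_and(p)
  while (p_peek(p) == "or") { p_next(p); e <- q_node("or", lhs = e, rhs = p_and(p)) }
  e
}
p_and <- function(p) {
  e <- p_not(p)
  while (p_peek(p) == "and") { p_next(p); e <- q_node("and", lhs = e, rhs = p_not(p)) }
  e
}
p_not <- function(p) {
  e <- p_adj(p)
  while (p_peek(p) == "not") { p_next(p); e <- q_node("not", lhs = e, rhs = p_adj(p)) }
  e
}
p_adj <- function(p) {
  e <- p_seq(p)
  while (p_peek(p) == "adj") {
    tk <- p_next(p)
    if (tk$n < 1L) p_fail(p, "adj window must be >= 1")
    e <- q_node("adj", n = tk$n, lhs = e, rhs = p_seq(p))
  }
  e
}
p_seq <- function(p) {
  atoms <- list()
  repeat {
    tt <- p_peek(p)
    if (tt == "lparen") {
      p_next(p)
      e <- p_scope(p)
      if (p_peek(p) != "rparen") p_fail(p, "missing closing parenthesis")
      p_next(p)
      if (p_peek(p) == "field") {
        tk <- p_next(p)
        e <- make_field(p, tk$field, e)
      }
      atoms[[length(atoms) + 1L]] <- e
    } else if (tt == "word") {
      tk <- p_next(p)
      atoms[[length(atoms) + 1L]] <- q_node("term", stem = tk$stem, trunc = tk$trunc)
    } else if (tt == "number") {
      tk <- p_next(p)
      atoms[[length(atoms) + 1L]] <- q_node("ref", n = tk$value)
    } else break
  }
  if (!length(atoms)) p_fail(p, "expected a term, line reference or '('")
  if (p_peek(p) == "slash") {
    p_next(p)
    ok <- all(vapply(atoms, function(a) a$kind == "term" && a$trunc == "none",
                     logical(1)))
    if (!ok) p_fail(p, "MeSH heading must be plain words before '/'")
    return(q_node("mesh",
                  heading = paste(vapply(atoms, `[[`, character(1), "stem"),
                                  collapse = " ")))
  }
  if (length(atoms) == 1L) return(atoms[[1L]])
  if (!all(vapply(atoms, function(a) a$kind == "term", logical(1))))
    p_fail(p, "juxtaposition is only valid between words (phrase)")
  q_node("phrase", terms = atoms)
}

make_field <- function(p, field, expr) {
  walk <- function(e) {
    switch(e$kind,
      ref = p_fail(p, "line references are not allowed inside a .", field, ". scope"),
      mesh = p_fail(p, "MeSH headings cannot be field-scoped"),
      field = p_fail(p, "nested field scopes are not allowed"),
      term = , phrase = NULL,
      adj = { walk(e$lhs); walk(e$rhs) },
      and = , or = , not = { walk(e$lhs); walk(e$rhs) }
    )
    invisible(NULL)
  }
  walk(expr)
  if (field == "pt") {
    terms <- if (expr$kind == "term") list(expr)
             else if (expr$kind == "phrase") expr$terms
             else p_fail(p, ".pt. accepts only a word or phrase (whole-value match)")
    if (any(vapply(terms, `[[`, character(1), "trunc") != "none"))
      p_fail(p, "truncation wildcards are not supported in .pt.")
    return(q_node("field", field = "pt",
                  value = paste(vapply(terms, `[[`, character(1), "stem"),
                                collapse = " ")))
  }
  q_node("field", field = "tw", expr = expr)
}

# A strategy line must bottom out in field-scoped, MeSH, or line-reference
# leaves; a bare textword with no qualifier is a dialect error.
validate_line_expr <- function(expr, lineno, known) {
  walk <- function(e) {
    switch(e$kind,
      and = , or = , not = { walk(e$lhs); walk(e$rhs) },
      field = , mesh = NULL,
      ref = {
        if (!e$n %in% known)
          stop_hedge("line ", lineno, ": reference to unknown or forward line ", e$n)
        if (e$n >= lineno)
          stop_hedge("line ", lineno, ": reference must target an earlier line")
      },
      stop_hedge("line ", lineno,
                 ": term-level expression needs a .tw./.pt. qualifier or MeSH '/'")
    )
    invisible(NULL)
  }
  walk(expr)
}

parse_query_line <- function(text, lineno, known) {
  p <- new_parser(lex_query(text, lineno), lineno)
  e <- p_scope(p)
  if (p_peek(p) != "eof")
    p_fail(p, "unexpected trailing input from token ", p$pos)
  validate_line_expr(e, lineno, known)
  e
}

#' Parse a numbered-line search strategy
#'
#' Parses the Ovid-style dialect used by the shipped filters: one numbered
#' query line per row (`N. expression`), comment lines starting with `#`
#' ignored, line numbers strictly increasing, line references resolving only
#' to earlier lines. The final line designates the strategy's result.
#'
#' @param text Strategy file content: a path, connection, or character vector
#'   of lines (a single string with newlines is also accepted).
#' @param name Strategy name to attach.
#' @return An object of class `search_strategy`: a list with `name`, `lines`
#'   (each with `number`, `text` and parsed expression) and `source_text`.
#' @examples
#' s <- parse_strategy(c("1. cluster$ adj2 randomi$.tw.",
#'                       "2. randomized controlled trial.pt.",
#'                       "3. 1 AND 2"))
#' s
#' @export
parse_strategy <- function(text, name = "strategy") {
  lines <- read_text_lines(text)
  if (length(lines) == 1L && grepl("\n", lines)) lines <- strsplit(lines, "\n")[[1]]
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  body <- lines[keep]
  if (!length(body)) stop_hedge("empty strategy: no query lines found")
  parsed <- vector("list", length(body))
  known <- integer(0)
  last <- 0L
  for (i in seq_along(body)) {
    m <- regexec("^\\s*([0-9]+)\\.\\s+(\\S.*?)\\s*$", body[[i]])
    g <- regmatches(body[[i]], m)[[1]]
    if (!length(g))
      stop_hedge("strategy line ", i, " is not of the form 'N. expression': ",
                 trimws(body[[i]]))
    no <- as.integer(g[2])
    if (no <= last)
      stop_hedge("line numbers must be strictly increasing (saw ", no,
                 " after ", last, ")")
    expr <- parse_query_line(g[3], no, known)
    parsed[[i]] <- list(number = no, text = g[3], expr = expr)
    known <- c(known, no)
    last <- no
  }
  structure(list(name = name, lines = parsed,
                 source_text = paste(lines, collapse = "\n")),
            class = "search_strategy")
}

#' @export
print.search_strategy <- function(x, ...) {
  cat("<search_strategy> ", x$name, " (", length(x$lines), " lines)\n", sep = "")
  for (ln in x$lines) cat(sprintf("  %d. %s\n", ln$number, ln$text))
  invisible(x)
}
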