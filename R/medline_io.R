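#' Construct a single bibliographic citation record
#'
#' A citation mirrors the fields exported from a MEDLINE record that matter
#' for filter evaluation: unique identifier, title, abstract, MeSH headings
#' (stored as indexed, possibly with a leading major-topic `*` and
#' `/subheading` suffixes), publication types, journal and publication year.
#'
#' @param uid Record identifier (canonically 8 decimal digits; other schemes
#'   are accepted with a warning).
#' @param title Article title; must be non-empty.
#' @param abstract Abstract text; may be empty.
#' @param mesh_terms Character vector of MeSH heading strings as stored.
#' @param pub_types Character vector of publication-type strings.
#' @param journal Journal title.
#' @param year Publication year (integer in 1900-2100, or `NA`).
#' @return An object of class `citation_record`.
#' @export
citation_record <- function(uid, title, abstract = "", mesh_terms = character(0),
                            pub_types = character(0), journal = "", year = NA_integer_) {
  uid <- as.character(uid)
  if (length(uid) != 1L || is.na(uid) || !nzchar(uid))
    stop_hedge("citation uid must be a non-empty string")
  if (!grepl("^[0-9]{8}$", uid))
    warning("uid '", uid, "' is not an 8-digit identifier", call. = FALSE)
  title <- squish(as.character(title))
  if (!nzchar(title)) stop_hedge("citation ", uid, ": title must be non-empty")
  year <- as.integer(year)
  if (!is.na(year) && (year < 1900L || year > 2100L))
    stop_hedge("citation ", uid, ": year ", year, " outside [1900, 2100]")
  structure(list(
    uid = uid, title = title, abstract = squish(as.character(abstract)),
    mesh_terms = as.character(mesh_terms), pub_types = as.character(pub_types),
    journal = squish(as.character(journal)), year = year
  ), class = "citation_record")
}

#' @export
print.citation_record <- function(x, ...) {
  cat("<citation ", x$uid, "> ", x$title, "\n", sep = "")
  if (!is.na(x$year)) cat("  year: ", x$year, "  journal: ", x$journal, "\n", sep = "")
  if (length(x$pub_types)) cat("  pub types: ", paste(x$pub_types, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Construct a citation corpus
#'
#' An ordered collection of [citation_record()] objects with unique uids.
#'
#' @param citations A list of `citation_record` objects.
#' @param provenance Free-text description of where the corpus came from.
#' @return An object of class `medline_corpus`.
#' @export
medline_corpus <- function(citations = list(), provenance = "") {
  ok <- vapply(citations, inherits, logical(1), what = "citation_record")
  if (!all(ok)) stop_hedge("all corpus elements must be citation_record objects")
  uids <- vapply(citations, `[[`, character(1), "uid")
  dup <- unique(uids[duplicated(uids)])
  if (length(dup))
    stop_hedge("duplicate uid(s) in corpus: ", paste(dup, collapse = ", "))
  structure(list(citations = citations, provenance = provenance),
            class = "medline_corpus")
}

#' @export
print.medline_corpus <- function(x, ...) {
  cat("<medline_corpus> ", corpus_size(x), " citations", sep = "")
  if (nzchar(x$provenance)) cat(" (", x$provenance, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of citations in a corpus
#' @param corpus A [medline_corpus()].
#' @return Integer count.
#' @export
corpus_size <- function(corpus) length(corpus$citations)

#' Unique identifiers of a corpus, in order
#' @param corpus A [medline_corpus()].
#' @return Character vector of uids.
#' @export
corpus_uids <- function(corpus)
  vapply(corpus$citations, `[[`, character(1), "uid")

# ---------------------------------------------------------------------------
# MEDLINE tagged format (nbib-style): "TAG - content", continuation lines
# indented; records separated by blank lines. Tags used: PMID, TI, AB, MH
# (repeated), PT (repeated), JT, DP.
# ---------------------------------------------------------------------------

medline_tag_re <- "^([A-Z][A-Z0-9]{0,3}) {0,3}- ?(.*)$"

#' Read a MEDLINE tagged-format citation file
#'
#' Accepts both the padded tag form (`TI  - `) and the unpadded form (`TI-`).
#' Continuation lines (indented) are joined to the open field with a single
#' space, with internal whitespace collapsed. Repeated `MH` and `PT` tags
#' accumulate in file order. Records lacking an `AB` field get an empty
#' abstract. Input is read as UTF-8; invalid bytes are replaced with a warning.
#'
#' @param source A file path, connection, or character vector of lines.
#' @return A [medline_corpus()].
#' @export
read_medline <- function(source) {
  lines <- read_text_lines(source)
  records <- list()
  cur <- NULL      # named list of field character vectors
  open_tag <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur)) records[[length(records) + 1L]] <<- cur
    cur <<- NULL; open_tag <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    if (grepl(medline_tag_re, ln)) {
      tag <- sub(medline_tag_re, "\\1", ln)
      val <- sub(medline_tag_re, "\\2", ln)
      if (is.null(cur)) cur <- list()
      cur[[tag]] <- c(cur[[tag]] %||% character(0), val)
      open_tag <- tag
    } else if (grepl("^[[:space:]]+\\S", ln)) {
      if (is.null(open_tag))
        stop_hedge("line ", i, ": continuation line with no open field")
      v <- cur[[open_tag]]
      v[length(v)] <- paste(v[length(v)], trimws(ln))
      cur[[open_tag]] <- v
    } else {
      stop_hedge("line ", i, ": malformed tag line: ", substr(ln, 1, 60))
    }
  }
  flush()
  cits <- lapply(records, function(r) {
    uid <- squish(paste((r[["PMID"]] %||% ""), collapse = " "))
    if (!nzchar(uid)) stop_hedge("record without PMID tag")
    dp <- squish(paste(r[["DP"]] %||% character(0), collapse = " "))
    year <- if (grepl("[0-9]{4}", dp))
      as.integer(regmatches(dp, regexpr("[0-9]{4}", dp))) else NA_integer_
    citation_record(
      uid = uid,
      title = squish(paste(r[["TI"]] %||% "", collapse = " ")),
      abstract = squish(paste(r[["AB"]] %||% character(0), collapse = " ")),
      mesh_terms = squish(r[["MH"]] %||% character(0)),
      pub_types = squish(r[["PT"]] %||% character(0)),
      journal = squish(paste(r[["JT"]] %||% character(0), collapse = " ")),
      year = year
    )
  })
  uids <- vapply(cits, `[[`, character(1), "uid")
  dup <- unique(uids[duplicated(uids)])
  if (length(dup))
    stop_hedge("duplicate uid(s) in input: ", paste(dup, collapse = ", "))
  medline_corpus(cits, provenance = "read_medline")
}

#' Write a corpus in MEDLINE tagged format
#'
#' Emits the padded tag form (`PMID- `, `TI  - `, ...), one line per field,
#' fields in a fixed order (PMID, TI, AB, MH, PT, JT, DP), records separated
#' by a blank line. Output is deterministic and re-readable by
#' [read_medline()] with field-level equality.
#'
#' @param corpus A [medline_corpus()].
#' @param sink A file path or writable connection.
#' @return Invisibly, the number of records written.
#' @export
write_medline <- function(corpus, sink) {
  if (!inherits(corpus, "medline_corpus")) stop_hedge("not a medline_corpus")
  out <- character(0)
  fmt <- function(tag, vals) {
    vals <- vals[nzchar(vals)]
    if (!length(vals)) return(character(0))
    sprintf("%s- %s", formatC(tag, width = 4, flag = "-"), vals)
  }
  for (cit in corpus$citations) {
    rec <- c(
      sprintf("PMID- %s", cit$uid),
      fmt("TI", cit$title),
      fmt("AB", cit$abstract),
      fmt("MH", cit$mesh_terms),
      fmt("PT", cit$pub_types),
      fmt("JT", cit$journal),
      if (!is.na(cit$year)) fmt("DP", as.character(cit$year)) else character(0)
    )
    out <- c(out, rec, "")
  }
  con <- if (is.character(sink)) {
    f <- file(sink, open = "wb", encoding = "UTF-8"); on.exit(close(f)); f
  } else sink
  writeLines(out, con, useBytes = FALSE)
  invisible(corpus_size(corpus))
}

read_text_lines <- function(source) {
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    raw <- readLines(source, warn = FALSE, encoding = "UTF-8")
  } else if (inherits(source, "connection")) {
    raw <- readLines(source, warn = FALSE, encoding = "UTF-8")
  } else {
    raw <- as.character(source)
  }
  bad <- !validUTF8(raw)
  if (any(bad)) {
    warning(sum(bad), " line(s) contained invalid UTF-8; bytes replaced",
            call. = FALSE)
    raw[bad] <- iconv(raw[bad], "UTF-8", "UTF-8", sub = "?")
  }
  raw
}

# ---------------------------------------------------------------------------
# Gold-standard labels
# ---------------------------------------------------------------------------

#' Construct a gold-standard label set
#'
#' Per-citation labels: whether the article reports a cluster randomized
#' trial, and for CRTs, how the design is identifiable from the title or
#' abstract: `CLEAR` (explicit cluster/group/community-randomized phrasing),
#' `UNIT` (identifiable only from the reported units of randomization), or
#' `NONE` (identifiable only from the full text). Non-CRTs carry `NA`.
#'
#' @param uid Character vector of citation identifiers.
#' @param is_crt Logical vector.
#' @param identifiability Character vector in `CLEAR`/`UNIT`/`NONE`, `NA` for
#'   non-CRTs.
#' @param year Integer vector of publication years.
#' @return A data frame of class `gold_labels`.
#' @export
gold_labels <- function(uid, is_crt, identifiability, year) {
  uid <- as.character(uid)
  if (anyDuplicated(uid)) stop_hedge("duplicate uids in labels")
  is_crt <- as.logical(is_crt)
  identifiability <- toupper(as.character(identifiability))
  identifiability[!nzchar(identifiability) | identifiability == "NA"] <- NA_character_
  bad <- !is.na(identifiability) &
    !identifiability %in% c("CLEAR", "UNIT", "NONE")
  if (any(bad))
    stop_hedge("unknown identifiability value(s): ",
               paste(unique(identifiability[bad]), collapse = ", "))
  if (any(!is_crt & !is.na(identifiability)))
    stop_hedge("non-CRT rows must have missing identifiability (uids: ",
               paste(utils::head(uid[!is_crt & !is.na(identifiability)], 5),
                     collapse = ", "), ")")
  df <- data.frame(uid = uid, is_crt = is_crt,
                   identifiability = identifiability,
                   year = as.integer(year), stringsAsFactors = FALSE)
  class(df) <- c("gold_labels", "data.frame")
  df
}

#' Read a gold-standard label file
#'
#' Comma- or tab-delimited text with header `uid,is_crt,identifiability,year`.
#' `is_crt` accepts `true/false`, `TRUE/FALSE`, `1/0`. Empty identifiability
#' for non-CRTs maps to `NA`.
#'
#' @param source File path, connection, or character vector of lines.
#' @return A [gold_labels()] data frame.
#' @export
read_labels <- function(source) {
  lines <- read_text_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_hedge("empty label file")
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("uid", "is_crt", "identifiability", "year")
  if (!all(need %in% names(df)))
    stop_hedge("label file must have header: ", paste(need, collapse = ","))
  crt_raw <- tolower(df$is_crt)
  if (!all(crt_raw %in% c("true", "false", "1", "0")))
    stop_hedge("unknown is_crt token(s): ",
               paste(unique(df$is_crt[!crt_raw %in% c("true", "false", "1", "0")]),
                     collapse = ", "))
  gold_labels(df$uid, crt_raw %in% c("true", "1"), df$identifiability, df$year)
}

#' Write a gold-standard label file
#' @param labels A [gold_labels()] data frame.
#' @param sink File path or connection.
#' @return Invisibly, the number of rows written.
#' @export
write_labels <- function(labels, sink) {
  out <- data.frame(
    uid = labels$uid,
    is_crt = ifelse(labels$is_crt, "true", "false"),
    identifiability = ifelse(is.na(labels$identifiability), "",
                             labels$identifiability),
    year = labels$year
  )
  con <- if (is.character(sink)) {
    f <- file(sink, open = "wb", encoding = "UTF-8"); on.exit(close(f)); f
  } else sink
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(nrow(out))
}

# Join labels against a corpus before evaluation; unmatched labels are
# reported, never silently dropped.
check_label_join <- function(labels, corpus, action = c("error", "warn")) {
  action <- match.arg(action)
  missing <- setdiff(labels$uid, corpus_uids(corpus))
  if (length(missing)) {
    msg <- paste0(length(missing), " labelled uid(s) absent from corpus: ",
                  paste(utils::head(missing, 5), collapse = ", "))
    if (action == "error") stop_hedge(msg) else warning(msg, call. = FALSE)
  }
  invisible(missing)
}
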