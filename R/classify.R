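# Title/abstract identifiability classification and term-frequency analysis.

#' Default unit-of-randomization lexicon
#'
#' Unit nouns (singular and plural) used by [classify_identifiability()] to
#' recognize unit-of-randomization phrasing such as "schools were
#' randomized" or "randomization by practice". User-extensible: pass a
#' modified vector to the classifier.
#'
#' @return Character vector of lowercase unit nouns.
#' @export
default_unit_lexicon <- function() {
  base <- c("school", "physician", "practice", "hospital", "community",
            "village", "ward", "team", "church")
  plural <- c("schools", "physicians", "practices", "hospitals",
              "communities", "villages", "wards", "teams", "churches")
  sort(c(base, plural))
}

design_word <- function(tok) {
  startsWith(tok, "cluster") | startsWith(tok, "communit") |
    startsWith(tok, "group")
}

clear_phrase_in <- function(toks) {
  if (length(toks) < 2) return(FALSE)
  n <- length(toks)
  any(design_word(toks[-n]) & grepl("^randomi[sz]", toks[-1]))
}

unit_phrase_in <- function(toks, lexicon, window) {
  rand_pos <- which(grepl("^random", toks))
  unit_pos <- which(toks %in% lexicon)
  if (!length(rand_pos) || !length(unit_pos)) return(FALSE)
  any(abs(outer(unit_pos, rand_pos, `-`)) <= window)
}

#' Classify how a trial's clustered design is identifiable
#'
#' Mirrors the manual classification of trial reports:
#' * `CLEAR` if a design phrase -- cluster/group/community followed
#'   immediately by a randomis/randomiz word (hyphens and spelling variants
#'   tolerated via tokenization) -- occurs in the title or abstract;
#' * else `UNIT` if a unit-of-randomization noun co-occurs within a token
#'   window of a randomization word (random/randomly/randomis.../randomiz...);
#' * else `NONE`: the design is not identifiable from title or abstract.
#'
#' Title and abstract are scanned independently (no cross-field windows).
#'
#' @param citation A [citation_record()].
#' @param unit_lexicon Unit-noun lexicon; see [default_unit_lexicon()].
#' @param window Maximum token distance between unit noun and randomization
#'   word for the `UNIT` class (default 4).
#' @return One of `"CLEAR"`, `"UNIT"`, `"NONE"`.
#' @examples
#' classify_identifiability(
#'   citation_record("00000001", "A cluster randomised trial of exercise"))
#' @export
classify_identifiability <- function(citation,
                                     unit_lexicon = default_unit_lexicon(),
                                     window = 4) {
  fields <- list(tokenize(citation$title), tokenize(citation$abstract))
  if (any(vapply(fields, clear_phrase_in, logical(1)))) return("CLEAR")
  if (any(vapply(fields, unit_phrase_in, logical(1),
                 lexicon = unit_lexicon, window = window))) return("UNIT")
  "NONE"
}

#' Term-frequency analysis of relevant vs other citations
#'
#' For every textword (title + abstract token) and every MeSH descriptor
#' (subheadings stripped, counted once per citation), counts the citations
#' containing it in the relevant set and in the complement, and ranks terms
#' by the relative document-frequency ratio, then relevant count, ties
#' broken alphabetically. Terms absent from the complement get an infinite
#' ratio and rank first. This is the frequency analysis used to discover
#' candidate filter terms.
#'
#' @param corpus A [medline_corpus()].
#' @param relevant Non-empty character vector of relevant uids (must be a
#'   subset of the corpus).
#' @return A data frame with columns `term`, `type` (`textword`/`mesh`),
#'   `n_relevant`, `n_other`, `ratio`, sorted by rank.
#' @export
term_frequency <- function(corpus, relevant) {
  relevant <- unique(as.character(relevant))
  if (!length(relevant)) stop_hedge("relevant set must be non-empty")
  uids <- corpus_uids(corpus)
  if (length(setdiff(relevant, uids)))
    stop_hedge("relevant uids not in corpus: ",
               paste(utils::head(setdiff(relevant, uids), 5), collapse = ", "))
  is_rel <- uids %in% relevant
  doc_terms <- lapply(corpus$citations, function(cit) {
    tw <- unique(c(tokenize(cit$title), tokenize(cit$abstract)))
    mh <- unique(normalize_mesh(cit$mesh_terms))
    rbind(
      if (length(tw)) data.frame(term = tw, type = "textword") else NULL,
      if (length(mh)) data.frame(term = mh, type = "mesh") else NULL
    )
  })
  tally <- function(sel) {
    tt <- do.call(rbind, doc_terms[sel])
    if (is.null(tt)) return(data.frame(term = character(0), type = character(0),
                                       n = integer(0)))
    ag <- stats::aggregate(list(n = rep(1L, nrow(tt))),
                           by = tt[c("term", "type")], FUN = sum)
    ag
  }
  rel <- tally(is_rel); oth <- tally(!is_rel)
  all <- merge(rel, oth, by = c("term", "type"), all = TRUE,
               suffixes = c("_relevant", "_other"))
  all$n_relevant <- ifelse(is.na(all$n_relevant), 0L, all$n_relevant)
  all$n_other <- ifelse(is.na(all$n_other), 0L, all$n_other)
  n_rel <- sum(is_rel); n_oth <- sum(!is_rel)
  rel_freq <- all$n_relevant / n_rel
  oth_freq <- if (n_oth > 0) all$n_other / n_oth else rep(0, nrow(all))
  all$ratio <- ifelse(oth_freq == 0, Inf, rel_freq / oth_freq)
  ord <- order(-all$ratio, -all$n_relevant, all$term)
  out <- all[ord, c("term", "type", "n_relevant", "n_other", "ratio")]
  rownames(out) <- NULL
  out
}
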