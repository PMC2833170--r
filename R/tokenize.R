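#' Tokenize free text for query matching
#'
#' Splits text into lowercase maximal alphanumeric runs. Hyphens, slashes and
#' all other punctuation act as separators, so "cluster-randomised" yields the
#' two tokens `cluster` and `randomised`. Token positions are 1-based
#' consecutive integers; adjacency (`adjN`) and phrase semantics are defined
#' over these positions. No stopwords are removed and no stemming is applied.
#'
#' @param text A character scalar (may be empty or `NA`).
#' @return A character vector of tokens; position `i` in the vector is token
#'   position `i` in the text. Empty or `NA` input gives a zero-length vector.
#' @examples
#' tokenize("Cluster-randomised trial")
#' tokenize("High schools (N = 24) were randomized")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop_hedge("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("[a-z0-9]+", tolower(text))[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
}
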