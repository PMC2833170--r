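# Shared fixtures, all built in code.

make_cit <- function(uid, title = "A study of something", abstract = "",
                     mesh = character(0), pt = "Journal Article",
                     journal = "Synthetic Journal", year = 2005) {
  citation_record(uid, title, abstract, mesh, pt, journal, year)
}

tiny_corpus <- function() {
  medline_corpus(list(
    make_cit("10000001", "A cluster randomised controlled trial of exercise",
             abstract = "Schools took part in the programme.",
             mesh = c("Humans", "*Health Promotion", "Cluster Analysis/methods"),
             pt = c("Randomized Controlled Trial", "Journal Article"),
             year = 2004),
    make_cit("10000002", "Serum markers in kidney disease",
             abstract = "Patients were randomised by physician to two arms.",
             mesh = c("Humans", "Biomarkers"), year = 2001),
    make_cit("10000003", "An animal model of arthritis",
             abstract = "Rats received the candidate compound.",
             mesh = c("Animals"), pt = "Journal Article", year = 2003)
  ), provenance = "tiny fixture")
}

# Published per-strategy contingency counts (retrieved totals and CRTs
# retrieved among 162 relevant in 25707 articles).
table2_counts <- function() {
  read.csv(system.file("extdata", "strategy_performance.csv",
                       package = "crthedges"), stringsAsFactors = FALSE)
}

trend_fixture <- function() {
  tt <- read.csv(system.file("extdata", "reporting_trend.csv",
                             package = "crthedges"))
  trend_table(tt$year, tt$identified, tt$total)
}

# A 162-trial gold-standard label fixture matching the published class
# structure: per-year CLEAR counts from the trend table, the remaining
# trials split UNIT then NONE deterministically to give totals 78/46/38.
gold_fixture_labels <- function(n_background = 0) {
  tt <- read.csv(system.file("extdata", "reporting_trend.csv",
                             package = "crthedges"))
  rows <- do.call(rbind, lapply(seq_len(nrow(tt)), function(i) {
    y <- tt$year[i]
    data.frame(year = rep(y, tt$total[i]),
               clear = seq_len(tt$total[i]) <= tt$identified[i])
  }))
  ident <- ifelse(rows$clear, "CLEAR", NA)
  nonclear <- which(!rows$clear)
  ident[nonclear[seq_len(46)]] <- "UNIT"
  ident[nonclear[-seq_len(46)]] <- "NONE"
  uid <- sprintf("%08d", seq_len(nrow(rows) + n_background))
  gold_labels(
    uid = uid,
    is_crt = c(rep(TRUE, nrow(rows)), rep(FALSE, n_background)),
    identifiability = c(ident, rep(NA_character_, n_background)),
    year = c(rows$year, rep(2005L, n_background))
  )
}
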