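# Random corpus and strategy generation for property tests. All callers wrap
# these in with_seed-style fixed seeding via set.seed().

rnd_vocab <- c("cluster", "randomised", "randomized", "trial", "school",
               "community", "intervention", "interventions", "patients",
               "care", "health", "programme", "outcome", "group", "therapy")
rnd_mesh <- c("Cluster Analysis", "Health Promotion", "Humans", "Animals")
rnd_pt <- c("Randomized Controlled Trial", "Journal Article", "Review")

random_corpus <- function(n = 50) {
  cits <- lapply(seq_len(n), function(i) {
    title <- paste(sample(rnd_vocab, sample(3:8, 1), replace = TRUE),
                   collapse = " ")
    abstract <- if (runif(1) < 0.8)
      paste(sample(rnd_vocab, sample(5:15, 1), replace = TRUE), collapse = " ")
    else ""
    mesh <- sample(rnd_mesh, sample(0:3, 1))
    if (length(mesh) && runif(1) < 0.3)
      mesh[1] <- paste0(sample(c("*", ""), 1), mesh[1],
                        sample(c("", "/methods"), 1))
    citation_record(sprintf("%08d", 20000000 + i), title, abstract,
                    mesh, sample(rnd_pt, sample(1:2, 1)),
                    "Random Journal", sample(2000:2007, 1))
  })
  medline_corpus(cits, provenance = "random fixture")
}

rnd_word <- function() {
  w <- sample(rnd_vocab, 1)
  r <- runif(1)
  if (r < 0.3) paste0(substr(w, 1, max(2, nchar(w) - 2)), "$")
  else if (r < 0.4) paste0(substr(w, 1, nchar(w) - 1), "?")
  else w
}

# random term-level expression rendered as dialect text
rnd_texpr <- function(depth) {
  if (depth <= 0 || runif(1) < 0.35) {
    if (runif(1) < 0.25) return(paste(sample(rnd_vocab, 2), collapse = " "))
    return(rnd_word())
  }
  op <- sample(c("AND", "OR", "NOT", paste0("adj", sample(1:3, 1))), 1)
  paste0("(", rnd_texpr(depth - 1), " ", op, " ", rnd_texpr(depth - 1), ")")
}

random_strategy <- function(max_lines = 6, max_depth = 3) {
  n_lines <- sample(2:max_lines, 1)
  lines <- character(n_lines)
  for (i in seq_len(n_lines)) {
    kind <- if (i >= 3 && runif(1) < 0.45) "refs"
            else sample(c("tw", "pt", "mesh"), 1, prob = c(0.6, 0.2, 0.2))
    lines[i] <- switch(kind,
      tw = paste0(i, ". ", rnd_texpr(sample(0:max_depth, 1)), ".tw."),
      pt = paste0(i, ". ", tolower(sample(rnd_pt, 1)), ".pt."),
      mesh = paste0(i, ". ", tolower(sample(rnd_mesh, 1)), "/"),
      refs = {
        k <- sample(seq_len(i - 1), min(i - 1, sample(1:3, 1)))
        op <- sample(c("AND", "OR", "NOT"), 1)
        paste0(i, ". ", paste(k, collapse = paste0(" ", op, " ")))
      })
  }
  parse_strategy(lines, name = "random")
}
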