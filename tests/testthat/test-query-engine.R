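test_that("tokenizer produces positional lowercase alphanumeric runs", {
  expect_equal(tokenize("Cluster-randomised trial"),
               c("cluster", "randomised", "trial"))
  toks <- tokenize("High schools (N = 24) paired on enrolment size were randomized")
  expect_equal(toks[2:4], c("schools", "n", "24"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize(NA_character_), character(0))
})

test_that("strategy parsing builds the documented syntax trees", {
  s <- parse_strategy(c("1. randomized controlled trial.pt.",
                        "2. animals/",
                        "3. humans/",
                        "4. 2 NOT (2 AND 3)",
                        "5. 1 NOT 4",
                        "6. cluster$ adj2 randomi$.tw.",
                        "11. cluster analysis/"))
  e1 <- s$lines[[1]]$expr
  expect_equal(e1$kind, "field"); expect_equal(e1$field, "pt")
  expect_equal(e1$value, "randomized controlled trial")

  e4 <- s$lines[[4]]$expr
  expect_equal(e4$kind, "not")
  expect_equal(e4$lhs$kind, "ref"); expect_equal(e4$lhs$n, 2L)
  expect_equal(e4$rhs$kind, "and")
  expect_equal(c(e4$rhs$lhs$n, e4$rhs$rhs$n), c(2L, 3L))

  e6 <- s$lines[[6]]$expr
  expect_equal(e6$kind, "field"); expect_equal(e6$field, "tw")
  expect_equal(e6$expr$kind, "adj"); expect_equal(e6$expr$n, 2L)
  expect_equal(e6$expr$lhs$stem, "cluster")
  expect_equal(e6$expr$lhs$trunc, "unlimited")

  e11 <- s$lines[[7]]$expr
  expect_equal(e11$kind, "mesh")
  expect_equal(e11$heading, "cluster analysis")
})

test_that("parse errors name the offending line", {
  expect_error(parse_strategy("1. 2 AND 3"), "line 1")          # forward ref
  expect_error(parse_strategy(c("1. a.tw.", "2. a.xy.")), "line 2")
  expect_error(parse_strategy(character(0)), "empty")
  expect_error(parse_strategy(c("1. a.tw.", "1. b.tw.")), "increasing")
  expect_error(parse_strategy("1. cluster$"), "qualifier")      # bare textword
  expect_error(parse_strategy("1. (1 AND 1).tw."), "reference")
  expect_error(parse_strategy("1. cluster$.pt."), "truncation")
})

test_that("expression matching follows adjacency, phrase and wildcard rules", {
  mk <- function(title, abstract = "")
    make_cit("30000001", title = title, abstract = abstract)
  ex <- function(line) parse_strategy(paste("1.", line))$lines[[1]]$expr

  adj <- ex("cluster$ adj2 randomi$.tw.")
  expect_true(evaluate_expression(adj,
    mk("A cluster randomised controlled trial of hand hygiene")))
  # reversed order at distance 2 still matches
  expect_true(evaluate_expression(adj,
    mk("Untitled", "patients randomised by cluster in the study")))
  # distance 3 exceeds the window
  expect_false(evaluate_expression(adj,
    mk("Untitled", "cluster of sites was then randomised")))

  opt <- ex("intervention?.tw.")
  expect_true(evaluate_expression(opt, mk("An intervention study")))
  expect_true(evaluate_expression(opt, mk("Complex interventions reviewed")))
  expect_false(evaluate_expression(opt, mk("An interventional approach")))

  phr <- ex("group$ randomi$.tw.")
  expect_true(evaluate_expression(phr, mk("Group randomization in practice")))
  expect_false(evaluate_expression(phr, mk("The group was randomized")))

  pt <- ex("randomized controlled trial.pt.")
  expect_true(evaluate_expression(pt,
    make_cit("30000002", pt = c("Randomized Controlled Trial", "Journal Article"))))
  expect_false(evaluate_expression(pt,
    make_cit("30000003", pt = "Controlled Clinical Trial")))

  msh <- ex("cluster analysis/")
  expect_true(evaluate_expression(msh,
    make_cit("30000004", mesh = "*Cluster Analysis/methods")))
  expect_false(evaluate_expression(msh,
    make_cit("30000005", mesh = "Cluster Headache")))
})

test_that("textword matches never span the title/abstract boundary", {
  cit <- make_cit("30000006", title = "Sites formed one cluster",
                  abstract = "Randomised allocation was used")
  adj <- parse_strategy("1. cluster$ adj2 randomi$.tw.")$lines[[1]]$expr
  expect_false(evaluate_expression(adj, cit))
})

test_that("strategy evaluation caches lines and honours set identities", {
  empty <- medline_corpus()
  expect_equal(evaluate_strategy(parse_strategy("1. dog$.tw."), empty)$retrieved,
               character(0))

  corpus <- tiny_corpus()
  res <- evaluate_strategy(parse_strategy(c("1. cluster$.tw.", "2. 1 NOT 1")),
                           corpus)
  expect_equal(res$retrieved, character(0))
  expect_equal(res$per_line[["1"]], "10000001")

  set.seed(401)
  rc <- random_corpus(60)
  a <- parse_strategy(c("1. cluster$.tw.", "2. intervention?.tw.",
                        "3. 1 OR 2", "4. 1 AND 2", "5. 1 NOT 2"))
  r <- evaluate_strategy(a, rc)$per_line
  expect_setequal(r[["3"]], union(r[["1"]], r[["2"]]))
  expect_setequal(r[["4"]], intersect(r[["1"]], r[["2"]]))
  expect_setequal(r[["5"]], setdiff(r[["1"]], r[["2"]]))
  expect_length(intersect(r[["5"]], r[["2"]]), 0)
  # idempotence
  expect_identical(evaluate_strategy(a, rc)$per_line, r)
})

test_that("adjacency windows nest and phrases imply adj1", {
  set.seed(402)
  for (rep in 1:20) {
    rc <- random_corpus(30)
    w1 <- sample(rnd_vocab, 1); w2 <- sample(rnd_vocab, 1)
    sets <- lapply(c(
      phrase = sprintf("1. %s %s.tw.", w1, w2),
      adj1 = sprintf("1. %s adj1 %s.tw.", w1, w2),
      adj2 = sprintf("1. %s adj2 %s.tw.", w1, w2),
      adj3 = sprintf("1. %s adj3 %s.tw.", w1, w2)
    ), function(txt) evaluate_strategy(parse_strategy(txt), rc)$retrieved)
    expect_true(all(sets$phrase %in% sets$adj1))
    expect_true(all(sets$adj1 %in% sets$adj2))
    expect_true(all(sets$adj2 %in% sets$adj3))
  }
})

test_that("engine agrees with the brute-force oracle on random instances", {
  set.seed(403)
  for (rep in 1:40) {
    rc <- random_corpus(sample(20:60, 1))
    st <- random_strategy()
    eng <- evaluate_strategy(st, rc)
    orc <- oracle_match(st, rc)
    expect_setequal(eng$retrieved, orc$retrieved)
    for (k in names(eng$per_line))
      expect_setequal(eng$per_line[[k]], orc$per_line[[k]])
  }
})

test_that("oracle sanity: single-term hit and Not containment", {
  corpus <- medline_corpus(list(make_cit("40000001", "A cluster of cases")))
  st <- parse_strategy("1. cluster$.tw.")
  expect_equal(oracle_match(st, corpus)$retrieved, "40000001")
  st2 <- parse_strategy(c("1. cluster$.tw.", "2. cases.tw.", "3. 1 NOT 2"))
  expect_true(all(oracle_match(st2, corpus)$retrieved %in% corpus_uids(corpus)))
})
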