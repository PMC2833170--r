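test_that("contingency construction matches set arithmetic", {
  relevant <- sprintf("R%03d", 1:162)
  retrieved <- c(relevant[1:152], sprintf("X%04d", 1:1545))
  ct <- make_contingency(retrieved, relevant, 25707)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(152, 1545, 10, 24000))
  expect_equal(ct$a + ct$b + ct$c + ct$d, ct$N)

  ct0 <- make_contingency(character(0), character(0), 10)
  expect_equal(c(ct0$a, ct0$b, ct0$c, ct0$d), c(0, 0, 0, 10))

  expect_error(make_contingency(as.character(1:5), as.character(6:10), 8),
               "inconsistent")

  set.seed(501)
  for (rep in 1:20) {
    pool <- as.character(1:100)
    ret <- sample(pool, sample(0:60, 1))
    rel <- sample(pool, sample(1:40, 1))
    ct <- make_contingency(ret, rel, 100)
    # direct set-comprehension oracle
    expect_equal(ct$a, sum(pool %in% ret & pool %in% rel))
    expect_equal(ct$b, sum(pool %in% ret & !pool %in% rel))
    expect_equal(ct$c, sum(!pool %in% ret & pool %in% rel))
    expect_equal(ct$d, sum(!pool %in% ret & !pool %in% rel))
  }
})

test_that("performance metrics reproduce published table arithmetic", {
  m5 <- compute_metrics(contingency_table(152, 1545, 10, 24000))
  expect_equal(round(100 * m5$sensitivity, 1), 93.8)
  expect_equal(round(100 * m5$one_minus_specificity, 1), 6.0)
  expect_equal(round(100 * m5$precision, 1), 9.0)

  m18 <- compute_metrics(contingency_table(146, 648, 16, 24897))
  expect_equal(round(100 * m18$sensitivity, 1), 90.1)
  expect_equal(round(100 * m18$precision, 1), 18.4)
  expect_equal(round(m18$nnr, 2), 5.44)
  expect_equal(m18$precision * m18$nnr, 1)

  m17 <- compute_metrics(contingency_table(161, 4422, 1, 21123))
  expect_equal(round(100 * m17$sensitivity, 1), 99.4)
  expect_equal(round(100 * m17$precision, 1), 3.5)
  # display convention: reciprocal of the 1-d.p. percentage
  expect_equal(round(m17$nnr_from_rounded_precision, 1), 28.6)

  und <- compute_metrics(contingency_table(0, 0, 5, 5))
  expect_true(is.na(und$precision))
  expect_true("precision" %in% und$undefined)
  expect_equal(und$sensitivity, 0)
})

test_that("relative recall counts reference-set retrieval", {
  ref <- sprintf("T%03d", 1:363)
  rr <- relative_recall(c(ref[1:355], "other"), ref)
  expect_equal(round(100 * rr$recall, 1), 97.8)
  expect_equal(relative_recall(c(ref, "extra"), ref)$recall, 1.0)
  expect_error(relative_recall("a", character(0)), "non-empty")
  set.seed(502)
  for (rep in 1:10) {
    ret <- sample(letters, sample(1:20, 1))
    ref <- sample(letters, sample(1:20, 1))
    expect_equal(relative_recall(ret, ref)$recall,
                 length(intersect(ret, ref)) / length(unique(ref)))
  }
  # recall of a union dominates its parts
  a <- sample(letters, 8); b <- sample(letters, 8); ref <- sample(letters, 12)
  expect_gte(relative_recall(union(a, b), ref)$recall,
             max(relative_recall(a, ref)$recall, relative_recall(b, ref)$recall))
})

test_that("Wald interval for a proportion difference matches the published CI", {
  ci <- diff_proportions_ci(16, 58, 62, 104)
  expect_equal(round(ci$difference, 1), 32.0)
  expect_equal(round(ci$lower, 1), 17.2)
  expect_equal(round(ci$upper, 1), 46.9)
  expect_true(ci$lower < ci$difference && ci$difference < ci$upper)

  same <- diff_proportions_ci(30, 100, 30, 100)
  expect_equal(same$difference, 0)
  expect_equal(same$lower, -same$upper)

  # interval width shrinks with sample size at fixed proportions
  w <- function(n) {
    ci <- diff_proportions_ci(round(0.3 * n), n, round(0.6 * n), n)
    ci$upper - ci$lower
  }
  expect_true(all(diff(sapply(c(50, 200, 800, 3200), w)) < 0))
})

test_that("Wald interval covers the true difference at about its nominal rate", {
  set.seed(503)
  n_sim <- 10000; n <- 100; p1 <- 0.3; p2 <- 0.6
  x1 <- rbinom(n_sim, n, p1); x2 <- rbinom(n_sim, n, p2)
  z <- qnorm(0.975)
  se <- sqrt(x1 / n * (1 - x1 / n) / n + x2 / n * (1 - x2 / n) / n)
  d <- x2 / n - x1 / n
  cover <- mean(d - z * se <= p2 - p1 & p2 - p1 <= d + z * se)
  expect_lt(abs(cover - 0.95), 0.02)
  # spot-check the vectorized oracle against the package function
  ci <- diff_proportions_ci(x1[1], n, x2[1], n)
  expect_equal(ci$lower / 100, d[1] - z * se[1], tolerance = 1e-12)
})

test_that("trend tests quantify the rise in clear identification", {
  tt <- trend_fixture()
  ls <- trend_test(tt)
  expect_equal(round(ls$statistic, 1), 3.6)
  expect_equal(ls$p_value, 2 * pnorm(-abs(ls$statistic)))
  expect_lt(abs(ls$p_value - 0.0003), 1e-4)

  ls2 <- trend_test(tt, exclude_years = 2006)
  expect_lt(ls2$p_value, 0.01)
  expect_lt(abs(ls2$p_value - 0.0012), 1e-3)

  # Cochran-Armitage route agrees with stats::prop.trend.test
  ca <- trend_test(tt, method = "cochran_armitage")
  ref <- prop.trend.test(tt$identified, tt$total, tt$year)
  expect_equal(ca$statistic^2, unname(ref$statistic), tolerance = 1e-10)
  expect_gt(ca$statistic, 0)

  # invariance to shifting all year scores
  tt_shift <- trend_table(tt$year - 2000, tt$identified, tt$total)
  for (m in c("ls_proportions", "cochran_armitage"))
    expect_equal(trend_test(tt_shift, method = m)$statistic,
                 trend_test(tt, method = m)$statistic, tolerance = 1e-10)

  # identical proportions every year: no trend
  flat <- trend_table(2000:2004, rep(5, 5), rep(10, 5))
  ca0 <- trend_test(flat, method = "cochran_armitage")
  expect_equal(ca0$statistic, 0)
  expect_equal(ca0$p_value, 1)

  expect_error(trend_test(trend_table(2000, 1, 2)), "2 rows")
})

test_that("kappa follows the closed-form po/pe arithmetic", {
  perf <- matrix(c(40, 0, 0, 60), 2)
  expect_equal(cohen_kappa(perf)$kappa, 1)

  chance <- outer(c(60, 40), c(70, 30)) / 10  # independent margins
  expect_equal(cohen_kappa(chance)$kappa, 0, tolerance = 1e-12)

  set.seed(504)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    k <- cohen_kappa(m)
    n <- sum(m)
    po <- sum(diag(m)) / n
    pe <- (sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])) / n^2
    expect_equal(k$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
    expect_true(k$lower <= k$kappa && k$kappa <= k$upper)
  }
  all_same <- matrix(c(10, 0, 0, 0), 2)
  expect_true(is.na(cohen_kappa(all_same)$kappa))
})

test_that("workload estimates screening hours from NNR", {
  expect_equal(round(workload_hours(794 / 146, 300, 3), 1), 81.6)
  expect_equal(round(workload_hours(4583 / 161, 300, 3), 0), 427)
  expect_equal(workload_hours(1, 20, 3), 1.0)
  m <- compute_metrics(contingency_table(146, 648, 16, 24897))
  expect_equal(workload_hours(m, 300, 3), 300 * (794 / 146) * 3 / 60)
  expect_error(workload_hours(compute_metrics(contingency_table(0, 5, 5, 5)),
                              300, 3), "NNR")
})

test_that("identifiability classification follows phrase and unit rules", {
  expect_equal(classify_identifiability(
    make_cit("90000001", "A cluster randomised trial of exercise")), "CLEAR")
  expect_equal(classify_identifiability(
    make_cit("90000002", "Title", "This group-randomized trial enrolled adults")),
    "CLEAR")
  expect_equal(classify_identifiability(
    make_cit("90000003", "Hygiene study", "In total 24 schools were randomized")),
    "UNIT")
  expect_equal(classify_identifiability(
    make_cit("90000004", "Title", "patients were randomized by physician")), "UNIT")
  expect_equal(classify_identifiability(
    make_cit("90000005", "Title", "patients were randomly assigned to drug or placebo")),
    "NONE")
  # the published distractor must not classify as CLEAR
  expect_false(classify_identifiability(
    make_cit("90000006", "Title",
             "patients in the participating hospitals were randomly assigned")) ==
    "CLEAR")
  # lexicon is configuration
  expect_equal(classify_identifiability(
    make_cit("90000007", "Title", "pubs were randomised to display the posters"),
    unit_lexicon = c("pubs")), "UNIT")
  expect_equal(classify_identifiability(
    make_cit("90000008", "Title", "pubs were randomised to display the posters")),
    "NONE")
})

test_that("trend aggregation reproduces the yearly identification table", {
  lab <- gold_fixture_labels(n_background = 50)
  tt <- aggregate_trend(lab)
  expect_equal(attr(tt, "total_identified"), 78L)
  expect_equal(attr(tt, "total_crts"), 162L)
  expect_equal(round(100 * attr(tt, "total_identified") /
                       attr(tt, "total_crts"), 1), 48.1)
  expect_equal(sum(tt$identified), attr(tt, "total_identified"))
  ref <- trend_fixture()
  expect_equal(tt$identified, ref$identified)
  expect_equal(tt$total, ref$total)

  one <- gold_labels("1", TRUE, "CLEAR", 2003)
  expect_equal(nrow(aggregate_trend(one)), 1L)

  missing_year <- gold_labels(c("1", "2"), c(TRUE, TRUE), c("CLEAR", "NONE"),
                              c(2003, NA))
  expect_warning(aggregate_trend(missing_year), "excluded")
})

test_that("term frequency ranks discriminating terms first", {
  corpus <- medline_corpus(list(
    make_cit("80000001", "cluster methods paper", "the cluster approach",
             mesh = c("Cluster Analysis/methods", "Humans")),
    make_cit("80000002", "general health study", "health outcomes improved",
             mesh = "Humans"),
    make_cit("80000003", "health survey", "survey of health habits", mesh = "Humans")
  ))
  tf <- term_frequency(corpus, relevant = "80000001")
  expect_true(is.infinite(tf$ratio[1]))
  expect_true("cluster" %in% tf$term[is.infinite(tf$ratio)])
  # MeSH descriptor counted once per citation, subheadings stripped
  row <- tf[tf$term == "cluster analysis" & tf$type == "mesh", ]
  expect_equal(row$n_relevant, 1L)
  # counting oracle on the shared term
  row_h <- tf[tf$term == "health" & tf$type == "textword", ]
  expect_equal(row_h$n_relevant, 0L)
  expect_equal(row_h$n_other, 2L)
  expect_error(term_frequency(corpus, character(0)), "non-empty")
})
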