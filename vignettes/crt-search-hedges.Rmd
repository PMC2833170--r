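---
title: "Evaluating search hedges for cluster randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating search hedges for cluster randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crthedges)
```

## The problem

Cluster randomized trials (CRTs) randomize intact groups — schools, medical
practices, hospital wards, villages — rather than individual participants.
Systematic reviewers who study CRT methodology need electronic search
filters ("hedges") that retrieve CRT reports from bibliographic databases
such as MEDLINE. Two properties govern a filter's usefulness:

* **sensitivity** (recall), the proportion of all relevant trials the filter
  retrieves, `a / (a + c)`;
* **precision**, the proportion of retrieved articles that are relevant,
  `a / (a + b)`, whose reciprocal is the **number needed to read** (NNR):
  how many citations must be screened per relevant trial found.

Here `a, b, c, d` are the cells of the usual retrieval-by-eligibility 2x2
table with total `N`; the false-positive rate `b / (b + d)` (fall-out, or
1 − specificity) is carried alongside.

Because MEDLINE has no publication type for cluster randomization, filters
must combine the indexer-assigned "Randomized Controlled Trial" publication
type with free-text and MeSH terms related to the clustered design. Whether
that works depends on reporting practice: only trials whose titles or
abstracts say "cluster randomized" (or group-/community-randomized) are
reachable by design-phrase textwords at all.

This package makes the whole evaluation pipeline executable and
reproducible without database access: a MEDLINE tagged-format reader and
writer, an engine for the Ovid-style query dialect the filters are written
in, the canonical filters as built-ins, the performance and trend
statistics, and a synthetic corpus generator that emulates the structure of
a hand-searched gold-standard pool.

## The query dialect and its semantics

Strategies are numbered-line programs:

```
1. randomized controlled trial.pt.
2. animals/
3. humans/
4. 2 NOT (2 AND 3)
5. 1 NOT 4
```

Each line is a Boolean/proximity expression over a citation's fields, or a
combination of earlier lines by number; the final line is the result. The
engine fixes the following semantics (Ovid's historical behaviour varies by
version, so the contract is pinned here and verified against a brute-force
oracle):

* Text is tokenized into lowercase maximal alphanumeric runs; hyphens and
  other punctuation separate tokens, so "cluster-randomised" is the token
  pair (`cluster`, `randomised`). No stemming, no stopword removal.
* `.tw.` (textword) matches within the tokenized title or the tokenized
  abstract, never across the boundary between them.
* `.pt.` is case-insensitive whole-value equality against a publication
  type entry; truncation wildcards are rejected there.
* A trailing `/` marks a MeSH heading line, matched unexploded (no tree
  expansion) against descriptors after stripping the major-topic `*` marker
  and any `/subheading` suffix.
* `term$` is unlimited right truncation; `term?` allows at most one extra
  trailing character (`intervention?` covers "intervention" and
  "interventions" but not "interventional").
* A multi-word sequence is a phrase: consecutive, in-order token matches.
* `x adjN y` requires match positions `p, q` in the same field with
  `|p − q| ≤ N`, in either order. For composite operands, the positions
  contributed by a match are the union of the participating operand
  positions.
* Operator precedence, loosest first: `OR`, `AND`, `NOT`, `adjN`,
  juxtaposition. A field suffix binds to the whole preceding expression at
  its parenthesis level, so `((a adj2 b) OR (a adj2 c)).tw.` scopes the
  union.

Every semantic rule above is enforced twice: once by the vectorized engine
(`evaluate_strategy()`) and once by `oracle_match()`, an intentionally
naive loop-based scan kept free of the engine's position-set algebra. The
test suite requires exact agreement on randomized strategy/corpus pairs as
well as on the full 18-line built-in programs.

## The shipped filters

Six built-ins cover the published numbered program: the RCT
publication-type filter with its animal-only exclusion (lines 1–5), the
cluster design-related textword block (6–9), the broad
intervention/health-promotion block (10–15), their union (16), and the two
composite hedges — highest sensitivity (`16 OR 5`, line 17) and highest
precision (`16 AND 5`, line 18). The files are stored verbatim, including
the printed form of the animal exclusion `2 NOT (2 AND 3)` (logically equal
to `animals/ NOT humans/`, but fidelity to the published text was preferred).
Two set identities follow from the construction and are asserted on
arbitrary corpora: line 17 retrieves exactly the union, and line 18 exactly
the intersection, of line 16 and line 5.

## Performance, validation and trend statistics

`make_contingency()` and `compute_metrics()` implement the 2x2 arithmetic.
Percentages print to one decimal place, matching the convention of the
published tables; raw proportions are always retained. Metrics with zero
denominators are explicit `NA` markers listed in `$undefined`, never silent
zeros. Two NNR conventions exist in the wild: from raw counts,
`(a + b) / a` (the default), and the reciprocal of the already-rounded
percentage (exposed as `nnr_from_rounded_precision`, since published
abstracts sometimes quote that form: 1/3.5% = 28.6 where raw counts give
28.5).

`relative_recall()` scores a filter against an independently assembled
reference set of trials. `diff_proportions_ci()` is the Wald interval
without continuity correction (z = 1.96 at 95%); that choice reproduces the
published pooled-period comparison (2000–2003 vs 2004–2007) exactly.

### The trend test

`trend_test()` deserves a note. The obvious choice for a trend in yearly
proportions is the Cochran–Armitage test with year scores, and it is
provided (`method = "cochran_armitage"`, cross-checked in the tests against
`stats::prop.trend.test`). On the shipped yearly table, however,
Cochran–Armitage gives z = 4.16 (p = 3e-5), while the published headline
pair (3.6, p = 0.0003) corresponds, exactly and self-consistently, to the
slope t-ratio of an **unweighted least-squares regression of the eight
yearly proportions on year**, referred to the standard normal
(t = 3.593, 2Φ(−3.593) = 0.00033). The default method is therefore
`"ls_proportions"`; both methods return a signed normal deviate and a
two-sided normal p so they are interchangeable in code. For the
sensitivity re-analysis that drops 2006 (the one year sampled from a
different journal frame), the least-squares route gives p = 0.0015 against
a published 0.0012; no standard variant we examined reproduces that value
exactly, and the default is the closest self-consistent choice. A perfectly
flat series fits the regression exactly (zero residual variance); the
statistic is defined as 0 in that case.

`cohen_kappa()` uses the closed form `(po − pe) / (1 − pe)` with the
large-sample standard error `sqrt(po(1 − po)/n) / (1 − pe)`; the exact CI
method behind the published reviewer-agreement interval is unstated, so the
standard asymptotic interval is used and the raw agreement table (which was
not published) is left to the user.

`workload_hours()` turns an NNR into screening time:
`target x NNR x minutes / 60`. With the published counts, assembling 300
CRTs at 3 minutes per retrieved article costs 81.6 h with the
highest-precision hedge (NNR 794/146) versus 427 h with the
highest-sensitivity hedge (NNR 4583/161).

### Identifiability classification

`classify_identifiability()` encodes the three-way reporting classification:

* `CLEAR`: a design phrase — `cluster`/`group`/`communit…` followed
  immediately by a `randomis`/`randomiz` token — in title or abstract;
* `UNIT`: otherwise, a unit-of-randomization noun within 4 tokens of a
  randomization word (`random`, `randomly`, `randomis…`, `randomiz…`);
* `NONE`: neither.

The window size and the unit-noun lexicon are configuration, not constants:
the published supplementary list of unit phrasings is unavailable, so the
default lexicon contains exactly the unit nouns quoted in the main text
(schools, physicians, practices, hospitals, communities, villages, wards,
teams, churches, in singular and plural). The window default of 4 reflects
the published observation that adjacency distances beyond 2 were already
imprecise while genuinely long-range phrasings ("High schools (N = 24)
paired on enrolment size … were randomized") are not electronically
reachable at any sensible window — the classifier deliberately files those
as `NONE`.

## The synthetic corpus generator

`generate_corpus()` exists so that every other module is testable without a
database download. Its defaults are the study conditions of the
gold-standard pool and were fixed once, from the printed tables:

* prevalence 162/25707 ≈ 0.63% CRTs;
* yearly weights proportional to the gold-standard trials per year
  (2000–2007);
* per-year probability that a CRT is `CLEAR` following the published yearly
  proportions (4/14 in 2000 … 30/52 in 2006, 11/17 in 2007), remaining mass
  split `UNIT:NONE = 46:38`;
* publication-type indexing sensitivity 0.938 for trials (cluster or
  individually randomized);
* non-trial composition: individually randomized trials 6.4%,
  health-promotion/programme-evaluation articles 11%, unrelated articles
  82.6% — back-derived from the published fall-out of the
  publication-type filter (6.0% ≈ 0.064 x 0.938), of the broad-term block
  (13.7% ≈ 0.11 + 0.064 x 0.42) and of the highest-precision hedge
  (2.5% ≈ 0.064 x 0.938 x 0.42);
* broad intervention vocabulary carried by 92% of CRTs (the broad block's
  published sensitivity) and 42% of individually randomized trials.

Text is template-based, drawn from a phrase bank anchored to the quoted
examples, including the distractor "patients in the participating hospitals
were randomly assigned", which is planted in individually randomized trials
precisely because unit-based searches must not mistake it for a cluster
design. Template generation guarantees — and `generate_corpus()` re-verifies
before returning — that every CRT's text classifies to its label.

What the generator does **not** emulate: real journal titles and abstracts
(vocabulary is a small closed set), MEDLINE indexing-policy changes over
time, correlated MeSH co-assignment, and the long tail of unusual
randomization units (football teams, pubs, "balozi"). Passing tests on
synthetic corpora therefore demonstrate the correctness of the machinery
and the internal consistency of the configured rates — not the real-world
performance of the filters, which is what the shipped contingency counts
record.

Determinism is part of the contract: the same `generator_config()` (seed
included) yields a byte-identical corpus and label file, and generation
restores the caller's RNG state.

## Numerical and design choices

* Tag dialect: the reader accepts padded (`TI  - `) and unpadded (`TI-`)
  tag lines; the writer emits the padded form, one line per field, fixed
  field order, so write–read is the identity and writes are
  byte-deterministic.
* Continuation lines join with a single space and internal whitespace
  collapses; tokenization is therefore position-stable across round trips.
* uids are opaque strings; the canonical 8-digit form is checked with a
  warning, not an error, since synthetic corpora may use other schemes.
* Labels joined against a corpus must resolve: unmatched uids raise an
  error naming them, never a silent drop.
* Empty abstracts participate normally (they match nothing).
* `term_frequency()` counts document frequency (once per citation), ranks
  by relative-frequency ratio with an infinite-ratio sentinel for terms
  absent outside the relevant set, and breaks ties by relevant count then
  alphabetically, so output order is deterministic.
* Problem sizes in the tests and the acceptance script were chosen to keep
  a full run at desk scale (a 12,000-article default-configuration corpus
  for parameter recovery; 100 random strategy/corpus pairs of 15–50
  citations for engine/oracle equivalence); binomial 3-sigma bounds make
  those checks seed-robust.

## Known limitations

* The engine implements exactly the dialect the shipped filters use; Ovid
  operators outside it (`exp`, frequency operators, limits) are rejected at
  parse time.
* Whether historical Ovid `$` implied bounded truncation, and whether
  `.tw.` covered fields beyond title and abstract in the original runs, is
  unrecorded; the contract here is unlimited truncation and title+abstract
  only, which reproduces the published arithmetic.
* The published trend p-value excluding 2006 (0.0012) is not exactly
  reproducible under any examined convention (closest: 0.0015, see above).
* Real-corpus performance claims rest on the shipped printed counts; the
  synthetic corpus validates machinery, not MEDLINE behaviour.
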