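# crthedges

Search filters ("hedges") that retrieve reports of **cluster randomized
trials (CRTs)** from MEDLINE-style bibliographic data, together with the
machinery to evaluate them. CRTs randomize intact groups — schools,
practices, villages — and MEDLINE has no publication type for them, so
reviewers rely on filters that combine the indexer-assigned
"Randomized Controlled Trial" publication type with cluster-design textwords
and MeSH headings. This package is for librarians, systematic reviewers and
methodologists who need those filters executable, measurable and
reproducible without live database access.

## What it does

* **MEDLINE tagged-format I/O** (`read_medline()`, `write_medline()`) and
  gold-standard label files (`read_labels()`), with strict validation and
  byte-deterministic round trips.
* **A query engine** (`parse_strategy()`, `evaluate_strategy()`) for the
  Ovid-style numbered-line dialect: Boolean operators, `adjN` proximity,
  `$`/`?` truncation, `.tw.`/`.pt.` field scopes, MeSH heading lines, line
  references — plus `oracle_match()`, an independent brute-force matcher
  used to verify the engine.
* **The canonical filters as built-ins** (`builtin_strategy()`): the RCT
  publication-type filter, the cluster-design and broad-term blocks, and
  the composite highest-sensitivity (`16 OR 5`) and highest-precision
  (`16 AND 5`) hedges.
* **Evaluation statistics**: contingency tables and sensitivity / fall-out /
  precision / number needed to read (`compute_metrics()`), relative recall
  against independent reference sets, Wald intervals for proportion
  differences, trend tests for reporting quality over time, Cohen's kappa,
  and screening-workload projections (`workload_hours()`).
* **A reporting classifier** (`classify_identifiability()`): is a trial
  "clearly identified" as cluster randomized in its title/abstract (CLEAR),
  identifiable only from unit-of-randomization phrasing (UNIT), or not
  identifiable at all (NONE)?
* **A seeded synthetic corpus generator** (`generate_corpus()`) emulating
  the structure of a hand-searched gold-standard pool (prevalence
  162/25707, rising clear-identification trend, 93.8% publication-type
  indexing sensitivity), so everything above is testable offline.
* **A CLI** (`hedge_cli()`, wrapper script in `inst/scripts/hedge`):
  `run`, `eval`, `trend`, `workload`, `simulate`, `list-builtins`.

The core quantities are the cells of the retrieval-by-eligibility table:
sensitivity `a/(a+c)`, fall-out `b/(b+d)`, precision `a/(a+b)`, and
NNR `(a+b)/a`.

## Worked example

Simulate a labelled corpus, run the highest-precision hedge, and score it:

```r
library(crthedges)

sim <- generate_corpus(generator_config(n_articles = 5000, seed = 42))
res <- evaluate_strategy("highest_precision", sim$corpus)
res
#> <result_set> strategy 'highest_precision': 155 of 5000 citations retrieved (final line 18)

ct <- make_contingency(res, sim$labels$uid[sim$labels$is_crt],
                       corpus_size(sim$corpus))
compute_metrics(ct)
#> <metrics_report>
#>   sensitivity:     81.1%
#>   1 - specificity: 2.5%
#>   precision:       19.4%
#>   NNR:             5.2
#>   counts: a=30 b=125 c=7 d=4838 N=5000
```

Of the 37 simulated CRTs, the hedge retrieved 30 while screening only 155
of 5,000 articles: roughly 5 citations read per trial found, at the cost of
missing the trials whose abstracts never phrase the design in retrievable
terms. The implied workload for assembling 300 trials at 3 minutes per
retrieved article:

```r
round(workload_hours(compute_metrics(ct), 300, 3), 1)
#> [1] 77.5
```

With the published retrieval counts the same arithmetic gives 81.6 hours
for the highest-precision hedge versus 427 hours for the
highest-sensitivity hedge — the trade-off the two composite filters exist
to expose.

The same pipeline runs from the shell:

```sh
Rscript -e 'crthedges::hedge_cli()' simulate --seed 42 --n 5000 \
    --out corpus.nbib --labels labels.csv
Rscript -e 'crthedges::hedge_cli()' eval --builtin highest_precision \
    --corpus corpus.nbib --labels labels.csv --report report.json
```

See `vignettes/crt-search-hedges.Rmd` for the query-dialect semantics, the
statistical conventions (including the two NNR conventions and the choice
of trend test), and what the synthetic generator does and does not emulate.

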