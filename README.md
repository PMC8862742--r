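# polarlex

Partisan polarization analysis of lexicon-filtered short-text corpora.

## What this is for

When legislators tweet about a health topic, *what* they talk about —
and how differently the two parties talk about it — is measurable.
polarlex packages the full measurement pipeline used in studies of
politicized vaccine discourse:

1. **Lexicon filtering** — keep tweets matching a vaccine term set
   (stem-prefix or exact matching), tag COVID-19 and other
   infectious-disease mentions, restrict to a date window.
2. **Descriptive contingency tests** — party-by-characteristic 2×2
   chi-square tests (retweets, disease mentions).
3. **Differential term use** — every unigram and 2-word phrase at
   ≥ 0.1% document frequency in either party, chi-square tested with
   Bonferroni control at *P* < .001, with direction and plot-ready
   scatter output.
4. **Topic modeling** — latent Dirichlet allocation fitted by a
   collapsed Gibbs sampler (`fit_lda()` returns a classed model with
   `print`, `summary`, `coef`, `plot`, `logLik`, `terms` methods),
   UMass coherence scoring, and grid-based selection of the topic
   count with a human-review sheet.
5. **Polarization** — mean topic representation by party and month
   (mean topic probability × 100) and the monthly polarization index

   P(m) = Σ_k | rep_D(k, m) − rep_R(k, m) |,   0 ≤ P ≤ 200,

   plus trend summaries and epidemic-wave segmentation from the nadir
   of the 7-day moving average of daily case counts.
6. **Synthetic corpora** — a generator that plants known party splits,
   topic structure and a polarization trend, so every estimator above
   is validated against ground truth without any data download.

The intended users are computational social scientists and
infodemiology researchers who need a reproducible, tested
implementation of these measurements.

## Worked example

```r
library(polarlex)

# a synthetic 2,000-tweet corpus with planted structure
sim <- generate_corpus(corpus_spec(n_tweets = 2000, seed = 42))
rec <- apply_flags(sim$records, lexicon())

descriptive_summary(rec)
#>              characteristic pct_D n_D pct_R n_R      chi2            p
#> 1                is_retweet  40.7 513  36.6 263  3.334871 6.782571e-02
#> 2            mentions_covid  52.4 660  55.8 401  2.064509 1.507635e-01
#> 3 mentions_noncovid_disease  14.7 185   7.8  56 20.397066 6.292620e-06

# fit a 5-topic model and measure polarization
# (alpha = 0.1: weak smoothing for representation measurement; see vignette)
dtm <- build_dtm(rec)
fit <- fit_lda(dtm, k = 5, alpha = 0.1, n_iter = 300, seed = 42)
fit
#> LDA topic model (collapsed Gibbs)
#>   topics:      5
#>   vocabulary: 381 terms
#>   documents:  2000
#>   iterations: 300 (burn-in 150, 15 snapshots)

ps <- polarization_series(fit$theta, rec[match(fit$doc_ids, rec$id), ])
head(as.data.frame(ps), 3)
#>     month    value n_D n_R
#> 1 2020-02 67.50952 104  66
#> 2 2020-03 35.38328 121  61
#> 3 2020-04 27.92039 125  68
```

The descriptive table reports each party's rate on a tweet
characteristic with the uncorrected 2×2 chi-square: here ~41% of
Democratic and ~37% of Republican tweets are retweets (a planted
difference too small to detect at n = 2,000), while the planted
non-COVID-disease gap (14.7% vs 7.8%) is highly significant. The
polarization series tracks the planted V shape: discourse divergence
falls from February to an April nadir (27.9) before rising through
November. Values are on the 0–200 scale — 0 means both parties spread
probability over topics identically, 200 means they discuss disjoint
topics.

Run a full pipeline (filter → descriptive → terms → topics → metrics →
report) with:

```r
write_tweets(sim$records, "corpus.jsonl")
cfg <- run_config("corpus.jsonl", "out/", k = 5, n_iter = 300, seed = 42)
run_pipeline(cfg)   # writes CSV/JSON artifacts, manifest.json, report.md
```

## Further reading

The methods vignette
(`vignettes/partisan-discourse-methods.Rmd`) documents the models,
parameter defaults, the generator's design, calibration caveats for
short documents, and known limitations.
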