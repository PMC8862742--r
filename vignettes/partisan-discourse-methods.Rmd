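---
title: "Measuring partisan polarization in vaccine discourse: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring partisan polarization in vaccine discourse: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarlex)
```

polarlex quantifies how differently two political parties talk about a
health topic on social media. It was built for the setting of
legislator tweets about vaccination during 2020, but every stage is
generic: a lexicon defines the corpus, chi-square tests compare
parties on tweet characteristics and on individual terms, a topic
model summarizes what the corpus is about, and a monthly polarization
index tracks how far apart the parties' topic usage drifts.

This vignette explains the models, the tunable parameters, the
synthetic-data generator used for validation, and the numerical
choices the package makes in ambiguous situations.

## Corpus definition and lexicon filtering

A tweet enters the analysis when its normalized tokens match the
vaccine term set. Normalization (`normalize_text()`) lowercases,
strips URLs, @-handles and a leading retweet marker, removes `#` while
keeping the hashtag word, and splits on punctuation; hyphenated
compounds are indexed both as the compound and as their parts, so
"anti-vaxxers" is findable either way.

Two matching modes exist because published term lists are usually
exact surface forms while real corpora contain inflections. The
default `stem_prefix` mode matches tokens beginning with any of the
stems `vaccin`, `vax`, `immuniz`, `immunis`, `inoculat`, `innoculat`,
`antivax`, `anti-vax`; a tweet such as "the best way to protect this
season is to get vaccinated" matches only under stems — an exact list
of nouns like "vaccine"/"vaccination" demonstrably under-includes
inflected verb forms. `exact_word` mode is retained for strict
replication of a fixed list, including parenthetical spelling variants
("vax(x)" covers both `vax` and `vaxx`).

COVID-19 and non-COVID-disease mentions are tagged independently with
exact term lists (defaults: `covid`, `covid19`, `covid-19`,
`coronavirus`, `sars-cov-2`, `sarscov2`; and `flu`, `influenza`,
`measles`, `mmr`, `hpv`, `polio`, `smallpox`, `fluseason`). Both flags
can be true on one tweet. A manual relevance review is replaced by an
optional `exclusion_terms` list, empty by default. The study window
(February 1 through December 11, 2020) is applied inclusively at both
endpoints, with timestamps compared as UTC dates.

## Descriptive contingency tests

Party-by-characteristic comparisons (retweet status, COVID mention,
non-COVID-disease mention) use Pearson's chi-square on the 2×2 table
without continuity correction — sample sizes in this setting are in
the thousands, where the correction is both unnecessary and
conservative; a `correct = TRUE` switch exists. Third-party and
unknown-party records are excluded from all partisan tests. Printed
percentages use round-half-up to one decimal (`party_share()`),
matching reporting conventions; base R's banker's rounding would
print 6.2 for 6.25%.

## Differential term use

`build_term_table()` counts, for every unigram and adjacent bigram,
the number of tweets per party containing it at least once. Document
frequency is deliberate: the tweet is the analysis unit throughout the
package, and repeating a word inside one tweet should not change any
proportion (a token-share variant is a config switch). Bigrams are
formed within sentences only, so phrases never span sentence-final
punctuation. Stopwords are retained here — phrases like "record time"
and common words like "free" are exactly the kind of partisan signal
this analysis wants — and no stemming is applied, because surface
forms ("launched", "anti-vaxxers") carry tone.

A term is retained when its document frequency reaches 0.1% of either
party's tweets (the per-party OR reading; a pooled-denominator variant
is available since the phrase "frequency across tweets by Democrats or Republicans" admits either denominator). Each
retained term gets a chi-square test of its 2×2
contains-by-party table; the family for Bonferroni correction is the
number of retained terms, and a term is flagged at corrected
*P* < .001. Direction is the party with the higher proportion; exact
ties are reported as `NA` rather than forced.

## Topic model

`fit_lda()` implements latent Dirichlet allocation with collapsed
Gibbs sampling, written for this package; collapsed Gibbs was chosen
because it is simple, auditable, and exactly reproducible under a
seed. Token-level topic assignments are resampled from

$$p(z_i = k \mid \cdot) \propto (n_{dk} + \alpha)\,
  \frac{n_{kw} + \beta}{n_k + V\beta}$$

and the reported $\phi$ (topic-word) and $\theta$ (document-topic)
matrices are posterior means over thinned post-burn-in count
snapshots (every 10th iteration after the first half), which is more
stable than a single final state. The joint log-likelihood is traced
per iteration; its trend is checked in the tests rather than used for
a convergence stop.

Defaults follow common practice: $\alpha = 50/K$, $\beta = 0.01$,
500 iterations. There is no hyperparameter optimization. Documents are
the filtered tweets (retweets included — they are part of what
followers see); the vocabulary excludes a standard English stopword
list and can be pruned by minimum document frequency and maximum
document proportion. Documents emptied by pruning are dropped with
their ids logged.

### Choosing the number of topics

`select_k()` fits a grid of candidate $K$ (same seed per candidate),
scores each topic's UMass coherence over its top 10 words,

$$C_t = \sum_{i=2}^{N}\sum_{j<i}
  \log\frac{D(w_i, w_j) + 1}{D(w_j)},$$

and recommends the $K$ with the highest mean coherence. UMass is
intrinsic — it needs no external reference corpus — which suits a
specialized political corpus. Because topic-count selection in practice combines
coherence with manual interpretability review, `select_k()` also emits
a review sheet (top 10 words and top 10 tweet ids per topic per
candidate) for a human pass; `sample_tweets()` draws additional random
tweets whose dominant topic matches, supporting spot checks. Topic
retention after review is expressed as an `included_topics` vector
consumed by all downstream metrics, defaulting to all topics.

## Topic representation and the polarization index

Mean topic representation for a party-period stratum is the mean of
the per-tweet topic probabilities times 100; over all topics it sums
to 100 per stratum. The monthly polarization index is

$$P(m) = \sum_{k} \bigl|\,\overline{\theta}^{D}_{k}(m) -
  \overline{\theta}^{R}_{k}(m)\,\bigr| \times 100,$$

which ranges from 0 (identical topic usage) to 200 (completely
disjoint usage). Months missing either party yield `NA`, never a
fabricated 0. Restricting `included_topics` can only reduce the value,
and swapping party labels leaves it unchanged — both properties are
tested.

Per-topic party comparisons default to a two-sample Wilcoxon rank-sum
test on per-tweet topic probabilities with Bonferroni family equal to
the number of included topics. A "signed-rank" comparison
across unpaired party groups is statistically ambiguous about the
pairing unit; a paired signed-rank over monthly (D, R) representation
pairs is therefore provided as `method = "signedrank_monthly"`, and
neither variant is privileged.

### A calibration caveat for short documents

Posterior-mean $\theta$ under $\alpha = 50/K$ shrinks a 15-token tweet
toward the uniform distribution by roughly $L/(L + 50)$ in the
data-vs-prior weighting, which biases every representation difference
— and hence the polarization index — toward zero. When topic
representation is the *measurement target* (rather than exploratory
topic discovery), the package therefore fits with weak smoothing
($\alpha = 0.1$). Conversely, when documents are genuinely mild
mixtures of topics, no smoothing choice can recover the mixture of a
15-token document: validation shows the index is recovered within a
few points when documents are topic-concentrated (one dominant topic
per tweet, the realistic regime for single-subject tweets) and
overshoots when planted documents are near-uniform mixtures. The
estimated-theta validation is therefore run in the concentrated
regime; the Monte-Carlo validation against sampled true mixtures uses
the mild-mixture regime.

## Pandemic wave segmentation

`segment_waves()` computes a trailing 7-day moving average of daily
new cases and places wave boundaries at its interior strict local
minima (first day of any plateau); when more nadirs exist than waves
requested, the deepest are kept, earliest-first on ties. A monotone
series yields a single wave with a warning. Differential term analysis
can then be repeated inside each wave, with the frequency floor and
Bonferroni family recomputed per wave.

## The synthetic corpus generator

Because real legislator tweet corpora are not redistributable, validation
rests on `generate_corpus()`, which plants known structure:

- **Party volume** D/R/I = 61.8 / 37.2 / 1.0% by default; third-party
  records are generated but excluded from partisan statistics, matching
  the two-party framing of the analysis.
- **Tweet characteristics**: per-party retweet probabilities
  (D 0.403, R 0.369), COVID-mention probabilities (D 0.532, R 0.583)
  and non-COVID-disease probabilities (D 0.144, R 0.075) — the per-party
  rates characteristic of 2020 legislator vaccine discourse.
- **Topics**: each planted topic is a Dirichlet(0.05) draw over an
  abstract vocabulary (sparse, hence separable); each tweet's topic
  mixture is Dirichlet(`mixture_concentration` × planted party-month
  mean); lengths are Poisson(15) truncated at 3 tokens so bigram
  extraction never degenerates.
- **Polarization trend**: party-month mixture means are symmetric
  displacements from uniform along a fixed partisan axis, scaled so
  the planted index follows a V-shaped profile (60 in February down to
  25 in April, rising to 95 in November, dipping to 90 in December) —
  the qualitative trajectory reported for 2020 legislator vaccine
  discourse.
- **Lexicon guarantee**: a vaccine anchor token (`vaccine`,
  `vaccination` or `vax`) is appended — not substituted — whenever a
  document sampled none, so the filter passes every document without
  distorting the planted topic structure.
- Timestamps are uniform within calendar months (UTC); months are the
  binning unit everywhere.

What the generator does **not** emulate: English syntax, hashtag
semantics, retweet cascades, author-level volume heterogeneity beyond
the party split, or vocabulary drift within a month. Passing tests
therefore demonstrate that the estimators recover known structure from
corpora with this statistical shape — not that the pipeline's
scientific conclusions transfer to any particular real corpus.

`generate_case_series()` plants epidemic waves whose smoothed nadirs
are exactly known: the raw series samples a raised-cosine wave curve
three days ahead of the trailing 7-day window (so the window is
centered), with per-segment amplitudes scaled to equalize curvature on
both sides of every trough. With no noise the moving-average minima
land exactly on the planted days; troughs must be ≥ 7 days from the
series ends and ≥ 14 days apart (epidemic waves span weeks).

## Validation scales and numerical choices

The shipped checks use problem sizes chosen to exercise each estimator
meaningfully while staying quick on one CPU:

- LDA recovery: 5 planted topics, vocabulary 500, 2,000 documents of
  mean length 15, 500 Gibbs iterations; estimated and planted
  topic-word vectors are matched by exhaustive-permutation assignment
  (mean cosine ≈ 0.93 at these settings, checked against a 0.8 floor).
- Topic-count selection: grid {2, 5, 10} over 20 replicate corpora.
- Polarization: Monte-Carlo agreement with the planted index at 5,000
  tweets/party/month; trend-sign recovery at 2,000 tweets/month.
- Term tests: planted 5% vs 1% enrichment at 5,000 tweets/party;
  200 label shuffles for the null calibration.

Tie-breaks are deterministic everywhere (alphabetical for equal word
probabilities, id order for equal document probabilities,
first-occurrence for equal nadirs). Degenerate inputs error loudly:
zero-margin contingency tables, empty party strata, windows with
reversed dates, vocabularies smaller than the topic count.

## Known limitations

- The collapsed Gibbs sampler is exact but not fast for very large
  corpora; there is no variational or online variant.
- UMass coherence rewards frequently cooccurring word sets and can
  rank a near-duplicate topic split as coherent as the true split; the
  review sheet exists precisely because automated coherence is not a
  complete selection criterion.
- The polarization index inherits the topic model's resolution: two
  parties discussing the same topic with opposite sentiment are not
  polarized by this measure, so it is a lower bound on discourse
  divergence.
- Estimated topic representation from very short documents is biased
  toward uniform under strong smoothing and toward sharpness under
  weak smoothing; the package's measurement default (weak smoothing,
  concentrated documents) is calibrated for the single-subject-tweet
  regime.
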