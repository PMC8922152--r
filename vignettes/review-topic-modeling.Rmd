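---
title: "Topic modeling of patient medication reviews: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic modeling of patient medication reviews: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pmrtopics analyzes patient-written drug reviews: free-text comments paired
with a 1–5 satisfaction rating and reviewer metadata (age, gender, time on
medication). It answers three kinds of questions: what latent topics the
reviews of a drug contain, how the prevalence of each reviewer's dominant
topic varies across age and time-on-medication strata, and whether
satisfaction ratings differ by dominant topic and stratum. This vignette
documents the model, the parameters that matter, the synthetic data
generator that stands in for scraped review sites, and the numerical and
design choices a maintainer would want spelled out.

## The model

Each review $d$ is modeled as a mixture of $K$ topics and each topic $k$ as
a distribution over the vocabulary — latent Dirichlet allocation with
symmetric priors:

$$\theta_d \sim \mathrm{Dir}(\alpha), \qquad
  \phi_k \sim \mathrm{Dir}(\beta), \qquad
  z_{di} \sim \mathrm{Cat}(\theta_d), \qquad
  w_{di} \sim \mathrm{Cat}(\phi_{z_{di}}).$$

Inference is collapsed Gibbs sampling: $\phi$ and $\theta$ are integrated
out and each token's topic is resampled from

$$p(z_{di} = k \mid z_{-di}, w) \;\propto\;
  (n_{dk}^{-di} + \alpha)\,
  \frac{n_{kw}^{-di} + \beta}{n_{k}^{-di} + V\beta},$$

where the $n$'s are topic-count caches with the current token excluded.
The sampler (in C++ via Rcpp, with its own seeded mt19937 stream so fits
are bit-reproducible and independent of R's RNG state) is validated two
ways in the test suite: count caches are rebuilt from the final assignment
vector, and on corpora small enough to enumerate every assignment vector
the sampled co-assignment frequencies are compared with the exact collapsed
posterior. Co-assignment probabilities $P(z_i = z_j)$ are used for that
comparison because single-token marginals are exactly $1/K$ under label
exchangeability and would test nothing.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `K` | 5 | topics per drug; five is the working size for review corpora of this kind, and `select_num_topics()` can choose it from data |
| `alpha` | `50/K` | document–topic concentration (standard collapsed-Gibbs convention) |
| `beta` | 0.1 | topic–word concentration |
| `n_iterations` | 2000 | total sweeps |
| `burn_in` | 500 | discarded sweeps |
| `sample_lag` | 10 | thinning for the posterior-mean $\hat\phi,\hat\theta$ |

Posterior means are averaged over the ~150 retained samples, which is more
stable than a single draw. The per-review *primary topic* — the unit of all
downstream analysis — is the topic holding the most tokens in the final
sweep, matching the token-count reading of "the topic most frequently
mentioned in a review"; `primary_topics(..., method = "theta")` offers the
$\arg\max \hat\theta_d$ reading instead. The two agree except near ties,
and all ties break deterministically to the lowest topic index.

### Choosing the number of topics

`select_num_topics()` fits one model per candidate $K$ and scores each by
*topic density*: the mean cosine similarity over all unordered pairs of
rows of $\hat\phi$. Distinct, independent topics have near-orthogonal word
distributions, so the criterion is minimized. Over-fitted models split a
real topic into near-duplicates (cosine near 1 between them); under-fitted
models merge topic supports and also raise the mean. The per-$K$ score
table is returned so the curve can be plotted rather than trusted blindly.
Which density criterion to use was an open choice; mean pairwise cosine is
implemented because it is simple, bounded in $[0,1]$, and directly measures
the "distinctive and independent" property being sought.

## Preprocessing

Comments become a document–term matrix through a fixed, order-documented
chain, each step exposed as its own function:

1. case-fold; delete punctuation and digit *characters*; split on
   whitespace; drop tokens shorter than 2 characters; apply a whole-token
   typo-correction map;
2. merge configured bigrams (defaults: "erectile dysfunction", "side
   effect") into single `a_b` tokens, one left-to-right pass, merged tokens
   never re-merged;
3. remove stopwords (packaged Snowball English list plus de-apostrophized
   contraction forms, configurable; "irrelevant word" removal is folded into
   this list);
4. Porter-stem every token (bigrams component-wise) and *complete* each
   stem back to the most corpus-frequent surface form sharing it, ties to
   the lexicographically smallest — so reports show readable words, not
   stems;
5. tally counts; vocabulary ordered by descending corpus frequency then
   lexicographically, so the matrix is bit-reproducible; documents emptied
   by preprocessing are dropped and reported, and carry a missing primary
   topic downstream.

The Porter (1980) stemmer is implemented in the package and pinned by a
frozen table of reference stems. Tokenizer conventions (deletion rather
than space-substitution of punctuation, minimum length 2) are the simplest
reading of the cleaning steps being emulated and are fixed in
`preprocess_config()` rather than hidden.

## Eligibility filtering

`filter_reviews()` removes, in order: records with whitespace-only
comments; records whose comment contains `http`, `.com`, or `www.`
(case-insensitive substring — the spam markers); records with missing age
or age under 19 (age exactly 19 is eligible). Female-authored records are
retained: partners and caregivers legitimately report the user's
experience. Precedence affects only which rule a doubly-ineligible record
is logged under, never the surviving set; the filter log reconciles exactly
(`input = output + removed`). Whether a review whose only text sits in a
separate side-effects field counts as "commented" is genuinely ambiguous;
the default says no, and `rescue_side_effect_comment = TRUE` flips that.

## The synthetic generator

No review corpus ships with the package, so `synthetic_config()` +
`generate_ground_truth()` + `render_corpus()` produce one with known
structure. The defaults are the study conditions the pipeline targets:

* two drug cohorts of 463 and 919 eligible reviews (the observed cohort
  imbalance of the motivating setting);
* `K_gen = 5` topics over a 200-pseudo-word vocabulary; topic–word rows
  drawn from `Dir(beta_gen)`;
* nine age × time strata with per-stratum Dirichlet concentrations, each
  stratum mildly favoring one topic — topic prevalence varies by stratum
  the way real review corpora do; stratum membership uses the marginal
  age (0.26/0.57/0.17) and time (0.42/0.28/0.30) proportions of the
  motivating setting;
* document lengths Poisson(100) truncated at 1. Review length statistics
  are not published for the motivating corpora, so the mean is a free
  choice exposed in the config; 100 tokens is a realistic comment length
  for health-portal reviews, which run longer than microblog posts;
* ratings = round-half-up-then-clip of
  $3 + \text{effect}(\text{primary topic}) + \text{shift}(\text{stratum}) +
  \mathcal N(0, 1.4^2)$. Additive effects with Gaussian noise is the
  minimal structure supporting rating-by-topic analyses; 1.4 matches the
  typical spread of 1–5 review ratings, the topic effects default to a
  ±0.9 ramp, and the time-on-medication shifts (−0.35, +0.2, +0.4) encode
  "longer on the drug, more satisfied";
* contaminants injected at spam 3%, empty-comment 5%, under-age/missing-age
  4.5% (about 12% total attrition, the ballpark observed when scraped
  review sets are filtered), each drawn binomially and recorded in a
  generator log so filter tests have exact expected counts.

Pseudo-words are CVCVCV syllable strings chosen so that cleaning leaves
them intact, none is a stopword, none contains a spam marker, and their
Porter stems are pairwise distinct. That makes the rendered corpus
*invertible*: after decoration with punctuation, digits and capitalisation
(30% of tokens by default), preprocessing recovers exactly the generated
tokens, and the DTM vocabulary maps one-to-one onto the generating
vocabulary. Token conservation and seeded byte-reproducibility are tested
properties, not hopes.

What the generator does **not** emulate: English prose and collocations
(the default bigram list finds nothing to merge in synthetic text), real
site field layouts, drug-name vocabulary, spam that avoids the three
markers, duplicate reviews, or non-English text. Passing tests therefore
demonstrate that the machinery is correct under the generative model LDA
assumes — not that five interpretable topics will emerge from any
particular scraped corpus.

### Test problem sizes

Recovery and selection checks run on corpora of 400 documents × ~100
tokens over a 50-term vocabulary with block-structured topics
(within-block concentration 5, off-block 0.05) and symmetric document
mixtures $\alpha_{gen} = 0.5$ — the package's operational definition of
"well-separated topics". Moderate mixing matters: with near-pure documents
an under-fitted model can park disjoint blocks in separate topics and look
spuriously "dense-free", whereas mixed documents force merged supports and
give the density criterion its signal. Under these conditions the fitted
$\hat\phi$ matches the generating topics at mean cosine ≥ 0.99 after
permutation alignment, and density-based selection recovers $K=3$ from
candidates {2,3,4,5} in ≥ 9 of 10 seeded replicates.

## Statistical layer

* **Share tables**: counts and percentages of primary topics per stratum,
  margins included; percentages are rounded half-up to one decimal (the
  convention of the report style being mirrored), so columns sum to
  100 ± 0.1.
* **Fisher exact test** (topic distribution between drugs): 2×2 tables get
  the exact two-sided hypergeometric p-value; larger tables get a seeded
  Monte-Carlo p over tables drawn with fixed margins (default 10^5 reps)
  with its binomial standard error reported. Full network enumeration of
  r×c tables is deliberately out of scope; the Monte-Carlo p is checked
  against brute-force enumeration on small tables in the tests.
* **Two-sample t**: Welch by default — group sizes and variances in rating
  data are visibly unequal — with the pooled variant available.
* **One-way ANOVA** (ratings across strata within a topic): classic
  fixed-effects F with $(g-1, N-g)$ df.
* All tests are two-sided at $\alpha = .05$, with no multiple-testing
  correction — each p-value is reported per comparison, and the absence of
  correction is a documented property of the output, not an oversight.
* SD is reported missing for cells with $n < 2$; records missing a rating,
  a stratum, or a primary topic are excluded from the relevant denominator
  and counted.

## Reproducibility mechanics

One global seed drives everything. Each pipeline stage derives a child
seed by mixing the stage name into the global seed (`child_seed()`), so
stages can be re-run in isolation and adding a drug does not shift the
randomness of another. The C++ sampler never touches R's RNG. Output
files contain no timestamps or absolute paths; the run manifest records
MD5 checksums of every artifact plus a hash of the canonical JSON
serialization of the configuration, and two runs from one configuration
are byte-identical — an invariant enforced by the test suite.

## Degenerate inputs and edge policies

* `K = 1` reduces to closed form ($\theta \equiv 1$, $\hat\phi$ the
  smoothed corpus frequencies) and is allowed; `K` exceeding the token
  count warns but fits.
* An all-empty corpus after preprocessing is a hard error; single empty
  documents are dropped and reported.
* Ratings outside 1..5 are validation errors naming the record; missing
  metadata maps to typed sentinels ("" for text, `"missing"` for
  categorical, `NA` for numeric) so CSV/JSONL round-trips are unambiguous.
* Degenerate test inputs (both groups zero-variance, empty groups, zero
  contingency margins) raise errors naming the offending group or margin
  rather than returning NaN.

## Limitations

Topic *naming* is inherently human: the package emits top-30 word lists
and share tables, never labels. The density criterion is one of several
published heuristics for choosing $K$ and can be flat between adjacent
candidates on weakly separated corpora. The Monte-Carlo Fisher p is an
estimate with a reported standard error, not an exact value. And because
the synthetic generator satisfies LDA's assumptions by construction,
performance on it bounds nothing about scraped text that violates them —
the generator exists to make the machinery falsifiable offline, not to
simulate the web.
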