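---
title: "Contextual semantic similarity measures: model, policies and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual semantic similarity measures: model, policies and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextsim)
```

## The problem

During natural reading, words that fit their preceding context are fixated
more briefly. One family of predictors for this effect quantifies, token by
token, how semantically related a target word is to the words just before it,
using distributional word embeddings: each word is a fixed-length real vector
learned from corpus co-occurrence, and relatedness is a function of the
vectors in a context window. `contextsim` computes six such *contextual
semantic similarity* scores per token so they can be exported as predictors
for reading-time models (eye-tracking fixation durations in particular).

## The dynamic measure

Let $w^t$ be the target word and $w^{t-3}, w^{t-2}, w^{t-1}$ its three
preceding words, each with an embedding vector of dimension $d$. Stack the
four vectors into a $4 \times d$ matrix and compute the $4 \times 4$ matrix
$R$ of Pearson correlations between the rows, i.e. between word vectors
across embedding dimensions:

$$ r_{ij} = \frac{\sum_k (v_{ik} - \bar v_i)(v_{jk} - \bar v_j)}
  {\sqrt{\sum_k (v_{ik} - \bar v_i)^2 \sum_k (v_{jk} - \bar v_j)^2}}. $$

The **dynamic similarity** of $w^t$ is the sum of the $k(k+1)/2 = 6$ entries
of the strict lower triangle of $R$ — one correlation per unordered word
pair, covering both target–context and context–context relatedness. The
**simpler dynamic similarity** keeps only the target's row: the sum of its
$k = 3$ correlations with the context words. Each cell is interpretable as
the relatedness of one word pair, and the sums are bounded
($[-6, 6]$ and $[-3, 3]$ at $k = 3$).

```{r fig3}
fx <- fig3_fixture()
fx$corr
dynamic_similarity(fx$corr)
simpler_dynamic_similarity(fx$corr)
```

Four comparison measures are implemented alongside:

* `cosine_content` — cosine of the target vector with the *sum* of the
  vectors of up to three preceding content words in the sentence (the
  classic content-word cosine baseline);
* `cosine_all` — the same cosine but over the three preceding words
  regardless of word class;
* `euclidean_sentence` — $1/d_2$, with $d_2$ the Euclidean distance between
  the target vector and the *mean* vector of all preceding words in the
  sentence;
* `euclidean_fixed` — the same inverse distance with a fixed three-word
  context.

## Window policies

Each measure is bound to exactly one context policy
(see `measure_policy()`):

* `FIXED_K_ALL` (dynamic measures, `cosine_all`, `euclidean_fixed`): the
  `k = 3` nearest preceding in-vocabulary tokens of any class. The window
  may cross sentence boundaries within a passage but never passage
  boundaries. We let it cross sentences because the stimuli this tooling
  targets are short multi-sentence passages; confining the fixed window to
  the sentence would silently discard most early-sentence tokens.
* `FIXED_K_CONTENT_SENT` (`cosine_content`): up to `k` most recent preceding
  content words in the current sentence.
* `ALL_PRECEDING_SENT` (`euclidean_sentence`): every preceding in-sentence
  token; its window size therefore varies with target position.

Two boundary rules matter for comparability:

* **Out-of-vocabulary context words are skipped, with the lookback extended
  further left** (never zero-filled: a zero vector has no defined Pearson
  correlation and biases sums and means).
* **`FIXED_K_ALL` is all-or-nothing**: unless a full set of `k` in-vocabulary
  predecessors exists, the window is undefined and the measure is missing.
  This keeps the dynamic measure's range fixed — always six correlation
  pairs at `k = 3` — so values are comparable across tokens. Whether a
  shrinking window would be preferable at passage starts is genuinely open;
  the fixed-size rule is this package's choice and is configurable only
  through `k`.

A target that is itself out of vocabulary, or sentence-initial under the
sentence policies, gets a missing value. Missing is always `NA`, never `0`:
zero is a meaningful similarity value.

## Degenerate inputs and numerical choices

* A constant (zero-variance) vector makes Pearson undefined; any such vector
  in a window makes the whole correlation matrix, and hence both dynamic
  values, missing (with a warning).
* A context whose vectors sum to zero makes the cosine measures missing.
* $1/d_2$ is unbounded; when the target coincides with the context mean
  (distance below $10^{-12}$) the value saturates at $10^{12}$ and carries a
  `saturated` flag, so downstream code can trim it.
* No length-normalization is applied to vectors before any measure. Pearson
  and cosine are scale-invariant anyway; the Euclidean measures are not, and
  normalizing would silently change their baselines.
* Correlation matrices are symmetrized and given an exact unit diagonal
  after `stats::cor`, and matrix labels are ordered context-first,
  target-last.

Token matching against the embedding vocabulary uses Unicode NFC,
lower-casing and edge-punctuation stripping (`normalize_words()`). Lowercase
matching maximizes hit rates on word2vec-style vocabularies; how the
original stimulus-to-vocabulary matching was done in published analyses is
typically unstated, so this is a documented default, overridable in
`read_vec()`. Word classification uses a packaged closed-class list
(determiners, prepositions, conjunctions, pronouns, auxiliaries/modals,
wh-words, negation), overridable per call — "content word" has no single
agreed definition, so the list is data, not doctrine. In `read_vec()`,
individual lines whose float count mismatches the header dimension are
skipped and counted rather than fatal, because distributed `.vec` files
contain multi-word-key artifacts.

## What the synthetic generators emulate

The package is testable without any external download because it generates
its own data with the statistical structure the analysis assumes:

* `make_embeddings()` draws word vectors from a latent-factor model
  $v_w = \Lambda l_w + s\,\varepsilon_w$, so the expected pairwise Pearson
  correlation between two words is the dot product of their loadings
  attenuated by the noise share — targeted correlation structure by
  construction. Defaults (300 dimensions, 5 factors, unit loadings, noise
  scale 1) give mildly correlated vocabularies similar in correlation range
  to pretrained embeddings.
* `make_passages()` emulates short reading stimuli: 55 passages averaging
  50 words and 2.5 sentences, with a 40% function-word rate by default, and
  records its own ground-truth word classes.
* `fig3_fixture()` reconstructs the six-word worked example exactly: vectors
  are built from a mean-zero orthonormal basis times the Cholesky factor of
  the target correlation matrix, so the sample correlations of
  "the/smart/watch/space" equal the printed values to machine precision
  (the two remaining words correlate at 0.10 with everything, a value chosen
  only to keep the matrix positive definite). These vectors are synthetic:
  they reproduce the example's correlation geometry, not any real
  embedding's.
* `simulate_fixations()` generates per-(token, participant) first and total
  fixation durations from a linear-additive model with word length and
  log-frequency covariates, a participant random intercept, residual noise,
  and a similarity coefficient `beta_sim` in ms per similarity unit.
  Durations are truncated at 1 ms. Defaults (intercept 214 ms, +36 ms mean
  refixation, participant SD 30 ms, residual SD 80 ms, +4 ms/char,
  −6 ms/log-unit, −10 ms/similarity-unit) sit at the scale typical of
  first/total fixation durations; the negative similarity coefficient
  emulates the empirical direction of the effect. Published analyses do not
  report the effect in ms per similarity unit, so the size is
  self-calibrated, chosen once for the simulations.

The generators emulate the *structure* the recovery analysis needs — not
real reading. They produce no skips, regressions, refixation dynamics,
word-order statistics, or nonlinear covariate surfaces, and passages are
bags of vocabulary draws. Passing recovery tests therefore show that the
measure-to-export-to-estimator chain is correct and sensitive at realistic
noise levels; they say nothing about how well any measure predicts real
eye movements.

## Effect recovery

`recover_similarity_effect()` is a deliberately lightweight estimator:
ordinary least squares on participant-mean-centered durations with length
and log-frequency covariates. In a balanced design the centering removes the
participant intercept exactly, so the similarity slope estimates the
generating `beta_sim` directly. Full analyses of real data use generalized
additive mixed models (smooth terms, tensor interactions, random effects);
those are ecosystem-bound and out of this package's scope — the exported CSV
schema (`write_scores_csv()`, `join_eyetracking()`) is designed so external
smooth-model software can consume the tables verbatim.

Simulation sizes used by the package's own checks, chosen to give stable
estimates with quick runs: recovery at ~5000 scored tokens × 20
participants (slope within ±20% of −10 ms/unit), a null calibration
(`beta_sim = 0`, slope within 2 SE of zero), and sign recovery over 100
replicates at ~500 tokens × 8 participants.

## Worked example

```{r pipeline}
fx <- fig3_fixture()
fq <- make_freq_table(rownames(fx$table$vectors), seed = 1)
scores <- compute_token_table(
  fx$tokens, fx$table,
  measures = c("dynamic_full", "dynamic_simpler"),
  k = 3, freq_table = fq)
scores[, c("norm", "word_class", "dynamic_full", "dynamic_simpler")]
```

The first three tokens have too few predecessors for a full three-word
window under `FIXED_K_ALL` and stay missing; "space" gets exactly the
triangle sums shown above.

## Known limitations

* English-centred tokenization and function-word list; no POS tagging.
* No subword fallback for out-of-vocabulary words (vectors are looked up,
  never synthesized), and no contextual (transformer) embeddings.
* The estimator is linear; nonlinear similarity effects in real data need
  external smooth-model software on the exported tables.
* `k` defaults to 3 everywhere, matching the fixed-window convention the
  measures were defined with; other window sizes are supported but the
  bounds in the documentation scale accordingly.
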