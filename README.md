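# contextsim

Per-token **contextual semantic similarity** from word embeddings, for
reading-time research. During natural reading, words that fit their
preceding context are fixated more briefly; `contextsim` computes the
token-level similarity predictors that quantify this fit, so they can be
joined with eye-tracking records (first and total fixation durations) and
exported to mixed-model software.

## The measures

For a target word $w^t$ with embedding vector $v_t$ and its $k = 3$
preceding words, stack the four vectors and form the $4 \times 4$ matrix
$R$ of Pearson correlations between word vectors (computed across embedding
dimensions). The package's central measure is the **dynamic similarity**

$$\mathrm{dyn}(w^t) = \sum_{i > j} r_{ij},$$

the sum of the six strict-lower-triangle correlations — every unordered
word pair in the window, target–context and context–context alike — and its
**simpler** variant, the sum of the target's own row,
$\sum_{j} r_{tj}$. Both are interpretable cell by cell: each term is the
relatedness of one word pair. Four established comparison measures are
implemented alongside: cosine of the target with the *summed* context
vectors (content words only, or all words), and inverse Euclidean distance
of the target to the *averaged* context vectors (whole sentence, or fixed
three-word window). Each measure is bound to its own context-window policy;
see `measure_policy()` and the vignette.

## Worked example

`fig3_fixture()` packages the six-word example "We invade the smart watch
space" with a synthetic embedding table whose sample correlations reproduce
the worked correlation matrix exactly:

```r
library(contextsim)
fx <- fig3_fixture()
fx$corr
#>        the smart watch space
#> the   1.00  0.17  0.18  0.42
#> smart 0.17  1.00  0.65  0.31
#> watch 0.18  0.65  1.00  0.25
#> space 0.42  0.31  0.25  1.00
dynamic_similarity(fx$corr)          # 0.17+0.18+0.65+0.42+0.31+0.25
#> [1] 1.98
simpler_dynamic_similarity(fx$corr)  # 0.42+0.31+0.25
#> [1] 0.98
```

The same numbers fall out of the full pipeline — tokenized text, window
extraction, correlation matrix, triangle sum:

```r
fq <- make_freq_table(rownames(fx$table$vectors), seed = 1)
scores <- compute_token_table(fx$tokens, fx$table,
                              measures = c("dynamic_full", "dynamic_simpler"),
                              k = 3, freq_table = fq)
scores[, c("norm", "word_class", "dynamic_full", "dynamic_simpler")]
#>     norm word_class dynamic_full dynamic_simpler
#> 1     we   function           NA              NA
#> 2 invade    content           NA              NA
#> 3    the   function           NA              NA
#> 4  smart    content         0.67            0.37
#> 5  watch    content         1.30            0.93
#> 6  space    content         1.98            0.98
```

The first three tokens lack a full three-word window and are missing (`NA`,
never 0); "space" scores 1.98 on the dynamic measure — the sum of the six
pairwise correlations among it and "the", "smart", "watch" — and 0.98 on
the simpler variant.

Real embedding tables load from the word2vec/fastText `.vec` text format
with `read_vec()`; passages load from plain text (`tokenize_text()`) or a
pre-tokenized CSV. A thin command-line front end ships in
`exec/contextsim` (`compute`, `simulate`, `export`, `recover`).

## Synthetic data and effect recovery

Everything is testable offline: `make_embeddings()` generates embedding
tables with controlled expected pairwise correlations (latent-factor
construction), `make_passages()` generates 50-word, 2.5-sentence passages
with a configurable function-word rate, and `simulate_fixations()`
generates per-participant fixation durations with word-length,
log-frequency and similarity effects plus a participant random intercept.
`recover_similarity_effect()` then estimates the similarity slope (ms per
similarity unit) by least squares on participant-mean-centered durations —
a linear stand-in for the additive mixed models used on real data, adequate
for sign and magnitude checks.

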