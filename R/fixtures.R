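#' Generate a synthetic embedding table with controlled correlation structure
#'
#' Word vectors follow a latent-factor model: the vector for word *w* is
#' `Lambda %*% loadings_w + noise_scale * eps_w`, where `Lambda` is a d x f
#' matrix of iid standard normals shared by all words and `eps_w` is
#' word-specific iid noise. Across embedding dimensions, the expected
#' Pearson correlation between two words is then
#' `dot(l_w, l_u) / sqrt((|l_w|^2 + s^2) (|l_u|^2 + s^2))`
#' (`s` = `noise_scale`): unit loadings with zero noise give a pairwise
#' correlation equal to the loading dot product, which makes targeted
#' correlation structure easy to build. A synthetic stand-in for pretrained
#' vectors, intended for tests and simulation, not for modelling language.
#'
#' @param n_words vocabulary size (ignored if `vocabulary` is given).
#' @param dimension embedding dimension d (>= 2; Pearson needs at least two
#'   dimensions).
#' @param n_factors number of latent factors f.
#' @param loadings optional `n_words x n_factors` matrix of per-word factor
#'   loadings; default: iid normal rows scaled to unit norm.
#' @param noise_scale idiosyncratic noise scale `s` (>= 0).
#' @param vocabulary optional character vector of word forms; default
#'   `"w0001"`, ... Supply real word forms (e.g. function words) when the
#'   table must back a tokenized passage.
#' @param seed integer seed; the generator is reproducible for a fixed seed.
#' @return an [embedding_table()].
#' @export
make_embeddings <- function(n_words = 200L, dimension = 300L, n_factors = 5L,
                            loadings = NULL, noise_scale = 1,
                            vocabulary = NULL, seed = 1L) {
  if (dimension < 2L) stop("dimension must be >= 2 (Pearson undefined at d=1)")
  stopifnot(noise_scale >= 0, n_factors >= 1L)
  if (is.null(vocabulary)) {
    vocabulary <- sprintf("w%04d", seq_len(n_words))
  }
  n_words <- length(vocabulary)
  if (anyDuplicated(vocabulary)) stop("vocabulary must be unique")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(loadings)) {
    loadings <- matrix(stats::rnorm(n_words * n_factors), n_words, n_factors)
    loadings <- loadings / sqrt(rowSums(loadings^2))
  }
  stopifnot(nrow(loadings) == n_words, ncol(loadings) == n_factors)
  Lambda <- matrix(stats::rnorm(dimension * n_factors), dimension, n_factors)
  eps <- matrix(stats::rnorm(dimension * n_words), dimension, n_words)
  vec <- t(Lambda %*% t(loadings) + noise_scale * eps)
  rownames(vec) <- vocabulary
  # latent normals are almost surely non-constant; guard regardless
  if (any(apply(vec, 1L, stats::sd) == 0)) stop("constant vector generated")
  embedding_table(vec, meta = list(synthetic = TRUE, seed = seed,
                                   n_factors = n_factors,
                                   noise_scale = noise_scale))
}

# Build m word vectors (d dims) whose sample Pearson correlation matrix is
# exactly R: mean-zero orthonormal columns times chol(R).
exact_corr_vectors <- function(R, dimension = 300L, seed = 42L) {
  m <- nrow(R)
  stopifnot(dimension > m + 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Z <- matrix(stats::rnorm(dimension * m), dimension, m)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- qr.Q(qr(Z))          # columns stay mean-zero under orthonormalization
  X <- Z %*% chol(R)
  t(X)                      # one row per word
}

#' The worked six-word example: passage, correlation matrix and embeddings
#'
#' Returns the single-sentence passage "We invade the smart watch space"
#' together with the 4 x 4 correlation matrix of the target word "space"
#' and its three preceding words ("the", "smart", "watch"): target row
#' 0.42, 0.31, 0.25 and context-context correlations 0.17, 0.18, 0.65, so
#' the full lower-triangle sum is 1.98 and the target-row sum is 0.98.
#' Also included is a synthetic six-word embedding table (300 dimensions)
#' constructed so that the sample correlations among "the", "smart",
#' "watch", "space" reproduce that matrix exactly (correlations involving
#' "we"/"invade" are fixed at 0.10), letting the whole pipeline — window
#' extraction, correlation matrix, measure — be exercised end to end
#' against known values.
#'
#' @return list with `tokens` (token table), `corr` (the 4 x 4 matrix,
#'   labels context-then-target) and `table` (an [embedding_table()]).
#' @export
#' @examples
#' fx <- fig3_fixture()
#' dynamic_similarity(fx$corr)
fig3_fixture <- function() {
  words4 <- c("the", "smart", "watch", "space")
  R4 <- matrix(c(
    1.00, 0.17, 0.18, 0.42,
    0.17, 1.00, 0.65, 0.31,
    0.18, 0.65, 1.00, 0.25,
    0.42, 0.31, 0.25, 1.00
  ), 4L, 4L, dimnames = list(words4, words4))

  words6 <- c("we", "invade", "the", "smart", "watch", "space")
  R6 <- matrix(0.10, 6L, 6L, dimnames = list(words6, words6))
  diag(R6) <- 1
  R6[words4, words4] <- R4
  vec <- exact_corr_vectors(R6, dimension = 300L, seed = 42L)
  rownames(vec) <- words6
  tokens <- tokenize_text("We invade the smart watch space.",
                          passage_ids = "fig3")
  list(tokens = tokens, corr = R4,
       table = embedding_table(vec, meta = list(synthetic = TRUE)))
}

#' Generate synthetic multi-sentence passages from an embedding vocabulary
#'
#' Emulates short naturalistic reading stimuli: passages of about 50 words
#' and 2.5 sentences by default. Tokens are drawn from the table's
#' vocabulary with a controllable function-word rate; function tokens are
#' sampled from the intersection of the vocabulary with
#' [function_word_list()] (supply such words via `vocabulary=` in
#' [make_embeddings()]), content tokens from the rest. The generator
#' records its own ground truth (`sim_class`) so downstream classification
#' and filtering can be tested against known counts.
#'
#' @param table an [embedding_table()] providing the vocabulary.
#' @param n_passages number of passages.
#' @param mean_words mean words per passage (Poisson, floor 4).
#' @param mean_sentences mean sentences per passage (>= 1; 1 + Poisson).
#' @param function_word_rate probability that a token is a function word, in
#'   `[0, 1)`; requires function words in the vocabulary when > 0.
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @return token table as from [tokenize_text()] plus a `sim_class` column
#'   with the generator's ground-truth word class.
#' @export
make_passages <- function(table, n_passages = 55L, mean_words = 50,
                          mean_sentences = 2.5, function_word_rate = 0.4,
                          seed = 1L) {
  stopifnot(inherits(table, "embedding_table"),
            function_word_rate >= 0, function_word_rate < 1,
            mean_words >= 1, mean_sentences >= 1)
  vocab <- rownames(table$vectors)
  if (length(vocab) < 2L) stop("vocabulary must contain at least 2 words")
  fw <- intersect(vocab, function_word_list())
  cw <- setdiff(vocab, fw)
  if (function_word_rate > 0 && !length(fw))
    stop("function_word_rate > 0 but the vocabulary has no function words")
  if (!length(cw)) stop("vocabulary has no content words")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  out <- vector("list", n_passages)
  for (p in seq_len(n_passages)) {
    n_w <- max(4L, stats::rpois(1L, mean_words))
    n_s <- min(1L + stats::rpois(1L, mean_sentences - 1), n_w)
    is_fun <- stats::runif(n_w) < function_word_rate
    words <- character(n_w)
    if (any(is_fun)) words[is_fun] <- sample(fw, sum(is_fun), replace = TRUE)
    words[!is_fun] <- sample(cw, sum(!is_fun), replace = TRUE)
    # spread sentence breaks evenly over the token sequence
    sent <- sort(rep_len(seq_len(n_s) - 1L, n_w))
    out[[p]] <- data.frame(
      passage_id = sprintf("p%03d", p),
      sentence_index = sent,
      token_index = seq_len(n_w) - 1L,
      surface = words,
      norm = words,
      word_class = classify_words(words),
      sim_class = ifelse(is_fun, "function", "content"),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Render generated passages back to plain text
#'
#' Joins tokens with spaces and terminates each sentence with a period, so
#' that [tokenize_text()] on the result reproduces the generated token and
#' sentence structure.
#'
#' @param tokens token table from [make_passages()] (or any token table).
#' @return character vector, one passage per element.
#' @export
passages_to_text <- function(tokens) {
  vapply(split(tokens, tokens$passage_id), function(p) {
    p <- p[order(p$token_index), ]
    sents <- vapply(split(p$surface, p$sentence_index),
                    function(s) paste0(paste(s, collapse = " "), "."),
                    character(1))
    paste(sents, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a Zipf-like word frequency table
#'
#' Counts fall off as `rank^-exponent` over a random permutation of the
#' vocabulary, scaled so the most frequent word has `top_count` occurrences
#' (minimum count 1). Used as the log-frequency covariate source for
#' synthetic corpora.
#'
#' @param words character vector of word forms.
#' @param exponent Zipf exponent (default 1.05).
#' @param top_count count of the most frequent word (default 1e6).
#' @param seed integer seed for the rank permutation.
#' @return `data.frame` with columns `word`, `count`.
#' @export
make_freq_table <- function(words, exponent = 1.05, top_count = 1e6,
                            seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ranks <- sample(length(words))
  data.frame(word = words,
             count = pmax(1, round(top_count * ranks^(-exponent))),
             stringsAsFactors = FALSE)
}

#' Simulate per-token fixation durations with a similarity effect
#'
#' Generates first and total fixation durations (ms) for every
#' (scored token, participant) pair under a linear-additive model:
#'
#' `first = beta0 + beta_len * length + beta_freq * log_freq +
#'   beta_sim * similarity + u_participant + eps`
#'
#' with `u_participant ~ N(0, sigma_u^2)`, `eps ~ N(0, sigma_e^2)`, and
#' `total = first + refix`, `refix ~ N(refix_mean, sigma_e^2)` truncated at
#' 0. Durations are truncated below at 1 ms. Tokens whose similarity value
#' is missing are skipped. A negative `beta_sim` emulates the empirical
#' direction of the similarity effect on reading times: higher contextual
#' similarity, shorter fixations. Defaults put intercepts near 214 ms
#' (first) and 250 ms (total), typical first-/total-fixation scales.
#'
#' @param scores a token score table from [compute_token_table()] (needs
#'   `passage_id`, `token_index`, `length`, `log_freq` and the measure
#'   column).
#' @param measure name of the similarity column to use as the predictor.
#' @param n_participants number of simulated participants (>= 1).
#' @param beta0 intercept, ms.
#' @param beta_len word-length effect, ms per character.
#' @param beta_freq log-frequency effect, ms per log-count unit.
#' @param beta_sim similarity effect, ms per similarity unit.
#' @param sigma_u participant random-intercept SD, ms.
#' @param sigma_e residual SD, ms.
#' @param refix_mean mean refixation time added to total duration, ms.
#' @param seed integer seed.
#' @return list with `fixations` (`data.frame`: `passage_id`, `token_index`,
#'   `participant`, `first_fixation_ms`, `total_fixation_ms`) and
#'   `participant_effects` (realized random intercepts, for introspection).
#' @export
simulate_fixations <- function(scores, measure, n_participants = 20L,
                               beta0 = 214, beta_len = 4, beta_freq = -6,
                               beta_sim = -10, sigma_u = 30, sigma_e = 80,
                               refix_mean = 36, seed = 1L) {
  stopifnot(measure %in% names(scores), sigma_u >= 0, sigma_e >= 0)
  if (n_participants < 1L) stop("n_participants must be >= 1")
  ok <- !is.na(scores[[measure]])
  sc <- scores[ok, , drop = FALSE]
  if (!nrow(sc)) stop("no tokens with non-missing similarity values")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  u <- stats::rnorm(n_participants, 0, sigma_u)
  n_tok <- nrow(sc)
  mu <- beta0 + beta_len * sc$length + beta_freq * sc$log_freq +
    beta_sim * sc[[measure]]
  idx_tok <- rep(seq_len(n_tok), times = n_participants)
  idx_par <- rep(seq_len(n_participants), each = n_tok)
  eps <- stats::rnorm(n_tok * n_participants, 0, sigma_e)
  first <- pmax(1, mu[idx_tok] + u[idx_par] + eps)
  refix <- pmax(0, stats::rnorm(n_tok * n_participants, refix_mean, sigma_e))
  total <- pmax(1, first + refix)
  list(
    fixations = data.frame(
      passage_id = sc$passage_id[idx_tok],
      token_index = sc$token_index[idx_tok],
      participant = sprintf("s%03d", idx_par),
      first_fixation_ms = first,
      total_fixation_ms = total,
      stringsAsFactors = FALSE
    ),
    participant_effects = data.frame(
      participant = sprintf("s%03d", seq_len(n_participants)),
      u = u, stringsAsFactors = FALSE
    )
  )
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
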