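#' The six contextual similarity measures and their window policies
#'
#' Each measure identifier is bound to exactly one window policy:
#'
#' | measure id           | context policy         | definition |
#' |----------------------|------------------------|------------|
#' | `dynamic_full`       | `FIXED_K_ALL`          | sum of all strictly-lower-triangle Pearson correlations among the k context vectors and the target vector |
#' | `dynamic_simpler`    | `FIXED_K_ALL`          | sum of the target's correlations with each of the k context vectors |
#' | `cosine_content`     | `FIXED_K_CONTENT_SENT` | cosine of the target vector with the sum of the preceding content-word vectors |
#' | `cosine_all`         | `FIXED_K_ALL`          | cosine of the target vector with the sum of the k preceding vectors, any word class |
#' | `euclidean_sentence` | `ALL_PRECEDING_SENT`   | 1 / Euclidean distance from the target vector to the mean of all preceding in-sentence vectors |
#' | `euclidean_fixed`    | `FIXED_K_ALL`          | 1 / Euclidean distance from the target vector to the mean of the k preceding vectors |
#'
#' @return character vector of the six measure identifiers.
#' @export
measure_ids <- function() {
  c("dynamic_full", "dynamic_simpler", "cosine_content", "cosine_all",
    "euclidean_sentence", "euclidean_fixed")
}

#' @rdname measure_ids
#' @param measure a measure identifier.
#' @return `measure_policy()`: the window policy bound to `measure`.
#' @export
measure_policy <- function(measure) {
  switch(match.arg(measure, measure_ids()),
    dynamic_full = "FIXED_K_ALL",
    dynamic_simpler = "FIXED_K_ALL",
    cosine_content = "FIXED_K_CONTENT_SENT",
    cosine_all = "FIXED_K_ALL",
    euclidean_sentence = "ALL_PRECEDING_SENT",
    euclidean_fixed = "FIXED_K_ALL"
  )
}

# saturation value reported when the target coincides with the context mean
EUCLIDEAN_SATURATION <- 1e12

#' Pearson correlation between two word vectors
#'
#' Computed across embedding dimensions. A constant (zero-variance) vector
#' has no defined correlation; that degenerate case yields `NA` with a
#' warning rather than an error or a numeric sentinel, so it can propagate
#' to a missing similarity value.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
pearson_cor <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2L)
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    warning("zero-variance vector: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(u, v)
}

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length. A zero-norm vector yields
#'   `NA` with a warning (degenerate, not an error).
#' @return cosine in `[-1, 1]`, or `NA` for degenerate input.
#' @export
cosine_sim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-norm vector: cosine undefined")
    return(NA_real_)
  }
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Pairwise correlation matrix over a context window
#'
#' Builds the (k+1) x (k+1) matrix of Pearson correlations among the word
#' vectors of a window, labelled context-first-then-target (the layout in
#' which the dynamic measures are defined). Any constant vector in the
#' window makes the whole matrix undefined (`NULL`), which the measure
#' dispatch reports as a missing similarity value.
#'
#' @param window a `context_window` from [extract_window()].
#' @param table an [embedding_table()].
#' @return symmetric numeric matrix with unit diagonal and dimnames =
#'   window word forms, or `NULL` if any vector is degenerate.
#' @export
correlation_matrix <- function(window, table) {
  if (is.null(window)) return(NULL)
  words <- c(window$context$norm, window$target$norm)
  vecs <- t(lookup_vectors(table, words))   # d x (k+1), columns = words
  corr_matrix_from_vecs(vecs, words)
}

# vecs: d x m matrix, one column per word
corr_matrix_from_vecs <- function(vecs, labels) {
  if (anyNA(vecs)) return(NULL)
  sds <- apply(vecs, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant word vector in window: correlation matrix undefined")
    return(NULL)
  }
  m <- stats::cor(vecs)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

#' Dynamic contextual semantic similarity
#'
#' `dynamic_similarity()` sums every entry of the strict lower triangle of
#' the window's correlation matrix — one Pearson correlation per unordered
#' word pair, so for a window of k context words plus the target there are
#' k(k+1)/2 terms and the value lies in `[-k(k+1)/2, k(k+1)/2]`.
#' `simpler_dynamic_similarity()` keeps only the target's own row: the sum
#' of its correlations with each context word, in `[-k, k]`.
#'
#' @param m correlation matrix from [correlation_matrix()] (context words
#'   first, target last).
#' @return numeric similarity value, or `NA` if `m` is `NULL`.
#' @export
#' @examples
#' fx <- fig3_fixture()
#' dynamic_similarity(fx$corr)          # 1.98
#' simpler_dynamic_similarity(fx$corr)  # 0.98
dynamic_similarity <- function(m) {
  if (is.null(m)) return(NA_real_)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  sum(m[lower.tri(m, diag = FALSE)])
}

#' @rdname dynamic_similarity
#' @export
simpler_dynamic_similarity <- function(m) {
  if (is.null(m)) return(NA_real_)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2L)
  p <- nrow(m)
  sum(m[p, seq_len(p - 1L)])
}

#' Cosine similarity of a target to its summed context vectors
#'
#' The context vectors are summed into a single composite vector and the
#' cosine with the target vector is returned. With the content-only window
#' this is the classic content-word cosine baseline; with the fixed-k
#' any-class window it is the modified variant that also counts function
#' words.
#'
#' @param window a `context_window` (or `NULL`, giving `NA`).
#' @param table an [embedding_table()].
#' @return cosine in `[-1, 1]`; `NA` when the window is undefined or the
#'   summed context vector has zero norm.
#' @export
cosine_measure <- function(window, table) {
  if (is.null(window)) return(NA_real_)
  ctx <- lookup_vectors(table, window$context$norm)
  tgt <- drop(lookup_vectors(table, window$target$norm))
  if (anyNA(ctx) || anyNA(tgt)) return(NA_real_)
  cosine_sim(colSums(ctx), tgt)
}

#' Inverse-distance similarity of a target to its averaged context vectors
#'
#' Returns `1 / d`, where `d` is the Euclidean distance between the target
#' vector and the mean of the context vectors. With the whole-sentence
#' window this is the inverse-Euclidean baseline; with the fixed-k window it
#' is the simpler variant with a constant context size. `1/d` is unbounded,
#' so when the target coincides with the context mean (distance below
#' 1e-12) the value saturates at `1e12` and the result carries a
#' `saturated` attribute.
#'
#' @param window a `context_window` (or `NULL`, giving `NA`).
#' @param table an [embedding_table()].
#' @return positive similarity value (`NA` when the window is undefined),
#'   with attribute `saturated = TRUE` when the cap was applied.
#' @export
euclidean_measure <- function(window, table) {
  if (is.null(window)) return(NA_real_)
  ctx <- lookup_vectors(table, window$context$norm)
  tgt <- drop(lookup_vectors(table, window$target$norm))
  if (anyNA(ctx) || anyNA(tgt)) return(NA_real_)
  d <- sqrt(sum((tgt - colMeans(ctx))^2))
  if (d < 1e-12) {
    return(structure(EUCLIDEAN_SATURATION, saturated = TRUE))
  }
  1 / d
}

#' Compute one similarity measure for one target token
#'
#' Extracts the measure's policy-bound context window and applies the
#' measure. Undefined windows (no preceding words, incomplete fixed-k
#' context, out-of-vocabulary target) and degenerate vector configurations
#' yield a missing value, never an error.
#'
#' @param tokens single-passage token table.
#' @param target_index 0-based token index of the target.
#' @param measure one of [measure_ids()].
#' @param k context size for fixed-k policies (default 3).
#' @param table an [embedding_table()].
#' @return list with `measure`, `value` (`NA` = missing), `n_context`
#'   (context words used, 0 when missing) and `saturated` (logical).
#' @export
compute_measure <- function(tokens, target_index, measure, k = 3L, table) {
  measure <- match.arg(measure, measure_ids())
  win <- extract_window(tokens, target_index, measure_policy(measure),
                        k = k, table = table)
  val <- apply_measure(win, measure, table)
  list(measure = measure,
       value = as.numeric(val),
       n_context = if (is.null(win)) 0L else nrow(win$context),
       saturated = isTRUE(attr(val, "saturated")))
}

apply_measure <- function(window, measure, table) {
  switch(measure,
    dynamic_full = dynamic_similarity(correlation_matrix(window, table)),
    dynamic_simpler = simpler_dynamic_similarity_or_na(window, table),
    cosine_content = cosine_measure(window, table),
    cosine_all = cosine_measure(window, table),
    euclidean_sentence = euclidean_measure(window, table),
    euclidean_fixed = euclidean_measure(window, table)
  )
}

simpler_dynamic_similarity_or_na <- function(window, table) {
  m <- correlation_matrix(window, table)
  if (is.null(m)) return(NA_real_)
  simpler_dynamic_similarity(m)
}
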