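# Independent brute-force reference for the six similarity measures.
# Deliberately shares no code with the package: its own two-pass Pearson,
# its own window scans, its own cosine / distance arithmetic. Used to
# check the package elementwise on synthetic corpora.

oracle_pearson <- function(u, v) {
  mu <- sum(u) / length(u)
  mv <- sum(v) / length(v)
  du <- u - mu
  dv <- v - mv
  den <- sqrt(sum(du^2)) * sqrt(sum(dv^2))
  if (den == 0) return(NA_real_)
  sum(du * dv) / den
}

oracle_cosine <- function(u, v) {
  den <- sqrt(sum(u^2)) * sqrt(sum(v^2))
  if (den == 0) return(NA_real_)
  sum(u * v) / den
}

# tokens: one passage, ordered; vec_of: function(word) -> vector or NULL
oracle_context <- function(tokens, i, policy, k, vec_of) {
  if (is.null(vec_of(tokens$norm[[i]]))) return(NULL)
  before <- if (i > 1L) seq_len(i - 1L) else integer(0)
  iv <- vapply(before, function(j) !is.null(vec_of(tokens$norm[[j]])),
               logical(1))
  if (policy == "FIXED_K_ALL") {
    cand <- before[iv]
    if (length(cand) < k) return(NULL)
    cand[(length(cand) - k + 1L):length(cand)]
  } else if (policy == "FIXED_K_CONTENT_SENT") {
    cand <- before[iv &
                     tokens$sentence_index[before] == tokens$sentence_index[[i]] &
                     tokens$word_class[before] == "content"]
    if (!length(cand)) return(NULL)
    cand[max(1L, length(cand) - k + 1L):length(cand)]
  } else {
    cand <- before[iv &
                     tokens$sentence_index[before] == tokens$sentence_index[[i]]]
    if (!length(cand)) return(NULL)
    cand
  }
}

# returns a data.frame of six measure columns, one row per token
oracle_all_measures <- function(tokens, table, k = 3L) {
  vec_of <- function(w) {
    ix <- match(w, rownames(table$vectors))
    if (is.na(ix)) NULL else table$vectors[ix, ]
  }
  specs <- list(
    dynamic_full = "FIXED_K_ALL", dynamic_simpler = "FIXED_K_ALL",
    cosine_content = "FIXED_K_CONTENT_SENT", cosine_all = "FIXED_K_ALL",
    euclidean_sentence = "ALL_PRECEDING_SENT", euclidean_fixed = "FIXED_K_ALL"
  )
  out <- matrix(NA_real_, nrow(tokens), length(specs),
                dimnames = list(NULL, names(specs)))
  for (pid in unique(tokens$passage_id)) {
    pt <- tokens[tokens$passage_id == pid, , drop = FALSE]
    pt <- pt[order(pt$token_index), , drop = FALSE]
    rows <- which(tokens$passage_id == pid)[order(
      tokens$token_index[tokens$passage_id == pid])]
    for (i in seq_len(nrow(pt))) {
      for (m in names(specs)) {
        ctx <- oracle_context(pt, i, specs[[m]], k, vec_of)
        if (is.null(ctx)) next
        cvecs <- lapply(pt$norm[ctx], vec_of)
        tvec <- vec_of(pt$norm[[i]])
        val <- if (m %in% c("dynamic_full", "dynamic_simpler")) {
          all_v <- c(cvecs, list(tvec))
          n <- length(all_v)
          pairs <- 0
          bad <- FALSE
          trow <- 0
          for (a in seq_len(n)) for (b in seq_len(n)) if (a > b) {
            r <- oracle_pearson(all_v[[a]], all_v[[b]])
            if (is.na(r)) bad <- TRUE
            pairs <- pairs + r
            if (a == n) trow <- trow + r
          }
          if (bad) NA_real_ else if (m == "dynamic_full") pairs else trow
        } else if (m %in% c("cosine_content", "cosine_all")) {
          oracle_cosine(Reduce(`+`, cvecs), tvec)
        } else {
          mean_v <- Reduce(`+`, cvecs) / length(cvecs)
          dd <- sqrt(sum((tvec - mean_v)^2))
          if (dd < 1e-12) 1e12 else 1 / dd
        }
        out[rows[[i]], m] <- val
      }
    }
  }
  as.data.frame(out)
}

# small vocabulary mixing function and content words, shared across tests
toy_table <- function(seed = 7L, n_content = 120L, dimension = 60L,
                      noise_scale = 1) {
  fw <- c("the", "a", "of", "in", "and", "we", "is", "to", "that", "it",
          "with", "for", "on", "was", "his", "her", "they", "be", "at",
          "by")
  make_embeddings(vocabulary = c(fw, sprintf("w%04d", seq_len(n_content))),
                  dimension = dimension, n_factors = 4L,
                  noise_scale = noise_scale, seed = seed)
}
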