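#' Score every token of a corpus on a set of similarity measures
#'
#' Produces the tidy per-token table that downstream mixed-model software
#' consumes: one row per (passage, token) with the word form, word length in
#' characters, natural-log frequency, word class and one column per
#' requested measure. Missing similarity values (undefined windows,
#' degenerate vectors, out-of-vocabulary targets) stay `NA` — they are never
#' encoded as 0 or a sentinel. The `dataset` filter mirrors the common
#' design of analysing content-word targets only (`dataset = 1`) versus all
#' tokens (`dataset = 2`).
#'
#' @param tokens token table (any number of passages).
#' @param table an [embedding_table()].
#' @param measures character vector of [measure_ids()] (default: all six).
#' @param k context size for fixed-k policies (default 3).
#' @param freq_table `data.frame` with columns `word`, `count`; words absent
#'   from it receive the table's minimum count and are flagged in
#'   `freq_imputed`. A warning is issued when coverage falls below 90%.
#' @param dataset `1` = content-word targets only, `2` = all targets.
#' @return `data.frame`: `passage_id`, `token_index`, `norm`, `length`,
#'   `log_freq`, `freq_imputed`, `word_class`, plus one numeric column per
#'   measure.
#' @export
compute_token_table <- function(tokens, table, measures = measure_ids(),
                                k = 3L, freq_table = NULL, dataset = 2L) {
  if (is.null(tokens) || !nrow(tokens)) stop("empty passage list")
  measures <- vapply(measures, function(m) match.arg(m, measure_ids()),
                     character(1), USE.NAMES = FALSE)
  stopifnot(dataset %in% c(1L, 2L))
  tokens <- set_in_vocab(tokens, table)
  tokens <- tokens[order(tokens$passage_id, tokens$token_index), ,
                   drop = FALSE]

  policies <- vapply(measures, measure_policy, character(1))
  res <- matrix(NA_real_, nrow(tokens), length(measures),
                dimnames = list(NULL, measures))
  vroot <- table$vectors
  row_id <- match(tokens$norm, rownames(vroot))

  for (p in split(seq_len(nrow(tokens)), tokens$passage_id)) {
    sent <- tokens$sentence_index[p]
    iv <- tokens$in_vocab[p]
    wc <- tokens$word_class[p]
    rid <- row_id[p]
    for (i in seq_along(p)) {
      if (!iv[[i]]) next
      win_cache <- list()
      cm_cache <- NULL
      for (j in seq_along(measures)) {
        pol <- policies[[j]]
        if (is.null(win_cache[[pol]])) {
          idx <- window_indices(sent, iv, wc, i, pol, k)
          win_cache[[pol]] <- if (is.null(idx)) NA else idx
        }
        idx <- win_cache[[pol]]
        if (length(idx) == 1L && is.na(idx[[1L]])) next
        m <- measures[[j]]
        if (m %in% c("dynamic_full", "dynamic_simpler")) {
          if (is.null(cm_cache)) {
            vecs <- t(vroot[c(rid[idx], rid[[i]]), , drop = FALSE])
            cm <- suppressWarnings(
              corr_matrix_from_vecs(vecs, c(tokens$norm[p][idx],
                                            tokens$norm[p][[i]])))
            cm_cache <- if (is.null(cm)) NA else cm
          }
          if (is.matrix(cm_cache)) {
            res[p[[i]], j] <- if (m == "dynamic_full")
              dynamic_similarity(cm_cache) else
              simpler_dynamic_similarity(cm_cache)
          }
        } else {
          ctx <- vroot[rid[idx], , drop = FALSE]
          tgt <- vroot[rid[[i]], ]
          res[p[[i]], j] <- if (m %in% c("cosine_content", "cosine_all")) {
            suppressWarnings(cosine_sim(colSums(ctx), tgt))
          } else {
            as.numeric(euclidean_measure_vec(tgt, ctx))
          }
        }
      }
    }
  }

  out <- data.frame(
    passage_id = tokens$passage_id,
    token_index = tokens$token_index,
    norm = tokens$norm,
    length = nchar(tokens$norm),
    word_class = tokens$word_class,
    stringsAsFactors = FALSE
  )
  fr <- resolve_frequencies(tokens$norm, freq_table)
  out$log_freq <- fr$log_freq
  out$freq_imputed <- fr$imputed
  out <- cbind(out, as.data.frame(res))
  if (dataset == 1L) out <- out[out$word_class == "content", , drop = FALSE]
  rownames(out) <- NULL
  out
}

euclidean_measure_vec <- function(tgt, ctx) {
  d <- sqrt(sum((tgt - colMeans(ctx))^2))
  if (d < 1e-12) structure(EUCLIDEAN_SATURATION, saturated = TRUE) else 1 / d
}

resolve_frequencies <- function(norm, freq_table) {
  if (is.null(freq_table)) {
    return(list(log_freq = rep(NA_real_, length(norm)),
                imputed = rep(NA, length(norm))))
  }
  stopifnot(all(c("word", "count") %in% names(freq_table)))
  cnt <- freq_table$count[match(norm, freq_table$word)]
  imputed <- is.na(cnt)
  coverage <- 1 - mean(imputed)
  if (coverage < 0.9) {
    warning(sprintf(
      "frequency table covers only %.1f%% of tokens; missing words imputed at the minimum count",
      100 * coverage))
  }
  cnt[imputed] <- min(freq_table$count)
  list(log_freq = log(cnt), imputed = imputed)
}

#' Join token scores with fixation-duration records
#'
#' Inner join on `(passage_id, token_index)`. Unmatched fixation rows are
#' counted and reported via the `unmatched` attribute; a warning is emitted
#' when fewer than 95% of fixation rows find a scored token.
#'
#' @param scores token score table from [compute_token_table()].
#' @param fixations `data.frame` (or CSV path) with columns `passage_id`,
#'   `token_index`, `participant`, `first_fixation_ms`, `total_fixation_ms`.
#' @return `data.frame` with the score columns replicated per participant,
#'   plus the two duration columns; attribute `unmatched` = number of
#'   fixation rows with no scored token.
#' @export
join_eyetracking <- function(scores, fixations) {
  if (is.character(fixations)) {
    fixations <- utils::read.csv(fixations, stringsAsFactors = FALSE,
                                 encoding = "UTF-8")
  }
  need <- c("passage_id", "token_index", "participant",
            "first_fixation_ms", "total_fixation_ms")
  miss <- setdiff(need, names(fixations))
  if (length(miss))
    stop("fixation data lacks required columns: ",
         paste(miss, collapse = ", "))
  key_s <- paste(scores$passage_id, scores$token_index)
  key_f <- paste(fixations$passage_id, fixations$token_index)
  matched <- key_f %in% key_s
  n_un <- sum(!matched)
  if (mean(matched) < 0.95) {
    warning(sprintf("only %.1f%% of fixation rows matched a scored token",
                    100 * mean(matched)))
  }
  joined <- merge(scores, fixations[matched, , drop = FALSE],
                  by = c("passage_id", "token_index"), sort = FALSE)
  joined <- joined[order(joined$passage_id, joined$token_index,
                         joined$participant), , drop = FALSE]
  rownames(joined) <- NULL
  structure(joined, unmatched = n_un)
}

#' Recover the similarity effect from fixation durations
#'
#' A deliberately lightweight estimator for simulation checks: ordinary
#' least squares on participant-mean-centered durations with word length
#' and log frequency as covariates. Centering by participant removes the
#' random intercept exactly in a balanced design, so the similarity slope
#' (ms per similarity unit) is directly comparable to the generating
#' coefficient of [simulate_fixations()]. This is a linear stand-in for the
#' additive mixed models used in full analyses of real eye-tracking data —
#' adequate for sign and magnitude recovery, not a smooth-model fit.
#'
#' @param analysis joined table from [join_eyetracking()].
#' @param measure similarity column to estimate the effect of.
#' @param response `"first"` or `"total"` fixation duration.
#' @return list with `slope` (ms per similarity unit), `se`, `n` (rows
#'   used) and the fitted `lm` object (`fit`).
#' @export
recover_similarity_effect <- function(analysis, measure,
                                      response = c("first", "total")) {
  response <- match.arg(response)
  ycol <- paste0(response, "_fixation_ms")
  stopifnot(measure %in% names(analysis), ycol %in% names(analysis))
  keep <- stats::complete.cases(
    analysis[, c(measure, ycol, "length", "log_freq", "participant")])
  d <- analysis[keep, , drop = FALSE]
  if (!nrow(d) || all(is.na(analysis[[measure]])))
    stop("measure column ", measure, " has no complete records")
  if (length(unique(d$participant)) < 2L)
    stop("need at least 2 participants")
  if (nrow(d) < 100L)
    stop("need at least 100 complete records, got ", nrow(d))
  pm <- stats::ave(d[[ycol]], d$participant)
  d$.y_centered <- d[[ycol]] - pm
  fml <- stats::reformulate(c(measure, "length", "log_freq"),
                            response = ".y_centered")
  fit <- stats::lm(fml, data = d)
  est <- summary(fit)$coefficients[measure, ]
  list(slope = unname(est[["Estimate"]]), se = unname(est[["Std. Error"]]),
       n = nrow(d), fit = fit)
}

#' Write and read token score / analysis tables as CSV
#'
#' UTF-8, header row, RFC-4180 quoting. Missing similarity values are
#' written as empty fields. Numeric columns round-trip to at least 1e-9.
#'
#' @param x a `data.frame`.
#' @param path output CSV path.
#' @return `path` (write) or the `data.frame` (read).
#' @export
write_scores_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(col) {
    ifelse(is.na(col), NA_character_, sprintf("%.15g", col))
  })
  utils::write.csv(x, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
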