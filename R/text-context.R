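#' Closed-class (function) word list
#'
#' The packaged English closed-class list used to split tokens into content
#' vs function words: determiners, prepositions, conjunctions, pronouns,
#' auxiliaries and modals, particles, wh-words and negation. Everything not
#' on the list is treated as a content word. Override by passing your own
#' vector (or a file read into one) to [classify_words()] and
#' [tokenize_text()].
#'
#' @return character vector of normalized function-word forms.
#' @export
function_word_list <- function() {
  c(
    # determiners / articles / quantifiers
    "a", "an", "the", "this", "that", "these", "those", "each", "every",
    "either", "neither", "some", "any", "no", "all", "both", "half",
    "several", "enough", "such", "another", "other", "much", "many", "few",
    "little", "most", "more", "less", "least", "own", "same",
    # prepositions / particles
    "of", "in", "on", "at", "by", "for", "with", "about", "against",
    "between", "among", "into", "through", "during", "before", "after",
    "above", "below", "to", "from", "up", "down", "out", "off", "over",
    "under", "again", "further", "then", "once", "here", "there", "near",
    "across", "behind", "beyond", "beside", "besides", "within", "without",
    "along", "around", "upon", "toward", "towards", "onto", "until", "till",
    "since", "despite", "except", "via", "per", "amid", "throughout",
    # conjunctions / complementizers
    "and", "but", "or", "nor", "so", "yet", "because", "although", "though",
    "while", "whereas", "if", "unless", "whether", "as", "than", "that",
    "lest", "albeit",
    # pronouns
    "i", "me", "my", "mine", "myself", "we", "us", "our", "ours",
    "ourselves", "you", "your", "yours", "yourself", "yourselves", "he",
    "him", "his", "himself", "she", "her", "hers", "herself", "it", "its",
    "itself", "they", "them", "their", "theirs", "themselves", "one",
    "ones", "oneself", "someone", "somebody", "something", "anyone",
    "anybody", "anything", "everyone", "everybody", "everything", "nobody",
    "nothing", "none",
    # auxiliaries / copula / modals
    "be", "am", "is", "are", "was", "were", "been", "being", "have", "has",
    "had", "having", "do", "does", "did", "doing", "will", "would", "shall",
    "should", "can", "could", "may", "might", "must", "ought", "need",
    "dare", "used",
    # wh-words
    "who", "whom", "whose", "which", "what", "where", "when", "why", "how",
    "whoever", "whatever", "whichever", "wherever", "whenever",
    # negation / infinitive marker / existential
    "not", "n't", "never", "ever", "too", "very", "just", "only", "also",
    "there"
  )
}

#' Classify normalized word forms as content or function words
#'
#' @param norm character vector of normalized forms.
#' @param function_words character vector of closed-class forms; defaults to
#'   the packaged list [function_word_list()].
#' @return character vector, each element `"function"` or `"content"`.
#' @export
#' @examples
#' classify_words(c("the", "watch"))
classify_words <- function(norm, function_words = function_word_list()) {
  ifelse(norm %in% function_words, "function", "content")
}

#' Tokenize passage text into a token table
#'
#' Deterministic, rule-based segmentation. Sentences end at runs of terminal
#' punctuation (`.`, `!`, `?`) optionally followed by closing quotes or
#' brackets; word tokens are produced by whitespace splitting with
#' surrounding punctuation stripped (hyphenated words stay whole; tokens that
#' are pure punctuation are discarded). Determinism of the token indices is
#' what makes a later join against fixation records by `(passage_id,
#' token_index)` reliable.
#'
#' @param text character vector of passages, or a single string in which
#'   passages are separated by blank lines.
#' @param passage_ids optional character vector of passage identifiers;
#'   defaults to `"p001"`, `"p002"`, ...
#' @param function_words closed-class list for [classify_words()].
#' @return a `data.frame` with one row per token: `passage_id`,
#'   `sentence_index` (0-based, non-decreasing), `token_index` (0-based,
#'   strictly increasing within passage), `surface`, `norm`, `word_class`.
#' @export
#' @examples
#' tokenize_text("We invade the smart watch space.")
tokenize_text <- function(text, passage_ids = NULL,
                          function_words = function_word_list()) {
  stopifnot(is.character(text), length(text) >= 1L)
  if (length(text) == 1L && grepl("\n[ \t]*\n", text)) {
    text <- strsplit(text, "\n[ \t]*\n")[[1L]]
  }
  text <- text[nzchar(trimws(text))]
  if (!length(text)) stop("no non-empty passage text supplied")
  if (is.null(passage_ids)) {
    passage_ids <- sprintf("p%03d", seq_along(text))
  }
  stopifnot(length(passage_ids) == length(text))

  out <- vector("list", length(text))
  for (p in seq_along(text)) {
    # sentence boundaries: terminal punctuation run + optional closing quotes
    sents <- stringi::stri_split_regex(
      text[[p]], "[.!?]+[\"'”’)\\]]*(\\s+|$)"
    )[[1L]]
    sents <- sents[nzchar(trimws(sents))]
    if (!length(sents)) stop("passage ", passage_ids[[p]],
                             " contains no sentences")
    surface <- character(0)
    sent_idx <- integer(0)
    for (s in seq_along(sents)) {
      toks <- stringi::stri_split_regex(sents[[s]], "\\s+")[[1L]]
      toks <- toks[nzchar(toks)]
      norm_probe <- normalize_words(toks)
      toks <- toks[nzchar(norm_probe)]        # drop standalone punctuation
      if (!length(toks)) next
      surface <- c(surface, toks)
      sent_idx <- c(sent_idx, rep.int(s - 1L, length(toks)))
    }
    if (!length(surface)) stop("passage ", passage_ids[[p]],
                               " contains no word tokens")
    # renumber sentences that were emptied by punctuation-only content
    sent_idx <- match(sent_idx, sort(unique(sent_idx))) - 1L
    norm <- normalize_words(surface)
    out[[p]] <- data.frame(
      passage_id = passage_ids[[p]],
      sentence_index = sent_idx,
      token_index = seq_along(surface) - 1L,
      surface = surface,
      norm = norm,
      word_class = classify_words(norm, function_words),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read a pre-tokenized passage CSV
#'
#' Accepts the alternative input schema with columns `passage_id`,
#' `sentence_index`, `token_index`, `surface`; normalization and word-class
#' columns are (re)computed on load.
#'
#' @param path CSV path (UTF-8, header row).
#' @param function_words closed-class list for [classify_words()].
#' @return token table as from [tokenize_text()].
#' @export
read_tokens_csv <- function(path, function_words = function_word_list()) {
  tok <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("passage_id", "sentence_index", "token_index", "surface")
  if (!all(need %in% names(tok)))
    stop("token CSV must have columns: ", paste(need, collapse = ", "))
  tok <- tok[order(tok$passage_id, tok$token_index), , drop = FALSE]
  tok$norm <- normalize_words(tok$surface)
  tok$word_class <- classify_words(tok$norm, function_words)
  rownames(tok) <- NULL
  tok
}

#' Flag tokens as in- or out-of-vocabulary against an embedding table
#'
#' @param tokens token table from [tokenize_text()].
#' @param table an [embedding_table()].
#' @return `tokens` with a logical `in_vocab` column added/replaced.
#' @export
set_in_vocab <- function(tokens, table) {
  tokens$in_vocab <- in_vocabulary(table, tokens$norm)
  tokens
}

#' Context-window policies
#'
#' Three policies cover the six similarity measures:
#' * `FIXED_K_ALL` — the `k` nearest preceding in-vocabulary tokens of any
#'   word class. Out-of-vocabulary tokens are skipped and the lookback
#'   extends further left, bounded by the passage start; sentence boundaries
#'   are crossed, passage boundaries never. The window is undefined unless a
#'   full set of `k` tokens is found, which keeps the dynamic measure's range
#'   fixed (exactly `k(k+1)/2` correlation pairs) and hence comparable
#'   across tokens.
#' * `FIXED_K_CONTENT_SENT` — up to `k` most recent preceding in-vocabulary
#'   content words within the current sentence; undefined if none.
#' * `ALL_PRECEDING_SENT` — every preceding in-vocabulary token in the
#'   current sentence, any class; undefined for sentence-initial targets.
#'
#' @return character vector of the policy identifiers.
#' @export
window_policies <- function() {
  c("FIXED_K_ALL", "FIXED_K_CONTENT_SENT", "ALL_PRECEDING_SENT")
}

# Core lookback over plain vectors; returns 1-based context indices
# (earliest first) or NULL when the window is undefined.
window_indices <- function(sentence_index, in_vocab, word_class,
                           target_i, policy, k) {
  if (!in_vocab[[target_i]]) return(NULL)
  if (policy == "FIXED_K_ALL") {
    cand <- which(in_vocab[seq_len(target_i - 1L)])
    if (length(cand) < k) return(NULL)
    sort(utils::tail(cand, k))
  } else if (policy == "FIXED_K_CONTENT_SENT") {
    pre <- seq_len(target_i - 1L)
    cand <- pre[sentence_index[pre] == sentence_index[[target_i]] &
                  in_vocab[pre] & word_class[pre] == "content"]
    if (!length(cand)) return(NULL)
    sort(utils::tail(cand, k))
  } else if (policy == "ALL_PRECEDING_SENT") {
    pre <- seq_len(target_i - 1L)
    cand <- pre[sentence_index[pre] == sentence_index[[target_i]] &
                  in_vocab[pre]]
    if (!length(cand)) return(NULL)
    cand
  } else {
    stop("unknown window policy: ", policy)
  }
}

#' Extract the preceding-context window for a target token
#'
#' @param tokens single-passage token table (see [tokenize_text()]); an
#'   `in_vocab` column is computed from `table` if absent.
#' @param target_index 0-based token index of the target within the passage.
#' @param policy one of [window_policies()].
#' @param k window size for the fixed-`k` policies (default 3, following the
#'   three-preceding-words convention).
#' @param table an [embedding_table()] used to resolve vocabulary membership.
#' @return a `context_window` (list with `target` and `context` token rows,
#'   `policy`, `k`), or `NULL` when the window is undefined under the policy
#'   (no preceding words, an out-of-vocabulary target, or an incomplete
#'   fixed-`k` context).
#' @export
extract_window <- function(tokens, target_index, policy, k = 3L, table) {
  stopifnot(policy %in% window_policies())
  if (length(unique(tokens$passage_id)) != 1L)
    stop("`tokens` must contain exactly one passage")
  if (k < 1L) stop("k must be >= 1")
  if (is.null(tokens$in_vocab)) tokens <- set_in_vocab(tokens, table)
  tokens <- tokens[order(tokens$token_index), , drop = FALSE]
  ti <- match(target_index, tokens$token_index)
  if (is.na(ti)) stop("target_index ", target_index, " not in passage")
  idx <- window_indices(tokens$sentence_index, tokens$in_vocab,
                        tokens$word_class, ti, policy, k)
  if (is.null(idx)) return(NULL)
  structure(
    list(target = tokens[ti, , drop = FALSE],
         context = tokens[idx, , drop = FALSE],
         policy = policy, k = as.integer(k)),
    class = "context_window"
  )
}

#' @export
print.context_window <- function(x, ...) {
  cat(sprintf("<context_window> policy=%s k=%d\n  [%s] -> %s\n",
              x$policy, x$k, paste(x$context$norm, collapse = ", "),
              x$target$norm))
  invisible(x)
}
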