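#' Normalize word forms for embedding lookup
#'
#' Applies the package's default matching policy: Unicode NFC, case-fold to
#' lower case, and strip leading/trailing punctuation. Word-internal hyphens
#' and apostrophes are preserved. Lowercase matching maximizes the hit rate
#' against word2vec-style vocabularies, which are dominated by lowercase keys.
#'
#' @param x character vector of raw word forms.
#' @param case_fold lower-case the forms (default `TRUE`).
#' @param strip_punct strip leading/trailing punctuation (default `TRUE`).
#' @return character vector of normalized forms, same length as `x`.
#' @export
#' @examples
#' normalize_words(c("Space,", "smart-watch", "“We”"))
normalize_words <- function(x, case_fold = TRUE, strip_punct = TRUE) {
  x <- stringi::stri_trans_nfc(as.character(x))
  if (case_fold) x <- stringi::stri_trans_tolower(x)
  if (strip_punct) {
    x <- stringi::stri_replace_all_regex(x, "^[\\p{P}\\p{S}]+|[\\p{P}\\p{S}]+$", "")
  }
  x
}

#' Construct an embedding table
#'
#' An `embedding_table` holds a |V| x d numeric matrix whose rownames are the
#' normalized vocabulary, plus parse metadata. Most users obtain one from
#' [read_vec()] or [make_embeddings()].
#'
#' @param vectors numeric matrix, one row per word, rownames = normalized
#'   vocabulary keys (must be unique).
#' @param meta optional list of provenance fields (declared count/dimension,
#'   skipped-line and collision counters).
#' @return an object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, meta = list()) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors)))
    stop("`vectors` must have unique rownames (the vocabulary)")
  if (ncol(vectors) < 1L || nrow(vectors) < 1L)
    stop("empty embedding table")
  if (!all(is.finite(vectors)))
    stop("embedding vectors must be finite")
  structure(
    list(vectors = vectors, dimension = ncol(vectors), meta = meta),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words x %d dimensions\n",
              nrow(x$vectors), x$dimension))
  if (length(x$meta)) {
    m <- x$meta
    if (!is.null(m$skipped) && m$skipped > 0)
      cat(sprintf("  skipped malformed lines: %d\n", m$skipped))
    if (!is.null(m$collisions) && m$collisions > 0)
      cat(sprintf("  normalization collisions (first occurrence kept): %d\n",
                  m$collisions))
  }
  invisible(x)
}

#' Read a word2vec/fastText plain-text embedding file
#'
#' Parses the `.vec` text dialect: a header line `"N D"` followed by one line
#' per word, `"word f1 ... fD"`, single-space separated, UTF-8. Lines whose
#' number of numeric fields does not match the declared dimension (a common
#' artifact of multi-word keys in distributed `.vec` files) are skipped and
#' counted, not fatal. When two raw words normalize to the same key the first
#' occurrence wins and a collision counter is incremented.
#'
#' @param path path to the `.vec` file.
#' @param case_fold,strip_punct normalization policy, see [normalize_words()].
#' @param max_words optional cap on the number of accepted words (useful for
#'   large files); `Inf` reads everything.
#' @return an [embedding_table()] whose `meta` records the declared header
#'   counts plus `skipped` and `collisions`.
#' @export
read_vec <- function(path, case_fold = TRUE, strip_punct = TRUE,
                     max_words = Inf) {
  if (!file.exists(path)) stop("cannot read embedding file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("malformed header: empty file")
  hdr <- strsplit(trimws(lines[[1L]]), " ", fixed = TRUE)[[1L]]
  hdr_n <- suppressWarnings(as.integer(hdr))
  if (length(hdr_n) != 2L || anyNA(hdr_n) || any(hdr_n <= 0L))
    stop("malformed header: expected two positive integers, got ",
         sQuote(lines[[1L]]))
  d <- hdr_n[[2L]]

  body <- lines[-1L]
  body <- body[nzchar(body)]
  words <- character(0)
  rows <- list()
  skipped <- 0L
  collisions <- 0L
  seen <- new.env(parent = emptyenv())
  for (ln in body) {
    fields <- strsplit(ln, " ", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (length(vals) != d || anyNA(vals) || !all(is.finite(vals))) {
      skipped <- skipped + 1L
      next
    }
    key <- normalize_words(fields[[1L]], case_fold, strip_punct)
    if (!nzchar(key) || !is.null(seen[[key]])) {
      collisions <- collisions + if (nzchar(key)) 1L else 0L
      skipped <- skipped + if (nzchar(key)) 0L else 1L
      next
    }
    seen[[key]] <- TRUE
    words[[length(words) + 1L]] <- key
    rows[[length(rows) + 1L]] <- vals
    if (length(rows) >= max_words) break
  }
  if (!length(rows)) stop("no well-formed embedding rows accepted from ", path)
  vec <- do.call(rbind, rows)
  rownames(vec) <- words
  embedding_table(vec, meta = list(
    declared_count = hdr_n[[1L]], declared_dim = d,
    skipped = skipped, collisions = collisions, source = path
  ))
}

#' Write an embedding table in `.vec` text format
#'
#' @param table an [embedding_table()].
#' @param path output file path.
#' @param digits significant digits per entry (default 17 round-trips doubles
#'   exactly; distributed files typically use 4-6).
#' @return `path`, invisibly.
#' @export
write_vec <- function(table, path, digits = 17) {
  stopifnot(inherits(table, "embedding_table"))
  v <- table$vectors
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[[i]], formatC(v[i, ], digits = digits, format = "g")),
          collapse = " ")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Look up embedding vectors by normalized word form
#'
#' Out-of-vocabulary forms are reported as missing, never as an error: the
#' result for an absent word is a row of `NA`.
#'
#' @param table an [embedding_table()].
#' @param words character vector of normalized forms.
#' @return numeric matrix with `length(words)` rows (rownames = `words`);
#'   `NA` rows mark out-of-vocabulary forms.
#' @export
lookup_vectors <- function(table, words) {
  stopifnot(inherits(table, "embedding_table"))
  idx <- match(words, rownames(table$vectors))
  out <- table$vectors[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  out[is.na(idx), ] <- NA_real_
  rownames(out) <- words
  out
}

#' Test vocabulary membership
#'
#' @param table an [embedding_table()].
#' @param words character vector of normalized forms.
#' @return logical vector: `TRUE` where the form is in the vocabulary.
#' @export
in_vocabulary <- function(table, words) {
  words %in% rownames(table$vectors)
}
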