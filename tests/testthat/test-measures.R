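test_that("pearson matches a from-definition two-pass computation", {
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               oracle_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    u <- rnorm(300); v <- rnorm(300)
    expect_equal(pearson_cor(u, v), oracle_pearson(u, v), tolerance = 1e-12)
  }
  u <- rnorm(50)
  expect_equal(pearson_cor(u, u), 1)
  expect_equal(pearson_cor(u, 2.5 * u + 7), 1)     # affine invariance
  expect_warning(r <- pearson_cor(u, rep(1, 50)), "zero-variance")
  expect_true(is.na(r))
})

test_that("cosine matches a from-definition dot/norm computation", {
  set.seed(32)
  for (i in 1:20) {
    u <- rnorm(300); v <- rnorm(300)
    expect_equal(cosine_sim(u, v), oracle_cosine(u, v), tolerance = 1e-12)
  }
  u <- rnorm(10)
  expect_equal(cosine_sim(u, 2 * u), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_warning(r <- cosine_sim(u, rep(0, 10)), "zero-norm")
  expect_true(is.na(r))
})

test_that("correlation matrices are symmetric, unit-diagonal and exact", {
  fx <- fig3_fixture()
  w <- extract_window(fx$tokens, 5L, "FIXED_K_ALL", 3L, fx$table)
  m <- correlation_matrix(w, fx$table)
  expect_equal(rownames(m), c("the", "smart", "watch", "space"))
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_identical(unname(diag(m)), rep(1, 4))
  expect_true(all(m >= -1 & m <= 1))
  # reproduces the printed worked-example cells
  expect_equal(m["space", "the"], 0.42, tolerance = 1e-10)
  expect_equal(unname(m[4, 1:3]), c(0.42, 0.31, 0.25), tolerance = 1e-10)
  expect_equal(unname(m[lower.tri(m)]),
               c(0.17, 0.18, 0.42, 0.65, 0.31, 0.25), tolerance = 1e-10)

  # random window: entrywise equal to brute-force pearson over all 6 pairs
  tab <- toy_table()
  tok <- make_passages(tab, n_passages = 1L, mean_words = 10,
                       function_word_rate = 0, seed = 17L)
  w2 <- extract_window(tok, 5L, "FIXED_K_ALL", 3L, tab)
  m2 <- correlation_matrix(w2, tab)
  words <- c(w2$context$norm, w2$target$norm)
  for (a in 1:4) for (b in 1:4) {
    expect_equal(m2[a, b],
                 oracle_pearson(drop(lookup_vectors(tab, words[[a]])),
                                drop(lookup_vectors(tab, words[[b]]))),
                 tolerance = 1e-12)
  }
})

test_that("dynamic measures sum the right triangle cells", {
  fx <- fig3_fixture()
  expect_equal(dynamic_similarity(fx$corr), 1.98, tolerance = 1e-12)
  expect_equal(simpler_dynamic_similarity(fx$corr), 0.98, tolerance = 1e-12)

  ones <- matrix(1, 4, 4)
  expect_equal(dynamic_similarity(ones), 6)
  expect_equal(simpler_dynamic_similarity(ones), 3)

  set.seed(33)
  for (i in 1:10) {
    x <- matrix(rnorm(40), 10, 4)
    m <- stats::cor(x)
    # explicit index-set sum
    full <- 0
    for (a in 1:4) for (b in 1:4) if (a > b) full <- full + m[a, b]
    expect_equal(dynamic_similarity(m), full, tolerance = 1e-12)
    # algebraic identity: target row = full minus context-context pairs
    ctx <- 0
    for (a in 1:3) for (b in 1:3) if (a > b) ctx <- ctx + m[a, b]
    expect_equal(simpler_dynamic_similarity(m), full - ctx,
                 tolerance = 1e-12)
  }
})

test_that("cosine and inverse-distance measures follow their definitions", {
  # one context word identical to the target -> cosine 1
  v <- matrix(rnorm(2 * 20), 2, 20)
  v[2, ] <- v[1, ]
  rownames(v) <- c("alpha", "beta")
  tab <- embedding_table(v)
  tok <- tokenize_text("Alpha beta.")
  w <- extract_window(tok, 1L, "ALL_PRECEDING_SENT", 3L, tab)
  expect_equal(cosine_measure(w, tab), 1)
  # target equal to context mean -> saturated inverse distance
  e <- euclidean_measure(w, tab)
  expect_equal(as.numeric(e), 1e12)
  expect_true(attr(e, "saturated"))

  # distance exactly 2 gives 0.5
  v2 <- rbind(alpha = c(1, 1, 0), beta = c(1, 1, 2))
  tab2 <- embedding_table(v2)
  w2 <- extract_window(tokenize_text("Alpha beta."), 1L,
                       "ALL_PRECEDING_SENT", 3L, tab2)
  expect_equal(as.numeric(euclidean_measure(w2, tab2)), 0.5)

  # context vectors summing to zero -> cosine missing, not an error
  v3 <- rbind(pos = c(1, 2, 3), neg = c(-1, -2, -3), tgt = c(1, 0, 1))
  tab3 <- embedding_table(v3)
  w3 <- extract_window(tokenize_text("Pos neg tgt."), 2L,
                       "ALL_PRECEDING_SENT", 3L, tab3)
  expect_warning(cv <- cosine_measure(w3, tab3), "zero-norm")
  expect_true(is.na(cv))
})

test_that("compute_measure dispatches per measure and propagates missingness", {
  fx <- fig3_fixture()
  r <- compute_measure(fx$tokens, 5L, "dynamic_full", 3L, fx$table)
  expect_equal(r$value, 1.98, tolerance = 1e-10)
  r2 <- compute_measure(fx$tokens, 5L, "dynamic_simpler", 3L, fx$table)
  expect_equal(r2$value, 0.98, tolerance = 1e-10)
  for (m in measure_ids()) {
    r0 <- compute_measure(fx$tokens, 0L, m, 3L, fx$table)
    expect_true(is.na(r0$value))
    expect_equal(r0$n_context, 0L)
  }
  # constant word vector -> missing dynamic value, no crash
  v <- rbind(flat = rep(2, 10), tgt = rnorm(10), tgt2 = rnorm(10))
  tabc <- embedding_table(v)
  tokc <- tokenize_text("Flat tgt tgt2.")
  expect_warning(
    rc <- compute_measure(tokc, 2L, "dynamic_full", 2L, tabc),
    "constant")
  expect_true(is.na(rc$value))
})

test_that("measure values respect their theoretical bounds", {
  tab <- toy_table(noise_scale = 0.6)
  tok <- make_passages(tab, n_passages = 8L, mean_words = 40,
                       function_word_rate = 0.3, seed = 23L)
  sc <- compute_token_table(tok, tab, k = 3L)
  expect_true(all(abs(sc$cosine_content) <= 1, na.rm = TRUE))
  expect_true(all(abs(sc$cosine_all) <= 1, na.rm = TRUE))
  expect_true(all(abs(sc$dynamic_full) <= 6, na.rm = TRUE))
  expect_true(all(abs(sc$dynamic_simpler) <= 3, na.rm = TRUE))
  expect_true(all(sc$euclidean_sentence > 0, na.rm = TRUE))
  expect_true(all(sc$euclidean_fixed > 0, na.rm = TRUE))
})

test_that("all measures are invariant to context-order permutation", {
  tab <- toy_table()
  tok <- make_passages(tab, n_passages = 2L, mean_words = 25,
                       function_word_rate = 0.3, seed = 29L)
  tok <- set_in_vocab(tok, tab)
  shuffle_ctx <- function(w, perm) {
    w$context <- w$context[perm, , drop = FALSE]
    w
  }
  set.seed(5)
  for (pid in unique(tok$passage_id)) {
    pt <- tok[tok$passage_id == pid, ]
    for (i in c(5L, 10L, 15L)) {
      for (m in measure_ids()) {
        w <- extract_window(pt, i, measure_policy(m), 3L, tab)
        if (is.null(w)) next
        perm <- sample(nrow(w$context))
        v1 <- contextsim:::apply_measure(w, m, tab)
        v2 <- contextsim:::apply_measure(shuffle_ctx(w, perm), m, tab)
        expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)
      }
    }
  }
})

test_that("dynamic measures are invariant to per-word positive affine maps", {
  tab <- toy_table()
  tok <- make_passages(tab, n_passages = 1L, mean_words = 20,
                       function_word_rate = 0, seed = 37L)
  set.seed(6)
  for (i in c(4L, 9L, 14L)) {
    w <- extract_window(tok, i, "FIXED_K_ALL", 3L, tab)
    words <- c(w$context$norm, w$target$norm)
    v0 <- tab$vectors
    # rescale one random word in the window: v -> a*v + b
    tweak <- v0
    pick <- sample(words, 1L)
    a <- runif(1, 0.2, 5); b <- rnorm(1, 0, 10)
    tweak[pick, ] <- a * tweak[pick, ] + b
    tab2 <- embedding_table(tweak)
    m1 <- correlation_matrix(w, tab)
    m2 <- correlation_matrix(w, tab2)
    expect_equal(dynamic_similarity(m1), dynamic_similarity(m2),
                 tolerance = 1e-10)
    expect_equal(simpler_dynamic_similarity(m1),
                 simpler_dynamic_similarity(m2), tolerance = 1e-10)
    # pure scaling also leaves cosine with any other word unchanged
    scale_only <- v0
    scale_only[pick, ] <- a * scale_only[pick, ]
    other <- setdiff(words, pick)[[1L]]
    expect_equal(
      cosine_sim(v0[pick, ], v0[other, ]),
      cosine_sim(scale_only[pick, ], scale_only[other, ]),
      tolerance = 1e-12)
  }
})

test_that("the pipeline agrees elementwise with the brute-force oracle", {
  tab <- toy_table(seed = 41L)
  tok <- make_passages(tab, n_passages = 5L, mean_words = 40,
                       mean_sentences = 2.5, function_word_rate = 0.35,
                       seed = 43L)
  sc <- compute_token_table(tok, tab, k = 3L)
  ref <- oracle_all_measures(tok, tab, k = 3L)
  for (m in measure_ids()) {
    expect_identical(is.na(sc[[m]]), is.na(ref[[m]]))
    expect_lt(max(abs(sc[[m]] - ref[[m]]), na.rm = TRUE), 1e-10)
  }
})
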