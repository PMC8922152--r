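test_that("the one-topic model reduces to its closed form", {
  dtm <- build_dtm(list(c("aa", "bb", "aa"), c("bb", "cc")))
  params <- topic_params(K = 1, alpha = 1, beta = 0.1, n_iterations = 20,
                         burn_in = 5, sample_lag = 1, seed = 1)
  m <- fit_lda(dtm, params)
  expect_true(all(m$theta == 1))
  counts <- as.integer(Matrix::colSums(dtm$counts))
  expect_equal(unname(m$phi[1, ]), (counts + 0.1) / (5 + 3 * 0.1),
               tolerance = 1e-12)
  expect_equal(log_likelihood(m, dtm),
               sum(counts * log((counts + 0.1) / (5 + 3 * 0.1))),
               tolerance = 1e-12)
})

test_that("a single token under symmetric priors splits topics evenly", {
  dtm <- build_dtm(list("aa"))
  expect_warning(
    m <- fit_lda(dtm, topic_params(K = 2, alpha = 1, beta = 1,
                                   n_iterations = 4000, burn_in = 500,
                                   sample_lag = 5, seed = 8)),
    "degenerate")
  expect_equal(unname(m$theta[1, ]), c(0.5, 0.5), tolerance = 0.05)
})

test_that("disjoint vocabulary blocks are recovered as separate topics", {
  # 100 docs drawn purely from each of two disjoint 10-word blocks
  set.seed(101)
  block1 <- sprintf("aw%02d", 1:10)
  block2 <- sprintf("bw%02d", 1:10)
  docs <- c(lapply(1:100, function(i) sample(block1, 20, replace = TRUE)),
            lapply(1:100, function(i) sample(block2, 20, replace = TRUE)))
  dtm <- build_dtm(docs)
  m <- fit_lda(dtm, topic_params(K = 2, alpha = 1, beta = 0.1,
                                 n_iterations = 300, burn_in = 100,
                                 sample_lag = 5, seed = 4))
  for (k in 1:2) {
    top <- top_words(m, k, 10)
    expect_true(all(top %in% block1) || all(top %in% block2))
  }
  expect_false(setequal(top_words(m, 1, 10), top_words(m, 2, 10)))
  # the two-topic model explains the block corpus better than one topic
  m1 <- fit_lda(dtm, topic_params(K = 1, alpha = 1, beta = 0.1,
                                  n_iterations = 50, burn_in = 10,
                                  sample_lag = 5, seed = 4))
  expect_gt(log_likelihood(m, dtm), log_likelihood(m1, dtm))
})

test_that("count caches stay consistent with the final assignments", {
  cfg <- separated_corpus_config(seed = 41, n_docs = 60, doc_length = 30)
  corpus <- render_corpus(generate_ground_truth(cfg), cfg)
  dtm <- preprocess_corpus(corpus$records)
  m <- fit_lda(dtm, topic_params(K = 3, n_iterations = 80, burn_in = 20,
                                 sample_lag = 5, seed = 6))
  K <- 3
  n_dk <- matrix(0L, nrow(dtm$counts), K)
  n_kv <- matrix(0L, K, ncol(dtm$counts))
  for (i in seq_along(m$z)) {
    n_dk[m$token_doc[i], m$z[i]] <- n_dk[m$token_doc[i], m$z[i]] + 1L
    n_kv[m$z[i], m$token_word[i]] <- n_kv[m$z[i], m$token_word[i]] + 1L
  }
  got_ndk <- m$n_dk
  dimnames(got_ndk) <- NULL
  got_nkv <- m$n_kv
  dimnames(got_nkv) <- NULL
  expect_identical(got_ndk, n_dk)
  expect_identical(got_nkv, n_kv)
  expect_identical(m$n_k, as.integer(rowSums(n_kv)))
  expect_identical(sum(m$n_k), sum(dtm$N_d))
  # phi/theta are smoothed probability rows
  expect_true(all(abs(rowSums(m$phi) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m$theta) - 1) < 1e-9))
  expect_true(all(m$phi > 0) && all(m$theta > 0))
})

test_that("fits are deterministic given dtm, params and seed", {
  dtm <- build_dtm(list(c("aa", "bb", "cc"), c("aa", "cc"), c("bb", "bb")))
  p <- topic_params(K = 2, alpha = 0.5, beta = 0.5, n_iterations = 200,
                    burn_in = 50, sample_lag = 3, seed = 99)
  m1 <- fit_lda(dtm, p)
  m2 <- fit_lda(dtm, p)
  expect_identical(m1$z, m2$z)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$loglik, m2$loglik)
})

test_that("uniform distributions give the closed-form log likelihood", {
  dtm <- build_dtm(list(c("aa", "bb"), c("cc", "dd", "aa")))
  V <- 4
  fake <- structure(list(
    phi = matrix(1 / V, 2, V, dimnames = list(NULL, colnames(dtm$counts))),
    theta = matrix(0.5, 2, 2, dimnames = list(dtm$doc_ids, NULL)),
    doc_ids = dtm$doc_ids), class = "lda_model")
  expect_equal(log_likelihood(fake, dtm), 5 * log(1 / V), tolerance = 1e-12)
})

test_that("log_likelihood rejects mismatched vocabularies", {
  dtm1 <- build_dtm(list(c("aa", "bb")))
  dtm2 <- build_dtm(list(c("aa", "cc")))
  m <- fit_lda(dtm1, topic_params(K = 1, alpha = 1, n_iterations = 10,
                                  burn_in = 2, sample_lag = 1))
  expect_error(log_likelihood(m, dtm2), "vocabulary mismatch")
})

test_that("topic density is the mean pairwise cosine", {
  expect_equal(topic_density(rbind(c(0.2, 0.8), c(0.2, 0.8))), 1.0)
  expect_equal(topic_density(rbind(c(1, 0), c(0, 1))), 0.0)
  expect_equal(topic_density(rbind(c(1, 0), c(0.5, 0.5))), 1 / sqrt(2),
               tolerance = 1e-9)
  expect_error(topic_density(matrix(1, 1, 3)), "at least 2")
})

test_that("K selection returns bounded scores and honors a single candidate", {
  dtm <- build_dtm(list(c("aa", "bb", "cc", "aa"), c("bb", "dd"),
                        c("cc", "dd", "dd")))
  p <- topic_params(n_iterations = 40, burn_in = 10, sample_lag = 2, seed = 2)
  sel <- select_num_topics(dtm, 3, p)
  expect_identical(sel$chosen_K, 3L)
  sel2 <- select_num_topics(dtm, c(2, 3), p)
  expect_true(all(sel2$scores$density >= 0 & sel2$scores$density <= 1))
  expect_error(select_num_topics(dtm, integer(0), p), "empty")
  expect_error(select_num_topics(dtm, 1:3, p), ">= 2")
})

test_that("primary topics use final token counts with lowest-index ties", {
  fake <- structure(list(
    n_dk = matrix(c(5, 3, 2, 3, 0, 0), nrow = 2,
                  dimnames = list(c("d1", "d2"), NULL)),
    theta = matrix(c(0.1, 0.6, 0.3, 0.5, 0.2, 0.3), nrow = 2, byrow = TRUE,
                   dimnames = list(c("d1", "d2"), NULL)),
    doc_ids = c("d1", "d2"), dropped_doc_ids = "d3",
    params = list(K = 3)), class = "lda_model")
  pt <- primary_topics(fake)
  expect_identical(pt$primary_topic, c(1L, 1L, NA))  # (3,3) tie -> topic 1
  expect_identical(pt$doc_id, c("d1", "d2", "d3"))
  th <- primary_topics(fake, method = "theta")
  expect_identical(th$primary_topic[1:2], c(2L, 1L))
})

test_that("top_words returns ranked terms with vocabulary-order ties", {
  fake <- structure(list(
    phi = matrix(c(0.5, 0.2, 0.2, 0.1), nrow = 1,
                 dimnames = list(NULL, c("tt", "uu", "vv", "ww"))),
    params = list(K = 1)), class = "lda_model")
  expect_identical(top_words(fake, 1, 1), "tt")
  expect_identical(top_words(fake, 1, 3), c("tt", "uu", "vv"))
  expect_identical(top_words(fake, 1, 10), c("tt", "uu", "vv", "ww"))
  expect_error(top_words(fake, 2), "out of range")
})

test_that("K larger than the token count warns but still fits", {
  dtm <- build_dtm(list(c("aa", "bb")))
  expect_warning(m <- fit_lda(dtm, topic_params(K = 5, alpha = 1,
                                                n_iterations = 20,
                                                burn_in = 5, sample_lag = 1)),
                 "degenerate")
  expect_identical(nrow(m$phi), 5L)
})
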