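test_that("one-topic configurations give degenerate mixtures", {
  cfg <- synthetic_config(n_docs_per_drug = c(drugx = 20), K_gen = 1,
                          V_gen = 30, doc_length_mean = 15,
                          alpha_gen = 1, rating_effects = 0, seed = 3)
  gt <- generate_ground_truth(cfg)
  expect_true(all(gt$theta_gen == 1))
  expect_true(all(gt$docs$primary_topic == 1))
})

test_that("generation and rendering are deterministic given the seed", {
  cfg <- synthetic_config(n_docs_per_drug = c(a = 25, b = 15), K_gen = 3,
                          V_gen = 40, doc_length_mean = 20, seed = 77)
  gt1 <- generate_ground_truth(cfg)
  gt2 <- generate_ground_truth(cfg)
  expect_identical(gt1, gt2)
  c1 <- render_corpus(gt1, cfg)
  c2 <- render_corpus(gt2, cfg)
  expect_identical(c1, c2)
})

test_that("simplex and label invariants hold", {
  cfg <- synthetic_config(n_docs_per_drug = c(a = 30), K_gen = 4, V_gen = 40,
                          doc_length_mean = 25, seed = 5)
  gt <- generate_ground_truth(cfg)
  expect_true(all(abs(rowSums(gt$phi_gen) - 1) < 1e-9))
  expect_true(all(abs(rowSums(gt$theta_gen) - 1) < 1e-9))
  expect_true(all(unlist(gt$z_gen) %in% seq_len(cfg$K_gen)))
  expect_true(all(gt$docs$length == lengths(gt$z_gen)))
})

test_that("corpus-wide topic token shares match the mixing weights", {
  cfg <- separated_corpus_config(seed = 21)
  gt <- generate_ground_truth(cfg)
  total <- sum(gt$docs$length)
  z_all <- unlist(gt$z_gen)
  # oracle: direct tally of the generating labels vs the length-weighted
  # mean of the drawn mixtures
  for (k in seq_len(cfg$K_gen)) {
    share <- sum(z_all == k) / total
    expected <- sum(gt$theta_gen[, k] * gt$docs$length) / total
    se <- sqrt(expected * (1 - expected) / total)
    expect_lt(abs(share - expected), 3 * se + 1e-12)
  }
})

test_that("rendering without contamination adds no records", {
  cfg <- synthetic_config(n_docs_per_drug = c(a = 12, b = 8), K_gen = 2,
                          V_gen = 30, doc_length_mean = 10,
                          contamination_rates = c(spam = 0, empty = 0,
                                                  underage = 0), seed = 2)
  corpus <- render_corpus(generate_ground_truth(cfg), cfg)
  expect_identical(nrow(corpus$records), 20L)
  expect_identical(nrow(corpus$generator_log$contaminant_ids), 0L)
})

test_that("noise-free ratings equal the configured clipped means exactly", {
  cfg <- synthetic_config(n_docs_per_drug = c(a = 60), K_gen = 3, V_gen = 30,
                          doc_length_mean = 12,
                          rating_effects = c(1.2, 0, -2.6),
                          rating_noise_sd = 0,
                          stratum_rating_shift = c(lt_1_month = 0,
                                                   m1_to_lt_1_year = 0,
                                                   ge_1_year = 0),
                          contamination_rates = c(spam = 0, empty = 0,
                                                  underage = 0), seed = 9)
  gt <- generate_ground_truth(cfg)
  corpus <- render_corpus(gt, cfg)
  # rating = clip(round_half_up(3 + effect)): 4.2 -> 4, 3 -> 3, 0.4 -> 1
  expected <- c(4L, 3L, 1L)[gt$docs$primary_topic]
  expect_identical(corpus$records$rating, expected)
  for (k in 1:3) {
    grp <- corpus$records$rating[gt$docs$primary_topic == k]
    if (length(grp)) expect_equal(mean(grp), expected[gt$docs$primary_topic == k][1])
  }
})

test_that("spam contaminant counts match a rescan of the rendered comments", {
  cfg <- synthetic_config(n_docs_per_drug = c(a = 200), K_gen = 2, V_gen = 40,
                          doc_length_mean = 15,
                          contamination_rates = c(spam = 0.1, empty = 0,
                                                  underage = 0), seed = 31)
  corpus <- render_corpus(generate_ground_truth(cfg), cfg)
  rescan <- sum(grepl("http", tolower(corpus$records$comment), fixed = TRUE) |
                  grepl(".com", tolower(corpus$records$comment), fixed = TRUE) |
                  grepl("www.", tolower(corpus$records$comment), fixed = TRUE))
  injected <- corpus$generator_log$injected
  expect_identical(rescan, as.integer(injected$count[injected$rule == "spam"]))
  expect_gt(rescan, 0)
})

test_that("stripping decoration recovers exactly the generated tokens", {
  cfg <- synthetic_config(n_docs_per_drug = c(a = 40), K_gen = 2, V_gen = 30,
                          doc_length_mean = 18, decorate_frac = 0.5,
                          contamination_rates = c(spam = 0, empty = 0,
                                                  underage = 0), seed = 13)
  gt <- generate_ground_truth(cfg)
  corpus <- render_corpus(gt, cfg)
  pc <- preprocess_config(stopwords = character(0))
  for (d in seq_len(nrow(gt$docs))) {
    toks <- clean_and_tokenize(corpus$records$comment[d], pc)
    expect_identical(toks, gt$vocabulary[gt$words[[d]]])
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_docs_per_drug = c(a = 10), K_gen = 2,
                                alpha_gen = c(1, -1)), "alpha_gen")
  expect_error(synthetic_config(n_docs_per_drug = c(a = 10), beta_gen = 0),
               "beta_gen")
  expect_error(synthetic_config(n_docs_per_drug = c(a = 10),
                                contamination_rates = c(spam = 0.5,
                                                        empty = 0.4,
                                                        underage = 0.2)),
               "contamination")
  expect_error(synthetic_config(n_docs_per_drug = c(a = 10), K_gen = 3,
                                rating_effects = c(1, 2)), "rating_effects")
})
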