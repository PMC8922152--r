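test_that("share percentages reproduce the printed one-decimal convention", {
  expect_equal(share_percent(94, 461), 20.4)
  expect_equal(share_percent(244, 915), 26.7)
  # round-half-up at the third decimal of the percentage
  expect_equal(share_percent(2035, 10000), 20.4)
  expect_error(share_percent(1, 0), "denominator")
})

test_that("share tables count, percentage and marginalize correctly", {
  a <- data.frame(doc_id = sprintf("d%d", 1:8),
                  primary_topic = c(1, 1, 2, 2, 2, 1, NA, 2))
  strata <- c("x", "x", "x", "y", "y", "y", "x", NA)
  st <- share_table(a, strata, K = 2)
  expect_identical(unname(st$counts[, "x"]), c(2L, 1L))
  expect_identical(unname(st$counts[, "y"]), c(1L, 2L))
  expect_identical(unname(st$counts[, "(all)"]), c(3L, 3L))
  expect_equal(unname(st$pct[, "x"]), c(66.7, 33.3))
  expect_identical(unname(st$margins), c(3L, 3L, 6L))
  # columns sum to their margins; percentages to ~100
  expect_true(all(colSums(st$counts) == st$margins))
  expect_true(all(abs(colSums(st$pct) - 100) <= 0.1))
  # single topic -> 100% everywhere
  b <- data.frame(doc_id = c("d1", "d2"), primary_topic = c(1, 1))
  stb <- share_table(b, c("x", "y"), K = 1)
  expect_true(all(stb$pct == 100))
})

test_that("the 2x2 Fisher test equals hypergeometric enumeration", {
  r <- fisher_exact(matrix(c(3, 0, 0, 3), 2))
  expect_equal(r$p_value, 0.1, tolerance = 1e-9)
  expect_equal(r$p_value, fisher_exact_enum(matrix(c(3, 0, 0, 3), 2)),
               tolerance = 1e-9)
  hom <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(hom$p_value, 1.0, tolerance = 1e-12)
  asym <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisher_exact(asym)$p_value, fisher_exact_enum(asym),
               tolerance = 1e-7)
  expect_error(fisher_exact(matrix(c(0, 0, 1, 2), 2)), "zero margin")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("the Monte-Carlo Fisher p converges to the enumerated exact p", {
  tab <- matrix(c(6, 1, 2, 5, 1, 4), nrow = 2)
  exact <- fisher_exact_enum(tab)
  r <- fisher_exact(tab, mc_reps = 2e4, seed = 11)
  expect_lt(abs(r$p_value - exact), 3 * r$mc_se + 1e-4)
  # seeded: same seed, same p
  r2 <- fisher_exact(tab, mc_reps = 2e4, seed = 11)
  expect_identical(r$p_value, r2$p_value)
})

test_that("the Welch t matches the textbook formula and is antisymmetric", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  r <- welch_t(a, b)
  expect_equal(r$statistic, welch_t_oracle(a, b), tolerance = 1e-9)
  expect_equal(r$statistic, -3.6742, tolerance = 1e-4)
  flipped <- welch_t(b, a)
  expect_equal(flipped$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(flipped$p_value, r$p_value, tolerance = 1e-12)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(c(1, 1), c(1, 1)), "degenerate")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA matches a hand sum-of-squares decomposition", {
  # groups (1,2), (2,3), (3,4): SSB = 4 on 2 df, SSW = 1.5 on 3 df -> F = 4
  r <- one_way_anova(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(r$statistic, 4, tolerance = 1e-9)
  expect_equal(unname(r$df), c(2, 3))
  expect_equal(r$p_value, stats::pf(4, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # equal group means -> F = 0, p = 1
  null <- one_way_anova(list(c(1, 3), c(2, 2), c(0, 4)))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2))), ">= 2 groups")
  expect_error(one_way_anova(list(c(1, 2), numeric(0))), "empty group")
})

test_that("with two groups the ANOVA F is the squared pooled t", {
  a <- c(2, 4, 3, 5, 4)
  b <- c(1, 2, 2, 3)
  r <- one_way_anova(list(a, b))
  tt <- welch_t(a, b, var_equal = TRUE)
  expect_equal(r$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(r$p_value, tt$p_value, tolerance = 1e-9)
})

test_that("rating summaries report n/mean/SD with the n<2 rule", {
  rs <- rating_summary(topics = c(1, 1, 2), ratings = c(3, 5, 4),
                       strata = c("x", "y", "x"))
  cells <- rs$cells
  one <- cells[cells$topic == "2" & cells$stratum == "overall", ]
  expect_identical(one$n, 1L)
  expect_equal(one$mean, 4)
  expect_true(is.na(one$sd))
  two <- cells[cells$topic == "1" & cells$stratum == "overall", ]
  expect_equal(two$mean, 4)
  expect_equal(two$sd, sqrt(2), tolerance = 1e-9)
  total <- cells[cells$topic == "total" & cells$stratum == "overall", ]
  expect_identical(total$n, 3L)
  expect_identical(rs$n_missing_rating, 0L)
})

test_that("on noise-free synthetic data group means equal the configured effects", {
  cfg <- synthetic_config(n_docs_per_drug = c(a = 80), K_gen = 2, V_gen = 30,
                          doc_length_mean = 12,
                          rating_effects = c(1, -1), rating_noise_sd = 0,
                          stratum_rating_shift = c(lt_1_month = 0,
                                                   m1_to_lt_1_year = 0,
                                                   ge_1_year = 0),
                          contamination_rates = c(spam = 0, empty = 0,
                                                  underage = 0), seed = 23)
  gt <- generate_ground_truth(cfg)
  corpus <- render_corpus(gt, cfg)
  rs <- rating_summary(gt$docs$primary_topic, corpus$records$rating,
                       rep("all", nrow(gt$docs)))
  cells <- rs$cells
  expect_equal(cells$mean[cells$topic == "1" & cells$stratum == "overall"], 4)
  expect_equal(cells$mean[cells$topic == "2" & cells$stratum == "overall"], 2)
})

test_that("topic-linked rating effects are detectable at n ~ 200 per group", {
  hits <- 0L
  for (r in 1:10) {
    cfg <- synthetic_config(n_docs_per_drug = c(a = 450), K_gen = 2,
                            V_gen = 30, doc_length_mean = 10,
                            alpha_gen = c(0.3, 0.3),
                            rating_effects = c(0.9, -0.9),
                            rating_noise_sd = 1.4,
                            contamination_rates = c(spam = 0, empty = 0,
                                                    underage = 0),
                            seed = 300 + r)
    gt <- generate_ground_truth(cfg)
    corpus <- render_corpus(gt, cfg)
    g1 <- corpus$records$rating[gt$docs$primary_topic == 1]
    g2 <- corpus$records$rating[gt$docs$primary_topic == 2]
    if (welch_t(g1, g2)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
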