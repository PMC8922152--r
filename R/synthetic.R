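# Synthetic review-corpus generator with known LDA ground truth. Emulates the
# structure of scraped patient medication reviews: two drug cohorts of unequal
# size, latent topics with stratum-dependent prevalence (age group x time on
# medication), 1-5 satisfaction ratings tied to each review's dominant topic,
# and ineligible contaminant records (spam links, empty comments, under-age
# or age-missing reviewers) that exercise the eligibility filters.

AGE_GROUPS <- c("19-44", "45-64", "65+")
TIME_GROUPS <- c("lt_1_month", "m1_to_lt_1_year", "ge_1_year")

stratum_label <- function(age_group, time_group) {
  paste(age_group, time_group, sep = "|")
}

#' Default per-stratum document-topic concentrations
#'
#' Builds a strata x K matrix of Dirichlet concentrations in which each
#' stratum mildly favours one topic (cycling through topics across the nine
#' age x time strata), so topic prevalence varies by stratum the way real
#' review corpora do.
#'
#' @param K number of topics.
#' @param base baseline concentration for every topic.
#' @param boost added concentration for the stratum's favoured topic.
#' @return matrix with one named row per age x time stratum.
#' @export
default_stratum_alphas <- function(K, base = 0.4, boost = 0.8) {
  strata <- as.vector(outer(AGE_GROUPS, TIME_GROUPS, stratum_label))
  m <- matrix(base, nrow = length(strata), ncol = K,
              dimnames = list(strata, NULL))
  for (s in seq_along(strata)) {
    m[s, ((s - 1) %% K) + 1] <- base + boost
  }
  m
}

#' Configuration for the synthetic review generator
#'
#' Defaults mirror the study conditions the pipeline targets: two drug
#' cohorts of 463 and 919 eligible reviews, five latent topics, topic-linked
#' rating shifts on the 1-5 Likert scale, longer time on medication raising
#' satisfaction, and a ~12% contamination load split across the three
#' eligibility rules.
#'
#' @param n_docs_per_drug named integer vector: eligible documents per drug.
#' @param K_gen number of generating topics.
#' @param V_gen vocabulary size (distinct pseudo-words).
#' @param alpha_gen document-topic Dirichlet concentrations: a length-`K_gen`
#'   vector (shared by all strata) or a strata x `K_gen` matrix with rows
#'   named `"<age>|<time>"`. Default [default_stratum_alphas()].
#' @param beta_gen topic-word Dirichlet concentration: scalar (symmetric),
#'   length-`V_gen` vector, or `K_gen` x `V_gen` matrix (e.g. block structure
#'   for well-separated topics).
#' @param doc_length_mean expected tokens per document (Poisson, truncated
#'   at 1).
#' @param rating_effects numeric length `K_gen`: mean rating shift (from the
#'   scale midpoint 3) for reviews whose dominant topic is k.
#' @param rating_noise_sd standard deviation of Gaussian rating noise before
#'   rounding and clipping to 1..5.
#' @param stratum_rating_shift named numeric over time-on-medication groups:
#'   additive rating shift per stratum.
#' @param contamination_rates named fractions (`spam`, `empty`, `underage`)
#'   of each drug's eligible count injected as contaminant records.
#' @param decorate_frac fraction of rendered tokens decorated with
#'   punctuation/digits to exercise text cleaning.
#' @param age_probs,time_probs stratum membership probabilities (length 3
#'   each, ordered as the age / time groups).
#' @param seed integer seed; the whole corpus is a pure function of the
#'   configuration.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_docs_per_drug = c(sildenafil = 463, tadalafil = 919),
                             K_gen = 5,
                             V_gen = 200,
                             alpha_gen = NULL,
                             beta_gen = 0.1,
                             doc_length_mean = 100,
                             rating_effects = NULL,
                             rating_noise_sd = 1.4,
                             stratum_rating_shift = c(lt_1_month = -0.35,
                                                      m1_to_lt_1_year = 0.2,
                                                      ge_1_year = 0.4),
                             contamination_rates = c(spam = 0.03, empty = 0.05,
                                                     underage = 0.045),
                             decorate_frac = 0.3,
                             age_probs = c(0.26, 0.57, 0.17),
                             time_probs = c(0.42, 0.28, 0.30),
                             seed = 1L) {
  assert_that(length(n_docs_per_drug) >= 1 && all(n_docs_per_drug >= 1),
              "n_docs_per_drug must be positive")
  assert_that(!is.null(names(n_docs_per_drug)) && all(nzchar(names(n_docs_per_drug))),
              "n_docs_per_drug must be a named vector of drug labels")
  assert_that(K_gen >= 1 && V_gen >= 2, "need K_gen >= 1 and V_gen >= 2")
  if (is.null(alpha_gen)) alpha_gen <- default_stratum_alphas(K_gen)
  if (is.matrix(alpha_gen)) {
    assert_that(ncol(alpha_gen) == K_gen, "alpha_gen must have K_gen columns")
  } else {
    assert_that(length(alpha_gen) == K_gen, "alpha_gen must have length K_gen")
  }
  assert_that(all(alpha_gen > 0), "alpha_gen concentrations must be > 0")
  assert_that(all(beta_gen > 0), "beta_gen concentrations must be > 0")
  if (is.matrix(beta_gen)) {
    assert_that(nrow(beta_gen) == K_gen && ncol(beta_gen) == V_gen,
                "matrix beta_gen must be K_gen x V_gen")
  } else {
    assert_that(length(beta_gen) %in% c(1L, V_gen),
                "beta_gen must be scalar, length V_gen, or K_gen x V_gen")
  }
  assert_that(doc_length_mean > 0, "doc_length_mean must be > 0")
  if (is.null(rating_effects)) {
    rating_effects <- if (K_gen == 1) 0 else
      round(seq(0.9, -0.9, length.out = K_gen), 2)
  }
  assert_that(length(rating_effects) == K_gen,
              "rating_effects must be defined for every topic (length K_gen)")
  assert_that(rating_noise_sd >= 0, "rating_noise_sd must be >= 0")
  assert_that(all(sort(names(contamination_rates)) ==
                    sort(c("spam", "empty", "underage"))),
              "contamination_rates needs names spam, empty, underage")
  assert_that(all(contamination_rates >= 0) && all(contamination_rates < 1) &&
                sum(contamination_rates) < 1,
              "contamination fractions must lie in [0,1) and sum to < 1")
  assert_that(all(sort(names(stratum_rating_shift)) == sort(TIME_GROUPS)),
              "stratum_rating_shift must be named over time-on-medication groups")
  assert_that(length(age_probs) == 3 && length(time_probs) == 3,
              "age_probs and time_probs must have length 3")
  structure(list(
    n_docs_per_drug = n_docs_per_drug, K_gen = as.integer(K_gen),
    V_gen = as.integer(V_gen), alpha_gen = alpha_gen, beta_gen = beta_gen,
    doc_length_mean = doc_length_mean, rating_effects = rating_effects,
    rating_noise_sd = rating_noise_sd,
    stratum_rating_shift = stratum_rating_shift,
    contamination_rates = contamination_rates, decorate_frac = decorate_frac,
    age_probs = age_probs, time_probs = time_probs, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Pronounceable CVCVCV pseudo-words whose Porter stems are pairwise distinct,
# that survive cleaning unchanged (alphabetic, length 6) and that never match
# a stopword or a spam marker. Keeps the rendered corpus invertible: the
# document-term matrix vocabulary maps one-to-one onto the generating
# vocabulary.
make_pseudo_vocabulary <- function(V) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  sw <- stopwords_en()
  words <- character(0)
  stems <- character(0)
  while (length(words) < V) {
    need <- V - length(words)
    cand <- vapply(seq_len(max(need * 3, 30)), function(i) {
      paste0(sample(cons, 3, TRUE), sample(vows, 3, TRUE), collapse = "")
    }, character(1))
    # interleave consonant/vowel: paste0 above pairs them columnwise already
    cand <- unique(cand)
    cand <- setdiff(cand, c(words, sw))
    st <- porter_stem(cand)
    keep <- !duplicated(st) & !(st %in% stems)
    cand <- cand[keep]
    st <- st[keep]
    take <- seq_len(min(length(cand), need))
    words <- c(words, cand[take])
    stems <- c(stems, st[take])
  }
  words
}

alpha_for_stratum <- function(config, stratum) {
  if (is.matrix(config$alpha_gen)) {
    assert_that(stratum %in% rownames(config$alpha_gen),
                "no alpha_gen row for stratum %s", stratum)
    config$alpha_gen[stratum, ]
  } else {
    config$alpha_gen
  }
}

beta_matrix <- function(config) {
  if (is.matrix(config$beta_gen)) return(config$beta_gen)
  matrix(config$beta_gen, nrow = config$K_gen, ncol = config$V_gen,
         byrow = length(config$beta_gen) == config$V_gen)
}

#' Generate LDA ground truth for a synthetic review corpus
#'
#' Draws topic-word distributions from `Dirichlet(beta_gen)`, assigns each
#' document to an age x time stratum, draws its topic mixture from the
#' stratum's `Dirichlet(alpha_gen)`, a truncated-Poisson length, per-token
#' topic labels and words. The dominant ("primary") generating topic of each
#' document is the topic with the most tokens (ties to the lowest index).
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_ground_truth`: list with `vocabulary`,
#'   `phi_gen` (K x V, rows sum to 1), `theta_gen` (D x K), `z_gen` and
#'   `words` (per-document integer vectors), and a `docs` data frame with
#'   drug, stratum, length, primary topic and the noise-free configured
#'   rating per document.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  K <- config$K_gen
  V <- config$V_gen
  withr::with_seed(child_seed(config$seed, "ground_truth"), {
    vocabulary <- make_pseudo_vocabulary(V)
    bmat <- beta_matrix(config)
    phi_gen <- t(vapply(seq_len(K), function(k) rdirichlet(1, bmat[k, ])[1, ],
                        numeric(V)))
    if (K == 1) phi_gen <- matrix(phi_gen, nrow = 1)
    drugs <- names(config$n_docs_per_drug)
    D <- sum(config$n_docs_per_drug)
    theta_gen <- matrix(0, nrow = D, ncol = K)
    z_gen <- vector("list", D)
    words <- vector("list", D)
    docs <- data.frame(
      doc_id = character(D), drug = character(D), age_group = character(D),
      time_group = character(D), length = integer(D),
      primary_topic = integer(D), rating_mu = numeric(D),
      stringsAsFactors = FALSE
    )
    d <- 0L
    for (drug in drugs) {
      for (i in seq_len(config$n_docs_per_drug[[drug]])) {
        d <- d + 1L
        age_group <- sample(AGE_GROUPS, 1, prob = config$age_probs)
        time_group <- sample(TIME_GROUPS, 1, prob = config$time_probs)
        alpha <- alpha_for_stratum(config, stratum_label(age_group, time_group))
        theta <- rdirichlet(1, alpha)[1, ]
        len <- max(1L, rpois(1, config$doc_length_mean))
        z <- sample.int(K, len, replace = TRUE, prob = theta)
        w <- integer(len)
        for (k in unique(z)) {
          idx <- which(z == k)
          w[idx] <- sample.int(V, length(idx), replace = TRUE,
                               prob = phi_gen[k, ])
        }
        primary <- which.max(tabulate(z, nbins = K))
        theta_gen[d, ] <- theta
        z_gen[[d]] <- z
        words[[d]] <- w
        docs$doc_id[d] <- sprintf("%s-%05d", drug, i)
        docs$drug[d] <- drug
        docs$age_group[d] <- age_group
        docs$time_group[d] <- time_group
        docs$length[d] <- len
        docs$primary_topic[d] <- primary
        docs$rating_mu[d] <- 3 + config$rating_effects[primary] +
          config$stratum_rating_shift[[time_group]]
      }
    }
    structure(list(config = config, vocabulary = vocabulary,
                   phi_gen = phi_gen, theta_gen = theta_gen, z_gen = z_gen,
                   words = words, docs = docs),
              class = "synthetic_ground_truth")
  })
}

.decorations <- c("!", "!!", "?", ",", ";", ":", "...", "1", "42", "2019", "!?")

render_comment <- function(tokens, decorate_frac) {
  n <- length(tokens)
  if (decorate_frac > 0 && n > 0) {
    deco <- which(stats::runif(n) < decorate_frac)
    if (length(deco)) {
      tokens[deco] <- paste0(tokens[deco],
                             sample(.decorations, length(deco), replace = TRUE))
    }
    caps <- which(stats::runif(n) < 0.15)
    if (length(caps)) {
      tokens[caps] <- paste0(toupper(substring(tokens[caps], 1, 1)),
                             substring(tokens[caps], 2))
    }
  }
  seps <- c(sample(c(" ", "  "), max(n - 1, 0), replace = TRUE,
                   prob = c(0.95, 0.05)), "")
  paste0(tokens, seps, collapse = "")
}

sample_age_in <- function(group, n = 1) {
  rng <- switch(group, "19-44" = 19:44, "45-64" = 45:64, "65+" = 65:88)
  rng[sample.int(length(rng), n, replace = TRUE)]
}

.spam_markers <- c("check out www.cheap-pills.example for deals",
                   "best prices at pillsonline.com today",
                   "order now at http://ed-meds.example")

#' Render a synthetic ground truth into review records
#'
#' Joins each document's pseudo-word tokens into comment text (a configured
#' fraction of tokens decorated with punctuation, digits and capitalisation
#' so cleaning has work to do), populates review metadata, and computes each
#' record's 1-5 rating as round-half-up-then-clip of
#' `3 + rating_effects[primary topic] + stratum shift + Gaussian noise`.
#' Contaminant records (spam links, empty comments, under-age/missing-age
#' reviewers) are appended after the eligible documents; their counts are
#' drawn binomially from `contamination_rates` and recorded in the generator
#' log so filter tests have exact expected counts.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param config the same [synthetic_config()] used to generate `gt`.
#' @return list with `records` (one data-frame row per review, eligible rows
#'   first and in document order) and `generator_log` (eligible counts,
#'   per-rule injected counts, contaminant record ids).
#' @export
render_corpus <- function(gt, config = gt$config) {
  stopifnot(inherits(gt, "synthetic_ground_truth"))
  withr::with_seed(child_seed(config$seed, "render"), {
    vocab <- gt$vocabulary
    D <- nrow(gt$docs)
    noise <- if (config$rating_noise_sd > 0) {
      rnorm(D, 0, config$rating_noise_sd)
    } else {
      numeric(D)
    }
    comments <- vapply(seq_len(D), function(d) {
      render_comment(vocab[gt$words[[d]]], config$decorate_frac)
    }, character(1))
    rating <- as.integer(pmin(5, pmax(1, round_half_up(gt$docs$rating_mu + noise))))
    eligible <- data.frame(
      record_id = gt$docs$doc_id,
      drug = gt$docs$drug,
      source = "synthetic",
      comment = comments,
      side_effect_comment = "",
      age_years = vapply(gt$docs$age_group, sample_age_in, integer(1)),
      gender = sample(c("male", "female", "missing"), D, replace = TRUE,
                      prob = c(0.95, 0.02, 0.03)),
      time_on_med = gt$docs$time_group,
      rating = rating,
      post_date = as.character(as.Date("2003-01-01") +
                                 sample.int(6000, D, replace = TRUE)),
      reviewer_type = sample(c("patient", "caregiver", "missing"), D,
                             replace = TRUE, prob = c(0.91, 0.03, 0.06)),
      stringsAsFactors = FALSE
    )
    rules <- c("spam", "empty", "underage")
    injected <- do.call(rbind, lapply(names(config$n_docs_per_drug), function(drug) {
      data.frame(drug = drug, rule = rules,
                 count = vapply(rules, function(r) {
                   rbinom(1, config$n_docs_per_drug[[drug]],
                          config$contamination_rates[[r]])
                 }, integer(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(injected) <- NULL
    contaminants <- list()
    for (j in seq_len(nrow(injected))) {
      n <- injected$count[j]
      if (n == 0) next
      drug <- injected$drug[j]
      rule <- injected$rule[j]
      filler <- vapply(seq_len(n), function(i) {
        paste(vocab[sample.int(length(vocab), 8, replace = TRUE)],
              collapse = " ")
      }, character(1))
      comment <- switch(rule,
        spam = paste(filler, sample(.spam_markers, n, replace = TRUE)),
        empty = sample(c("", "   "), n, replace = TRUE),
        underage = filler)
      age <- switch(rule,
        spam = sample(19:80, n, replace = TRUE),
        empty = sample(19:80, n, replace = TRUE),
        underage = sample(c(NA_integer_, 13:18), n, replace = TRUE))
      contaminants[[length(contaminants) + 1]] <- data.frame(
        record_id = sprintf("%s-%s-%03d", drug, rule, seq_len(n)),
        drug = drug, source = "synthetic", comment = comment,
        side_effect_comment = "",
        age_years = as.integer(age),
        gender = sample(c("male", "female", "missing"), n, replace = TRUE,
                        prob = c(0.95, 0.02, 0.03)),
        time_on_med = sample(TIME_GROUPS, n, replace = TRUE),
        rating = sample(1:5, n, replace = TRUE),
        post_date = as.character(as.Date("2003-01-01") +
                                   sample.int(6000, n, replace = TRUE)),
        reviewer_type = "patient",
        stringsAsFactors = FALSE
      )
    }
    records <- rbind(eligible, do.call(rbind, contaminants))
    rownames(records) <- NULL
    log <- list(
      eligible = as.list(config$n_docs_per_drug),
      injected = injected,
      contaminant_ids = if (length(contaminants)) {
        do.call(rbind, lapply(seq_along(contaminants), function(i) {
          data.frame(record_id = contaminants[[i]]$record_id,
                     drug = contaminants[[i]]$drug[1],
                     rule = {
                       # recover rule from the id suffix
                       sub("^.*-([a-z]+)-[0-9]+$", "\\1",
                           contaminants[[i]]$record_id)
                     },
                     stringsAsFactors = FALSE)
        }))
      } else {
        data.frame(record_id = character(0), drug = character(0),
                   rule = character(0), stringsAsFactors = FALSE)
      }
    )
    list(records = records, generator_log = log)
  })
}

#' Write synthetic ground truth as a JSON sidecar
#'
#' @param gt a [generate_ground_truth()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "synthetic_ground_truth"))
  out <- list(
    vocabulary = gt$vocabulary,
    phi_gen = gt$phi_gen,
    theta_gen = gt$theta_gen,
    z_gen = gt$z_gen,
    words = gt$words,
    docs = gt$docs
  )
  jsonlite::write_json(out, path, digits = 12, auto_unbox = FALSE)
  invisible(path)
}
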