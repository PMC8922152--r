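# Latent Dirichlet allocation by collapsed Gibbs sampling, density-based
# selection of the number of topics, top-word extraction, and per-review
# primary-topic assignment.

#' Topic model hyperparameters and sampler schedule
#'
#' `alpha = 50/K` and `beta = 0.1` follow the long-standing collapsed-Gibbs
#' convention for symmetric priors. The default schedule (2000 sweeps, 500
#' burn-in, thinning lag 10) averages ~150 retained samples into the
#' posterior-mean `phi` and `theta`.
#'
#' @param K number of topics (>= 1).
#' @param alpha symmetric document-topic concentration; default `50/K`.
#' @param beta symmetric topic-word concentration.
#' @param n_iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging (`< n_iterations`).
#' @param sample_lag thinning interval for averaged estimates (>= 1).
#' @param seed integer seed; fits are deterministic given (dtm, params).
#' @return object of class `topic_params`.
#' @export
topic_params <- function(K = 5, alpha = NULL, beta = 0.1,
                         n_iterations = 2000, burn_in = 500,
                         sample_lag = 10, seed = 1L) {
  assert_that(K >= 1, "K must be >= 1")
  alpha_auto <- is.null(alpha)
  if (alpha_auto) alpha <- 50 / K
  assert_that(alpha > 0 && beta > 0, "alpha and beta must be > 0")
  assert_that(burn_in < n_iterations, "burn_in must be < n_iterations")
  assert_that(sample_lag >= 1, "sample_lag must be >= 1")
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 alpha_auto = alpha_auto,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 sample_lag = as.integer(sample_lag),
                 seed = as.integer(seed)),
            class = "topic_params")
}

# flatten a dtm into per-token (doc, word) indices, 0-based, ordered by
# (document, term index) so token order is reproducible
dtm_tokens <- function(dtm) {
  trip <- Matrix::summary(dtm$counts)
  ord <- order(trip$i, trip$j, method = "radix")
  trip <- trip[ord, , drop = FALSE]
  reps <- as.integer(trip$x)
  list(doc = rep(trip$i - 1L, reps), word = rep(trip$j - 1L, reps))
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Runs the collapsed sampler (topic of each token resampled from
#' `(n_dk + alpha)(n_kv + beta)/(n_k + V beta)` with the token excluded from
#' all counts; topics initialized uniformly at random from the seed).
#' `phi` and `theta` are posterior means averaged over post-burn-in thinned
#' sweeps; `z` and the count caches come from the final sweep, matching the
#' token-count reading of per-review primary topics.
#'
#' @param dtm a `dtm` from [build_dtm()] (no empty documents).
#' @param params a [topic_params()].
#' @param track_z_marginal also accumulate per-token topic frequencies over
#'   retained sweeps (for posterior diagnostics on small corpora).
#' @return object of class `lda_model` with `phi` (K x V), `theta` (D x K),
#'   `z`, `n_dk`, `n_kv`, `n_k`, a per-sweep log-likelihood trace, and the
#'   vocabulary/document bookkeeping of `dtm`.
#' @export
fit_lda <- function(dtm, params = topic_params(), track_z_marginal = FALSE) {
  stopifnot(inherits(dtm, "dtm"), inherits(params, "topic_params"))
  D <- nrow(dtm$counts)
  V <- ncol(dtm$counts)
  assert_that(D >= 1 && V >= 1 && sum(dtm$N_d) >= 1, "empty document-term matrix")
  assert_that(all(dtm$N_d > 0), "dtm contains empty documents")
  total_tokens <- sum(dtm$N_d)
  if (params$K > total_tokens) {
    warning(sprintf("K = %d exceeds the %d tokens in the corpus; the model is degenerate",
                    params$K, total_tokens), call. = FALSE)
  }
  toks <- dtm_tokens(dtm)
  fit <- lda_gibbs_cpp(toks$word, toks$doc, D, V, params$K,
                       params$alpha, params$beta, params$n_iterations,
                       params$burn_in, params$sample_lag, params$seed,
                       track_z_marginal)
  phi <- fit$phi
  theta <- fit$theta
  dimnames(phi) <- list(NULL, colnames(dtm$counts))
  dimnames(theta) <- list(dtm$doc_ids, NULL)
  n_kv <- fit$n_kv
  colnames(n_kv) <- colnames(dtm$counts)
  n_dk <- fit$n_dk
  rownames(n_dk) <- dtm$doc_ids
  structure(list(
    params = params,
    z = fit$z + 1L,
    token_doc = toks$doc + 1L,
    token_word = toks$word + 1L,
    n_dk = n_dk, n_kv = n_kv, n_k = fit$n_k,
    phi = phi, theta = theta,
    loglik = fit$loglik,
    n_samples = fit$n_samples,
    z_marginal = if (track_z_marginal) fit$z_marginal else NULL,
    z_pair = if (track_z_marginal) fit$z_pair else NULL,
    doc_ids = dtm$doc_ids,
    dropped_doc_ids = dtm$dropped_doc_ids,
    vocabulary = dtm$vocabulary
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("LDA model: K = %d topics, %d documents, %d terms, %d tokens\n",
              x$params$K, nrow(x$theta), ncol(x$phi), length(x$z)))
  cat(sprintf("  alpha = %.3f, beta = %.3f, %d sweeps (%d burn-in, lag %d), %d averaged samples\n",
              x$params$alpha, x$params$beta, x$params$n_iterations,
              x$params$burn_in, x$params$sample_lag, x$n_samples))
  invisible(x)
}

#' Held-in log likelihood of a fitted model
#'
#' Sum over observed tokens of `log(sum_k theta[d,k] phi[k,w])`; finite and
#' negative for any non-degenerate model.
#'
#' @param model an `lda_model`.
#' @param dtm the `dtm` the model was fitted on (same vocabulary).
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(model, dtm) {
  stopifnot(inherits(model, "lda_model"), inherits(dtm, "dtm"))
  assert_that(identical(colnames(dtm$counts), colnames(model$phi)),
              "vocabulary mismatch between model and dtm")
  assert_that(identical(dtm$doc_ids, model$doc_ids),
              "document mismatch between model and dtm")
  mix <- model$theta %*% model$phi  # D x V token probabilities
  trip <- Matrix::summary(dtm$counts)
  sum(trip$x * log(mix[cbind(trip$i, trip$j)]))
}

#' Mean pairwise cosine similarity of topic-word distributions
#'
#' The density criterion for choosing the number of topics: the mean cosine
#' similarity over all unordered pairs of rows of `phi`. Lies in `[0, 1]`
#' for non-negative `phi`; lower values mean more distinct topics.
#'
#' @param phi K x V row-stochastic matrix (K >= 2).
#' @return scalar in `[0, 1]`.
#' @export
topic_density <- function(phi) {
  K <- nrow(phi)
  assert_that(!is.null(K) && K >= 2, "topic_density needs at least 2 topics")
  norms <- sqrt(rowSums(phi^2))
  sims <- (phi / norms) %*% t(phi / norms)
  mean(sims[upper.tri(sims)])
}

#' Select the number of topics by minimizing topic density
#'
#' Fits one model per candidate K (same seed and schedule, `alpha = 50/K`
#' unless fixed in the template) and picks the K whose fitted `phi` has the
#' lowest mean pairwise cosine similarity. The full score table is returned
#' for plotting/inspection.
#'
#' @param dtm a `dtm`.
#' @param candidates integer vector of K values, all >= 2.
#' @param params template [topic_params()] supplying priors, schedule and
#'   seed.
#' @return list with `scores` (data frame K, density, loglik) and `chosen_K`.
#' @export
select_num_topics <- function(dtm, candidates, params = topic_params()) {
  assert_that(length(candidates) >= 1, "empty candidate list")
  assert_that(all(candidates >= 2), "all candidate K must be >= 2")
  candidates <- as.integer(candidates)
  scores <- data.frame(K = candidates, density = NA_real_, loglik = NA_real_)
  for (i in seq_along(candidates)) {
    K <- candidates[i]
    p <- topic_params(K = K,
                      alpha = if (params$alpha_auto) NULL else params$alpha,
                      beta = params$beta,
                      n_iterations = params$n_iterations,
                      burn_in = params$burn_in,
                      sample_lag = params$sample_lag,
                      seed = params$seed)
    fit <- fit_lda(dtm, p)
    scores$density[i] <- topic_density(fit$phi)
    scores$loglik[i] <- log_likelihood(fit, dtm)
  }
  list(scores = scores, chosen_K = scores$K[which.min(scores$density)])
}

#' Per-document primary topics
#'
#' The primary topic of a review is the topic assigned to the largest number
#' of its tokens in the final retained Gibbs sample (`method = "tokens"`,
#' the default) or the argmax of the averaged `theta` (`method = "theta"`).
#' Ties break to the lowest topic index. Documents dropped during DTM
#' construction are reported with a missing primary topic.
#'
#' @param model an `lda_model`.
#' @param method `"tokens"` or `"theta"`.
#' @return data frame with `doc_id`, `primary_topic` (1-based, NA for
#'   dropped documents) and `n_tokens`.
#' @export
primary_topics <- function(model, method = c("tokens", "theta")) {
  stopifnot(inherits(model, "lda_model"))
  method <- match.arg(method)
  scores <- if (method == "tokens") model$n_dk else model$theta
  primary <- apply(scores, 1, which.max)  # which.max ties -> lowest index
  out <- data.frame(doc_id = model$doc_ids,
                    primary_topic = as.integer(primary),
                    n_tokens = as.integer(rowSums(model$n_dk)),
                    stringsAsFactors = FALSE)
  if (length(model$dropped_doc_ids)) {
    out <- rbind(out, data.frame(doc_id = model$dropped_doc_ids,
                                 primary_topic = NA_integer_,
                                 n_tokens = 0L, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Top terms of a topic
#'
#' @param model an `lda_model`.
#' @param topic 1-based topic index.
#' @param n number of terms (default 30, the conventional list length for
#'   manual topic naming); returns `min(n, V)` terms.
#' @return character vector of terms, by descending `phi`, ties in
#'   vocabulary order.
#' @export
top_words <- function(model, topic, n = 30) {
  stopifnot(inherits(model, "lda_model"))
  assert_that(topic >= 1 && topic <= model$params$K,
              "topic index %s out of range 1..%d", topic, model$params$K)
  p <- model$phi[topic, ]
  ord <- order(-p, seq_along(p), method = "radix")
  colnames(model$phi)[ord][seq_len(min(n, length(p)))]
}

#' Align fitted topics to reference topics
#'
#' Finds the topic permutation maximizing the mean cosine similarity between
#' matched rows of `phi_fit` and `phi_ref` by exhaustive search over
#' permutations (K <= 8), i.e. the optimal assignment for these sizes.
#'
#' @param phi_fit,phi_ref K x V row-stochastic matrices over the same
#'   vocabulary (columns aligned).
#' @return list with `perm` (fitted topic matched to each reference topic),
#'   `per_topic` cosines and their `mean_cosine`.
#' @export
align_topics <- function(phi_fit, phi_ref) {
  K <- nrow(phi_ref)
  assert_that(nrow(phi_fit) == K, "topic counts differ")
  assert_that(ncol(phi_fit) == ncol(phi_ref), "vocabulary sizes differ")
  assert_that(K <= 8, "exhaustive alignment supports K <= 8")
  sim <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) sim[i, j] <- cosine_sim(phi_fit[i, ], phi_ref[j, ])
  }
  perms <- permutations_of(K)
  best <- NULL
  best_val <- -Inf
  for (p in perms) {
    val <- mean(sim[cbind(p, seq_len(K))])
    if (val > best_val) {
      best_val <- val
      best <- p
    }
  }
  list(perm = best, per_topic = sim[cbind(best, seq_len(K))],
       mean_cosine = best_val)
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

#' Box-style topic report
#'
#' For each topic: its top-`n_words` terms and the count and percentage of
#' documents having it as primary topic (shares over documents with a
#' defined primary topic).
#'
#' @param model an `lda_model`.
#' @param assignments result of [primary_topics()] (recomputed if omitted).
#' @param n_words terms per topic.
#' @return data frame with topic, n, share_pct, words (comma-joined).
#' @export
topic_report <- function(model, assignments = primary_topics(model),
                         n_words = 30) {
  assigned <- assignments$primary_topic[!is.na(assignments$primary_topic)]
  N <- length(assigned)
  counts <- tabulate(assigned, nbins = model$params$K)
  data.frame(
    topic = seq_len(model$params$K),
    n = counts,
    share_pct = round_half_up(100 * counts / N, 1),
    words = vapply(seq_len(model$params$K), function(k) {
      paste(top_words(model, k, n_words), collapse = ", ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
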