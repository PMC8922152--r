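# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately brute-force and separate from the package
# code paths it checks.

# block-diagonal topic-word concentrations: each topic owns ~V/K terms
block_beta <- function(K, V, high = 5, low = 0.05) {
  b <- matrix(low, K, V)
  sz <- ceiling(V / K)
  for (k in seq_len(K)) b[k, ((k - 1) * sz + 1):min(V, k * sz)] <- high
  b
}

# the study conditions used for topic-recovery and K-selection checks:
# well-separated topics (block-structured phi), moderately mixed documents
separated_corpus_config <- function(seed, n_docs = 400, K = 3, V = 50,
                                    doc_length = 100) {
  synthetic_config(
    n_docs_per_drug = c(drugx = n_docs), K_gen = K, V_gen = V,
    alpha_gen = rep(0.5, K), beta_gen = block_beta(K, V),
    doc_length_mean = doc_length, rating_effects = rep(0, K),
    contamination_rates = c(spam = 0, empty = 0, underage = 0),
    seed = seed)
}

# exact collapsed LDA posterior by enumeration of all K^N assignment vectors
# (token order must match the sampler's: sorted by document, then term index)
enumerate_collapsed <- function(tok_doc, tok_word, D, V, K, alpha, beta) {
  N <- length(tok_doc)
  logp_of <- function(z) {
    n_dk <- matrix(0, D, K)
    n_kv <- matrix(0, K, V)
    for (i in seq_len(N)) {
      n_dk[tok_doc[i], z[i]] <- n_dk[tok_doc[i], z[i]] + 1
      n_kv[z[i], tok_word[i]] <- n_kv[z[i], tok_word[i]] + 1
    }
    lp <- 0
    for (d in seq_len(D)) {
      lp <- lp + sum(lgamma(n_dk[d, ] + alpha)) -
        lgamma(sum(n_dk[d, ]) + K * alpha)
    }
    for (k in seq_len(K)) {
      lp <- lp + sum(lgamma(n_kv[k, ] + beta)) -
        lgamma(sum(n_kv[k, ]) + V * beta)
    }
    lp
  }
  zs <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  lp <- apply(zs, 1, logp_of)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pair <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) pair[i, j] <- sum(p[zs[, i] == zs[, j]])
  }
  marginal <- vapply(seq_len(N), function(i) {
    vapply(seq_len(K), function(k) sum(p[zs[, i] == k]), numeric(1))
  }, numeric(K))
  list(probs = p, assignments = zs, pair = pair, marginal = t(marginal))
}

# all r x c contingency tables with the given margins (small tables only)
enumerate_tables <- function(row_margins, col_margins) {
  r <- length(row_margins)
  fill <- function(rows_left, cols_remaining) {
    if (length(rows_left) == 1) {
      if (all(cols_remaining >= 0) && sum(cols_remaining) == rows_left) {
        return(list(matrix(cols_remaining, nrow = 1)))
      }
      return(list())
    }
    n <- rows_left[1]
    c_ <- length(cols_remaining)
    out <- list()
    # enumerate compositions of n over c_ cells bounded by cols_remaining
    comps <- compositions_bounded(n, cols_remaining)
    for (row in comps) {
      for (rest in fill(rows_left[-1], cols_remaining - row)) {
        out[[length(out) + 1]] <- rbind(row, rest, deparse.level = 0)
      }
    }
    out
  }
  fill(row_margins, col_margins)
}

compositions_bounded <- function(n, bounds) {
  if (length(bounds) == 1) {
    if (n <= bounds) return(list(n))
    return(list())
  }
  out <- list()
  for (x in 0:min(n, bounds[1])) {
    for (rest in compositions_bounded(n - x, bounds[-1])) {
      out[[length(out) + 1]] <- c(x, rest)
    }
  }
  out
}

# multivariate hypergeometric probability of a table given its margins
table_log_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# exact two-sided Fisher p for any small table: sum the probabilities of all
# tables (same margins) that are no more probable than the observed one
fisher_exact_enum <- function(tab) {
  tabs <- enumerate_tables(rowSums(tab), colSums(tab))
  lp <- vapply(tabs, table_log_prob, numeric(1))
  obs <- table_log_prob(tab)
  sum(exp(lp[lp <= obs + 1e-9]))
}

# hand Welch t statistic
welch_t_oracle <- function(a, b) {
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  (mean(a) - mean(b)) / se
}

# a small hand-built review record table
make_records <- function(comment, age = 50, drug = "drugx", rating = 3,
                         id = NULL) {
  n <- length(comment)
  data.frame(
    record_id = id %||% sprintf("r%03d", seq_len(n)),
    drug = rep_len(drug, n), source = "synthetic", comment = comment,
    side_effect_comment = "", age_years = as.integer(rep_len(age, n)),
    gender = "male", time_on_med = "lt_1_month",
    rating = as.integer(rep_len(rating, n)), post_date = "2015-01-01",
    reviewer_type = "patient", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
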