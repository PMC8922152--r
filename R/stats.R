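# Downstream statistical layer: stratified topic-share tables, satisfaction
# rating summaries, and the Fisher / Welch t / one-way ANOVA tests, all at
# the conventional alpha of .05 with no multiple-testing correction (each
# test is reported per comparison, as in the report tables this mirrors).

ALPHA_LEVEL <- 0.05

stat_test_result <- function(method, statistic, df, p_value, n,
                             seed = NA_integer_, mc_se = NA_real_,
                             estimate = NA_real_) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, n = n,
                 significant = is.finite(p_value) && p_value < ALPHA_LEVEL,
                 seed = seed, mc_se = mc_se, estimate = estimate),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g%s\n", x$method,
              if (is.na(x$statistic)) "NA" else format(x$statistic, digits = 5),
              paste(format(x$df, digits = 5), collapse = ", "),
              x$p_value,
              if (x$significant) " (significant at .05)" else ""))
  invisible(x)
}

#' Percentage share, rounded as printed
#'
#' `100 * n / total`, rounded half-up to one decimal — the convention used
#' in all of the package's share tables (e.g. 94 of 461 -> 20.4).
#'
#' @param n count(s).
#' @param total denominator.
#' @return numeric percentage(s), one decimal.
#' @export
share_percent <- function(n, total) {
  assert_that(all(total > 0), "share_percent needs a positive denominator")
  round_half_up(100 * n / total, 1)
}

#' Stratified primary-topic share table
#'
#' Cross-tabulates primary topics against a stratum label (age group, time
#' on medication, or drug), with counts, one-decimal percentages per stratum
#' column, and margins. Records missing either the primary topic or the
#' stratum are excluded from the relevant denominators.
#'
#' @param assignments data frame with `doc_id` and `primary_topic`
#'   (see [primary_topics()]).
#' @param strata character vector of stratum labels aligned to
#'   `assignments` rows (NA allowed), or a data frame with `doc_id` and
#'   `stratum` merged by id.
#' @param K number of topics (defaults to the maximum observed).
#' @return object of class `share_table`: `counts` and `pct` matrices
#'   (topics x strata plus an `(all)` margin column), and `margins` (column
#'   totals).
#' @export
share_table <- function(assignments, strata, K = NULL) {
  assert_that(nrow(assignments) > 0, "no assignments")
  if (is.data.frame(strata)) {
    idx <- match(assignments$doc_id, strata$doc_id)
    strata <- strata$stratum[idx]
  }
  assert_that(length(strata) == nrow(assignments),
              "strata must align with assignments")
  topic <- assignments$primary_topic
  keep <- !is.na(topic) & !is.na(strata) & strata != "missing"
  topic <- topic[keep]
  strata <- as.character(strata[keep])
  if (is.null(K)) K <- max(topic)
  levels <- sort(unique(strata))
  counts <- matrix(0L, nrow = K, ncol = length(levels) + 1,
                   dimnames = list(paste0("topic", seq_len(K)),
                                   c(levels, "(all)")))
  for (s in seq_along(levels)) {
    counts[, s] <- tabulate(topic[strata == levels[s]], nbins = K)
  }
  counts[, "(all)"] <- tabulate(topic, nbins = K)
  margins <- setNames(as.integer(colSums(counts)), colnames(counts))
  pct <- counts
  for (j in seq_len(ncol(counts))) {
    pct[, j] <- if (margins[j] > 0) share_percent(counts[, j], margins[j]) else NA_real_
  }
  structure(list(counts = counts, pct = pct, margins = margins),
            class = "share_table")
}

#' @export
print.share_table <- function(x, ...) {
  cat("Primary-topic shares (n, %):\n")
  m <- matrix(sprintf("%d (%.1f)", x$counts, x$pct), nrow = nrow(x$counts),
              dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  invisible(x)
}

#' Fisher exact test on a contingency table
#'
#' For 2 x 2 tables: the exact two-sided p-value by hypergeometric
#' enumeration (tables with probability no larger than the observed one are
#' summed). For larger tables: a Monte-Carlo p-value over `mc_reps` tables
#' drawn with fixed margins from the given seed, reported together with its
#' binomial standard error.
#'
#' @param tab r x c matrix of non-negative integer counts, all margins
#'   positive.
#' @param mc_reps Monte-Carlo replicates for tables larger than 2 x 2.
#' @param seed seed for the Monte-Carlo draw.
#' @return a `stat_test_result` (method `"fisher_exact"`).
#' @export
fisher_exact <- function(tab, mc_reps = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  assert_that(all(tab >= 0) && all(tab == round(tab)),
              "table cells must be non-negative integers")
  assert_that(nrow(tab) >= 2 && ncol(tab) >= 2, "need at least a 2x2 table")
  zr <- which(rowSums(tab) == 0)
  zc <- which(colSums(tab) == 0)
  if (length(zr)) stopf("zero margin in row %s", paste(zr, collapse = ", "))
  if (length(zc)) stopf("zero margin in column %s", paste(zc, collapse = ", "))
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    ft <- stats::fisher.test(tab)
    stat_test_result("fisher_exact", statistic = unname(ft$estimate),
                     df = NA_real_, p_value = ft$p.value,
                     n = sum(tab), estimate = unname(ft$estimate))
  } else {
    mc_reps <- as.integer(mc_reps)
    ft <- withr::with_seed(seed,
      stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_reps))
    p <- ft$p.value
    stat_test_result("fisher_exact", statistic = NA_real_, df = NA_real_,
                     p_value = p, n = sum(tab), seed = as.integer(seed),
                     mc_se = sqrt(p * (1 - p) / mc_reps))
  }
}

#' Welch two-sample t test
#'
#' Two-sided, unequal-variance t test with Welch-Satterthwaite degrees of
#' freedom (group variances in review-rating data are visibly unequal, so
#' the pooled variant is not the default).
#'
#' @param group_a,group_b numeric rating samples, each of size >= 2, with
#'   nonzero variance in at least one group.
#' @param var_equal use the pooled-variance t test instead.
#' @return a `stat_test_result` (method `"welch_t"` or `"pooled_t"`).
#' @export
welch_t <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs n >= 2")
  assert_that(stats::var(group_a) > 0 || stats::var(group_b) > 0,
              "degenerate groups: both have zero variance")
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  stat_test_result(if (var_equal) "pooled_t" else "welch_t",
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n = c(length(group_a), length(group_b)),
                   estimate = unname(diff(rev(tt$estimate))))
}

#' One-way analysis of variance
#'
#' Classic fixed-effects ANOVA: F with (g - 1, N - g) degrees of freedom.
#'
#' @param groups list of >= 2 numeric rating samples, none empty, total
#'   n > number of groups.
#' @return a `stat_test_result` (method `"one_way_anova"`).
#' @export
one_way_anova <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  empty <- which(lengths(groups) == 0)
  if (length(empty)) stopf("empty group(s): %s", paste(empty, collapse = ", "))
  g <- length(groups)
  N <- sum(lengths(groups))
  assert_that(N > g, "total n must exceed the number of groups")
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_len(g), lengths(groups)))
  res <- stats::oneway.test(y ~ f, var.equal = TRUE)
  stat_test_result("one_way_anova", statistic = unname(res$statistic),
                   df = unname(res$parameter), p_value = res$p.value,
                   n = lengths(groups))
}

#' Rating summary by primary topic and stratum
#'
#' n, mean and sample SD of the 1-5 satisfaction rating for every
#' primary-topic x stratum cell, plus per-topic overall rows, per-stratum
#' total rows and a grand total; SD is reported missing when n < 2. Each
#' topic row carries the one-way ANOVA p-value comparing its ratings across
#' strata (NA when fewer than two strata have data).
#'
#' @param topics integer primary topics (NA allowed).
#' @param ratings integer ratings 1..5 (NA excluded and counted).
#' @param strata stratum labels aligned with `topics`.
#' @return object of class `rating_summary`: `cells` long data frame
#'   (topic, stratum incl. `"overall"`, n, mean, sd), `anova` data frame
#'   (topic incl. `"total"`, statistic, p_value), `n_missing_rating`.
#' @export
rating_summary <- function(topics, ratings, strata) {
  assert_that(length(topics) == length(ratings) &&
                length(ratings) == length(strata),
              "topics, ratings and strata must have equal length")
  ok_rating <- !is.na(ratings)
  assert_that(all(ratings[ok_rating] %in% 1:5), "ratings must be integers 1..5")
  n_missing <- sum(!ok_rating)
  keep <- ok_rating & !is.na(topics) & !is.na(strata) & strata != "missing"
  topics <- topics[keep]
  ratings <- ratings[keep]
  strata <- as.character(strata[keep])
  levels_t <- sort(unique(topics))
  levels_s <- sort(unique(strata))
  rows <- list()
  for (tp in c(levels_t, NA)) {  # NA = total row over all topics
    sel_t <- if (is.na(tp)) rep(TRUE, length(topics)) else topics == tp
    label_t <- if (is.na(tp)) "total" else as.character(tp)
    for (st in c("overall", levels_s)) {
      sel <- sel_t & (st == "overall" | strata == st)
      x <- ratings[sel]
      rows[[length(rows) + 1]] <- data.frame(
        topic = label_t, stratum = st, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  anova <- do.call(rbind, lapply(c(levels_t, NA), function(tp) {
    sel_t <- if (is.na(tp)) rep(TRUE, length(topics)) else topics == tp
    label_t <- if (is.na(tp)) "total" else as.character(tp)
    grp <- split(ratings[sel_t], strata[sel_t])
    grp <- grp[lengths(grp) > 0]
    res <- if (length(grp) >= 2 && sum(lengths(grp)) > length(grp)) {
      tryCatch(one_way_anova(grp), error = function(e) NULL)
    }
    data.frame(topic = label_t,
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, anova = anova,
                 n_missing_rating = n_missing),
            class = "rating_summary")
}

#' @export
print.rating_summary <- function(x, ...) {
  cat("Rating summary (mean (SD), n) by primary topic and stratum:\n")
  print(x$cells, row.names = FALSE)
  cat("ANOVA across strata per topic:\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Serialize a stat test result as a plain list (for JSON output)
#' @param x a `stat_test_result`.
#' @return named list.
#' @export
as_list.stat_test_result <- function(x) {
  list(method = x$method, statistic = x$statistic, df = x$df,
       p_value = x$p_value, n = x$n, significant = x$significant,
       seed = x$seed, mc_se = x$mc_se, estimate = x$estimate)
}
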