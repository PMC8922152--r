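# End-to-end orchestration: acquire (synthetic or files) -> filter ->
# preprocess -> one LDA model per drug -> primary topics -> stratified
# shares, rating summaries and tests -> report bundle + run manifest.
# Every stage draws its randomness from a child seed derived from the
# single global seed, so stages are individually re-runnable and two runs
# from one config produce byte-identical outputs.

#' Pipeline configuration
#'
#' Exactly one of `input` and `synthetic` must be active. The default fits
#' a fixed K = 5 topics per drug; supplying `k_candidates` switches on
#' density-based selection of K per drug.
#'
#' @param input `NULL`, or `list(path =, format = "csv"|"jsonl")` pointing
#'   at a review table with a `drug` column.
#' @param synthetic `NULL`, or a [synthetic_config()]; its seed is re-derived
#'   from the pipeline's global `seed`.
#' @param preprocess a [preprocess_config()].
#' @param lda a [topic_params()] template (K used directly when
#'   `k_candidates` is `NULL`).
#' @param k_candidates optional integer vector of candidate topic counts.
#' @param fisher_mc_reps Monte-Carlo replicates for the cross-drug Fisher
#'   test on tables larger than 2 x 2.
#' @param rescue_side_effect_comment see [filter_reviews()].
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            synthetic = synthetic_config(),
                            preprocess = preprocess_config(),
                            lda = topic_params(),
                            k_candidates = NULL,
                            fisher_mc_reps = 1e4,
                            rescue_side_effect_comment = FALSE,
                            seed = 1L) {
  assert_that(xor(is.null(input), is.null(synthetic)),
              "exactly one of input and synthetic must be set")
  if (!is.null(input)) {
    assert_that(is.list(input) && !is.null(input$path),
                "input must be list(path =, format =)")
    input$format <- input$format %||% "csv"
  }
  stopifnot(is.null(synthetic) || inherits(synthetic, "synthetic_config"))
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(lda, "topic_params"))
  if (!is.null(k_candidates)) {
    assert_that(all(k_candidates >= 2), "k_candidates must all be >= 2")
  }
  structure(list(input = input, synthetic = synthetic,
                 preprocess = preprocess, lda = lda,
                 k_candidates = k_candidates,
                 fisher_mc_reps = as.integer(fisher_mc_reps),
                 rescue_side_effect_comment = isTRUE(rescue_side_effect_comment),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

age_group_of <- function(age_years) {
  out <- rep(NA_character_, length(age_years))
  out[!is.na(age_years) & age_years >= 19 & age_years <= 44] <- "19-44"
  out[!is.na(age_years) & age_years >= 45 & age_years <= 64] <- "45-64"
  out[!is.na(age_years) & age_years >= 65] <- "65+"
  out
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12, na = "null")
  invisible(path)
}

share_table_long <- function(st) {
  strata <- colnames(st$counts)
  do.call(rbind, lapply(seq_along(strata), function(j) {
    data.frame(stratum = strata[j], topic = seq_len(nrow(st$counts)),
               n = st$counts[, j], pct = st$pct[, j],
               margin = unname(st$margins[j]), stringsAsFactors = FALSE)
  }))
}

write_topic_box <- function(report, drug, n_assigned, path) {
  lines <- c(sprintf("## %s (N=%d)", drug, n_assigned), "")
  for (i in seq_len(nrow(report))) {
    lines <- c(lines,
               sprintf("- **Topic %d (n=%d, %.1f%%)**", report$topic[i],
                       report$n[i], report$share_pct[i]),
               sprintf("  Words: %s", report$words[i]), "")
  }
  writeLines(lines, path)
  invisible(path)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[pmrtopics] %s", sprintf(fmt, ...)))
}

#' Run the full review-topic pipeline
#'
#' Executes acquire -> filter -> preprocess -> per-drug LDA (fixed K or
#' density-based selection) -> primary topics -> share tables, rating
#' summaries and tests, writing a report bundle (CSV/JSON/MTX/Markdown)
#' and a manifest with per-file checksums into `out_dir`. Fully
#' deterministic given the configuration; on any stage error the partially
#' written output directory is removed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must not exist or be empty).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  assert_that(!dir.exists(out_dir) || !length(dir(out_dir)),
              "out_dir exists and is not empty: %s", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))
  stages <- character(0)
  run_stage <- function(name, expr) {
    pipeline_log("stage %s", name)
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  records <- run_stage("acquire", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      syn$seed <- child_seed(config$seed, "synthetic")
      gt <- generate_ground_truth(syn)
      corpus <- render_corpus(gt, syn)
      write_reviews(corpus$records, file.path(out_dir, "corpus.csv"), "csv")
      write_ground_truth(gt, file.path(out_dir, "ground_truth.json"))
      write_json_file(corpus$generator_log,
                      file.path(out_dir, "generator_log.json"))
      corpus$records
    } else {
      read_reviews(config$input$path, config$input$format)
    }
  })

  filtered <- run_stage("filter", {
    fl <- filter_reviews(records, config$rescue_side_effect_comment)
    write_reviews(fl$records, file.path(out_dir, "filtered.csv"), "csv")
    write_filter_log(fl$log, file.path(out_dir, "filter_log.json"))
    assert_that(nrow(fl$records) > 0, "no records survive the eligibility filters")
    fl$records
  })

  drugs <- unique(filtered$drug)
  per_drug <- list()
  for (drug in drugs) {
    sub <- filtered[filtered$drug == drug, , drop = FALSE]
    drug_dir <- file.path(out_dir, drug)
    dir.create(drug_dir, showWarnings = FALSE)

    dtm <- run_stage(paste0("preprocess-", drug), {
      d <- preprocess_corpus(sub, config$preprocess)
      write_dtm(d, file.path(drug_dir, "dtm"))
      d
    })

    model <- run_stage(paste0("lda-", drug), {
      seed_k <- child_seed(config$seed, paste0("lda-", drug))
      template <- topic_params(
        K = config$lda$K,
        alpha = if (config$lda$alpha_auto) NULL else config$lda$alpha,
        beta = config$lda$beta,
        n_iterations = config$lda$n_iterations,
        burn_in = config$lda$burn_in,
        sample_lag = config$lda$sample_lag,
        seed = seed_k)
      if (!is.null(config$k_candidates)) {
        sel <- select_num_topics(dtm, config$k_candidates, template)
        utils::write.csv(sel$scores, file.path(drug_dir, "k_selection.csv"),
                         row.names = FALSE)
        template <- topic_params(
          K = sel$chosen_K,
          alpha = if (template$alpha_auto) NULL else template$alpha,
          beta = template$beta, n_iterations = template$n_iterations,
          burn_in = template$burn_in, sample_lag = template$sample_lag,
          seed = seed_k)
      }
      fit <- fit_lda(dtm, template)
      utils::write.csv(as.data.frame(fit$phi),
                       file.path(drug_dir, "phi.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(fit$theta),
                       file.path(drug_dir, "theta.csv"), row.names = FALSE)
      write_json_file(list(K = fit$params$K, alpha = fit$params$alpha,
                           beta = fit$params$beta,
                           n_iterations = fit$params$n_iterations,
                           burn_in = fit$params$burn_in,
                           sample_lag = fit$params$sample_lag,
                           seed = fit$params$seed,
                           loglik_final = fit$loglik[length(fit$loglik)]),
                      file.path(drug_dir, "lda_params.json"))
      fit
    })

    per_drug[[drug]] <- run_stage(paste0("report-", drug), {
      assignments <- primary_topics(model)
      meta_idx <- match(assignments$doc_id, sub$record_id)
      assignments$age_group <- age_group_of(sub$age_years[meta_idx])
      assignments$time_on_med <- sub$time_on_med[meta_idx]
      assignments$rating <- sub$rating[meta_idx]
      utils::write.csv(assignments, file.path(drug_dir, "assignments.csv"),
                       row.names = FALSE)
      report <- topic_report(model, assignments)
      utils::write.csv(report, file.path(drug_dir, "topics.csv"),
                       row.names = FALSE)
      write_topic_box(report, drug, sum(!is.na(assignments$primary_topic)),
                      file.path(drug_dir, "topics.md"))
      for (strat in c("age_group", "time_on_med")) {
        st <- share_table(assignments, assignments[[strat]],
                          K = model$params$K)
        utils::write.csv(share_table_long(st),
                         file.path(drug_dir, paste0("shares_by_", strat, ".csv")),
                         row.names = FALSE)
        rs <- rating_summary(assignments$primary_topic, assignments$rating,
                             assignments[[strat]])
        utils::write.csv(rs$cells,
                         file.path(drug_dir, paste0("ratings_by_", strat, ".csv")),
                         row.names = FALSE)
        utils::write.csv(rs$anova,
                         file.path(drug_dir, paste0("ratings_by_", strat, "_anova.csv")),
                         row.names = FALSE)
      }
      assignments
    })
  }

  if (length(drugs) >= 2) {
    run_stage("cross-drug", {
      a <- per_drug[[drugs[1]]]
      b <- per_drug[[drugs[2]]]
      K <- max(c(a$primary_topic, b$primary_topic), na.rm = TRUE)
      tab <- rbind(tabulate(a$primary_topic[!is.na(a$primary_topic)], K),
                   tabulate(b$primary_topic[!is.na(b$primary_topic)], K))
      rownames(tab) <- drugs[1:2]
      tests <- list(
        topic_distribution_fisher = as_list.stat_test_result(
          fisher_exact(tab, mc_reps = config$fisher_mc_reps,
                       seed = child_seed(config$seed, "fisher"))),
        overall_rating_welch_t = as_list.stat_test_result(
          welch_t(a$rating, b$rating)),
        drugs = drugs[1:2],
        topic_counts = tab
      )
      write_json_file(tests, file.path(out_dir, "cross_drug_tests.json"))
      NULL
    })
  }

  manifest <- run_stage("manifest", {
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.json"))
    checksums <- as.list(unname(tools::md5sum(file.path(out_dir, files))))
    names(checksums) <- files
    m <- list(
      package_version = as.character(utils::packageVersion("pmrtopics")),
      config_hash = config_hash(config),
      seed = config$seed,
      stages = stages,
      drugs = drugs,
      checksums = checksums
    )
    write_json_file(m, file.path(out_dir, "manifest.json"))
    m
  })

  ok <- TRUE
  invisible(manifest)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization of the configuration; identical
#' configurations hash identically, and the run manifest records the hash.
#'
#' @param config a [pipeline_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass_deep(config),
                                           auto_unbox = TRUE, digits = 12,
                                           na = "null")), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.matrix(x)) {
    apply(x, 1, identity, simplify = FALSE)
  } else {
    unclass(x)
  }
}
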