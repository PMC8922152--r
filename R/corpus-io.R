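# Reading, writing and eligibility filtering of patient review records.
#
# A review record has: record_id, drug, source, comment, side_effect_comment,
# age_years (integer or NA), gender, time_on_med, rating (integer 1..5 or NA),
# post_date, reviewer_type. Text fields use "" for missing, categorical
# fields use the literal level "missing", numeric fields use NA; this makes
# CSV round-trips unambiguous.

REVIEW_COLUMNS <- c("record_id", "drug", "source", "comment",
                    "side_effect_comment", "age_years", "gender",
                    "time_on_med", "rating", "post_date", "reviewer_type")

.review_text_cols <- c("record_id", "drug", "source", "comment",
                       "side_effect_comment", "post_date")
.review_enum_cols <- c(gender = "missing", time_on_med = "missing",
                       reviewer_type = "missing")

normalize_reviews <- function(df, origin = "input") {
  for (col in setdiff(REVIEW_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, REVIEW_COLUMNS, drop = FALSE]
  for (col in .review_text_cols) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- ""
    df[[col]] <- x
  }
  for (col in names(.review_enum_cols)) {
    x <- as.character(df[[col]])
    x[is.na(x) | !nzchar(x)] <- .review_enum_cols[[col]]
    df[[col]] <- x
  }
  df$age_years <- suppressWarnings(as.integer(df$age_years))
  df$rating <- suppressWarnings(as.integer(df$rating))
  bad <- which(!is.na(df$rating) & (df$rating < 1 | df$rating > 5))
  if (length(bad)) {
    stopf("%s: rating outside 1..5 for record(s) %s", origin,
          paste(df$record_id[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read patient review records
#'
#' Reads a review table from CSV (RFC-4180, UTF-8, header row) or JSON-lines.
#' Missing cells map to the record's missing sentinel ("" for text, the level
#' `"missing"` for categorical fields, `NA` for age and rating). Malformed
#' JSONL lines are skipped with a warning naming their line numbers; a rating
#' outside 1..5 is a validation error naming the record.
#'
#' @param path input file.
#' @param format `"csv"` or `"jsonl"`.
#' @return data frame of review records.
#' @export
read_reviews <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read reviews: no such file '%s'", path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parsed <- vector("list", length(lines))
    bad <- integer(0)
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(rec) || is.null(names(rec))) {
        bad <- c(bad, i)
      } else {
        parsed[[i]] <- as.data.frame(
          lapply(rec, function(x) if (is.null(x)) NA else x),
          stringsAsFactors = FALSE)
      }
    }
    if (length(bad)) {
      warning(sprintf("skipped %d malformed JSONL line(s): %s", length(bad),
                      paste(bad, collapse = ", ")), call. = FALSE)
      parsed <- parsed[-bad]
    }
    if (!length(parsed)) {
      df <- data.frame()
    } else {
      cols <- unique(unlist(lapply(parsed, names)))
      parsed <- lapply(parsed, function(p) {
        for (col in setdiff(cols, names(p))) p[[col]] <- NA
        p[, cols, drop = FALSE]
      })
      df <- do.call(rbind, parsed)
    }
  }
  normalize_reviews(df, origin = path)
}

#' Write patient review records
#'
#' @param records review data frame.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_reviews <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  records <- normalize_reviews(records, origin = "write_reviews input")
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      writeLines(as.character(
        jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                         na = "null", digits = 12)), con)
    }
  }
  invisible(path)
}

contains_spam <- function(comment) {
  x <- tolower(comment)
  grepl("http", x, fixed = TRUE) | grepl(".com", x, fixed = TRUE) |
    grepl("www.", x, fixed = TRUE)
}

#' Apply review eligibility filters
#'
#' Removes, in order of rule precedence: (1) records whose comment is empty
#' after whitespace stripping, (2) records whose comment contains any of the
#' case-insensitive spam substrings `"http"`, `".com"`, `"www."`, and
#' (3) records with missing age or age under 19. Each removed record is
#' logged under the first rule it matches; precedence affects only log
#' attribution, never the surviving set. Records by female reviewers are
#' retained (reviews may come from partners or caregivers). Survivors keep
#' their input order.
#'
#' @param records review data frame.
#' @param rescue_side_effect_comment if `TRUE`, a record with an empty main
#'   comment but a non-empty side-effect comment passes the empty-comment
#'   rule (the side-effect text then feeds downstream preprocessing via
#'   `effective_comment`). Default `FALSE`: a side-effects-only post counts
#'   as uncommented.
#' @return list with `records` (survivors) and `log` (a `filter_log`:
#'   per-rule removed counts, per-record reasons, input/output totals).
#' @export
filter_reviews <- function(records, rescue_side_effect_comment = FALSE) {
  records <- normalize_reviews(records, origin = "filter_reviews input")
  n <- nrow(records)
  empty_main <- !nzchar(trimws(records$comment))
  empty <- if (rescue_side_effect_comment) {
    empty_main & !nzchar(trimws(records$side_effect_comment))
  } else {
    empty_main
  }
  spam <- contains_spam(records$comment)
  underage <- is.na(records$age_years) | records$age_years < 19
  reason <- rep(NA_character_, n)
  reason[underage] <- "underage"
  reason[spam] <- "spam"
  reason[empty] <- "empty_comment"  # highest precedence assigned last
  keep <- is.na(reason)
  removed <- c(
    empty_comment = sum(reason == "empty_comment", na.rm = TRUE),
    spam = sum(reason == "spam", na.rm = TRUE),
    underage = sum(reason == "underage", na.rm = TRUE)
  )
  log <- structure(list(
    input_total = n,
    output_total = sum(keep),
    removed = removed,
    reasons = data.frame(record_id = records$record_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  ), class = "filter_log")
  survivors <- records[keep, , drop = FALSE]
  rownames(survivors) <- NULL
  list(records = survivors, log = log)
}

#' @export
print.filter_log <- function(x, ...) {
  cat(sprintf("Review filter log: %d in, %d out\n", x$input_total,
              x$output_total))
  for (r in names(x$removed)) {
    cat(sprintf("  removed (%s): %d\n", r, x$removed[[r]]))
  }
  invisible(x)
}

#' Serialize a filter log as JSON
#'
#' @param log a `filter_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(log, path) {
  stopifnot(inherits(log, "filter_log"))
  jsonlite::write_json(
    list(input_total = log$input_total, output_total = log$output_total,
         removed = as.list(log$removed), reasons = log$reasons),
    path, auto_unbox = TRUE)
  invisible(path)
}
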