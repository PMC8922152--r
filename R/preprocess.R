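# Text preprocessing: review comments -> document-term matrix.
#
# Chain: case-fold -> delete punctuation and digit characters -> split on
# whitespace -> drop short tokens -> typo correction -> bigram merging ->
# stopword removal -> Porter stemming with corpus-frequency stem completion
# -> sparse document-term matrix. The whole chain is a pure function of
# (documents, config).

#' Preprocessing configuration
#'
#' @param stopwords character vector of stopwords ([stopwords_en()] by
#'   default; "irrelevant word" removal is folded into this list).
#' @param bigrams list of length-2 lowercase character vectors; adjacent
#'   token pairs matching an entry are merged into a single `a_b` token
#'   before stemming. Defaults cover the domain's two stock collocations.
#' @param typo_map named character vector mapping misspelled whole tokens to
#'   their corrections.
#' @param min_token_length tokens shorter than this are dropped.
#' @param case_fold lower-case the text first.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(stopwords = stopwords_en(),
                              bigrams = list(c("erectile", "dysfunction"),
                                             c("side", "effect")),
                              typo_map = character(0),
                              min_token_length = 2,
                              case_fold = TRUE) {
  stopifnot(is.character(stopwords))
  assert_that(all(vapply(bigrams, length, integer(1)) == 2),
              "each bigram must be a pair of words")
  keys <- vapply(bigrams, paste, character(1), collapse = " ")
  assert_that(!anyDuplicated(keys), "bigram pairs must be distinct")
  assert_that(all(keys == tolower(keys)), "bigram pairs must be lowercase")
  if (length(typo_map)) {
    assert_that(!is.null(names(typo_map)) && !anyDuplicated(names(typo_map)),
                "typo_map keys must be unique")
  }
  structure(list(stopwords = stopwords, bigrams = bigrams,
                 typo_map = typo_map,
                 min_token_length = as.integer(min_token_length),
                 case_fold = isTRUE(case_fold)),
            class = "preprocess_config")
}

#' Clean and tokenize free text
#'
#' Case-folds, deletes punctuation and digit characters, splits on
#' whitespace, drops tokens shorter than the configured minimum, and applies
#' the whole-token typo-correction map.
#'
#' @param text a single character string (possibly empty).
#' @param config a [preprocess_config()].
#' @return character vector of tokens (empty for empty text).
#' @examples
#' clean_and_tokenize("Took 50mg;  HEADACHE!!", preprocess_config())
#' @export
clean_and_tokenize <- function(text, config = preprocess_config()) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character(0))
  if (config$case_fold) text <- tolower(text)
  text <- gsub("[[:punct:][:digit:]]+", "", text)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens) & nchar(tokens) >= config$min_token_length]
  if (length(config$typo_map)) {
    hit <- tokens %in% names(config$typo_map)
    tokens[hit] <- unname(config$typo_map[tokens[hit]])
  }
  tokens
}

#' Merge listed bigrams into single tokens
#'
#' Single left-to-right pass: each adjacent token pair matching a listed
#' bigram is replaced by the two words joined with `"_"`. Merged tokens are
#' never re-merged.
#'
#' @param tokens cleaned, lowercased tokens.
#' @param bigrams list of word pairs (see [preprocess_config()]).
#' @return token vector with merges applied.
#' @export
merge_bigrams <- function(tokens, bigrams) {
  if (!length(tokens) || !length(bigrams)) return(tokens)
  keys <- vapply(bigrams, paste, character(1), collapse = " ")
  out <- character(length(tokens))
  m <- 0L
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (i < n && paste(tokens[i], tokens[i + 1]) %in% keys) {
      m <- m + 1L
      out[m] <- paste(tokens[i], tokens[i + 1], sep = "_")
      i <- i + 2L
    } else {
      m <- m + 1L
      out[m] <- tokens[i]
      i <- i + 1L
    }
  }
  out[seq_len(m)]
}

#' Remove stopwords
#'
#' Whole-token membership test; bigram-merged tokens (containing `"_"`)
#' never match a single stopword.
#'
#' @param tokens token vector.
#' @param stopwords character vector.
#' @return filtered token vector.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!(tokens %in% stopwords)]
}

stem_token <- function(tokens) {
  parts <- strsplit(tokens, "_", fixed = TRUE)
  vapply(parts, function(p) paste(porter_stem(p), collapse = "_"),
         character(1))
}

#' Stem tokens and complete stems to their dominant surface form
#'
#' Every token is Porter-stemmed (bigram tokens component-wise); each stem is
#' then replaced by the surface form with the highest corpus frequency among
#' all original tokens sharing that stem, ties broken by the
#' lexicographically smallest surface form. This is corpus-level: the
#' completion map is built from all documents jointly.
#'
#' @param documents list of token vectors.
#' @return list of token vectors of the same shape, tokens replaced by their
#'   completed forms.
#' @export
stem_and_complete <- function(documents) {
  assert_that(length(documents) > 0, "stem_and_complete needs a non-empty corpus")
  all_tokens <- unlist(documents, use.names = FALSE)
  if (!length(all_tokens)) return(documents)
  tab <- table(all_tokens)
  surfaces <- names(tab)
  freq <- as.integer(tab)
  stems <- stem_token(surfaces)
  ord <- order(stems, -freq, surfaces, method = "radix")
  first <- !duplicated(stems[ord])
  completion <- setNames(surfaces[ord][first], stems[ord][first])
  surface_map <- setNames(unname(completion[stems]), surfaces)
  lapply(documents, function(toks) {
    if (!length(toks)) return(character(0))
    unname(surface_map[toks])
  })
}

#' Build a sparse document-term matrix
#'
#' Vocabulary is the union of tokens ordered by descending corpus frequency,
#' ties by lexicographic order, so the matrix is bit-reproducible. Documents
#' emptied by preprocessing are dropped and their ids reported; it is an
#' error for every document to be empty.
#'
#' @param documents list of token vectors.
#' @param doc_ids document identifiers (default `doc1..docD`).
#' @return object of class `dtm`: sparse `counts` (documents x vocabulary),
#'   `vocabulary` data frame (term, index, freq), `doc_ids`, `N_d` row
#'   totals, and `dropped_doc_ids`.
#' @export
build_dtm <- function(documents, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_along(documents))
  assert_that(length(doc_ids) == length(documents),
              "doc_ids must match documents in length")
  lens <- lengths(documents)
  dropped <- doc_ids[lens == 0]
  keep <- lens > 0
  assert_that(any(keep), "all documents empty after preprocessing")
  documents <- documents[keep]
  doc_ids <- doc_ids[keep]
  all_tokens <- unlist(documents, use.names = FALSE)
  tab <- table(all_tokens)
  terms <- names(tab)
  freq <- as.integer(tab)
  ord <- order(-freq, terms, method = "radix")
  terms <- terms[ord]
  freq <- freq[ord]
  term_index <- setNames(seq_along(terms), terms)
  i <- rep(seq_along(documents), lengths(documents))
  j <- unname(term_index[all_tokens])
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(documents), length(terms)),
                                 dimnames = list(doc_ids, terms))
  counts <- methods::as(counts, "CsparseMatrix")
  structure(list(
    counts = counts,
    vocabulary = data.frame(term = terms, index = seq_along(terms),
                            freq = freq, stringsAsFactors = FALSE),
    doc_ids = doc_ids,
    N_d = setNames(as.integer(Matrix::rowSums(counts)), doc_ids),
    dropped_doc_ids = dropped
  ), class = "dtm")
}

#' @export
print.dtm <- function(x, ...) {
  cat(sprintf("Document-term matrix: %d documents x %d terms, %d tokens",
              nrow(x$counts), ncol(x$counts), sum(x$N_d)))
  if (length(x$dropped_doc_ids)) {
    cat(sprintf(" (%d empty documents dropped)", length(x$dropped_doc_ids)))
  }
  cat("\n")
  invisible(x)
}

#' Preprocess review records into a document-term matrix
#'
#' Runs the full chain ([clean_and_tokenize()], [merge_bigrams()],
#' [remove_stopwords()], [stem_and_complete()], [build_dtm()]) over the
#' `comment` field of eligible review records.
#'
#' @param records review data frame (typically [filter_reviews()] survivors).
#' @param config a [preprocess_config()].
#' @return a `dtm` whose `doc_ids` are the record ids.
#' @export
preprocess_corpus <- function(records, config = preprocess_config()) {
  assert_that(nrow(records) > 0, "no records to preprocess")
  docs <- lapply(records$comment, function(text) {
    toks <- clean_and_tokenize(text, config)
    toks <- merge_bigrams(toks, config$bigrams)
    remove_stopwords(toks, config$stopwords)
  })
  docs <- stem_and_complete(docs)
  build_dtm(docs, doc_ids = records$record_id)
}

#' Write a document-term matrix as MatrixMarket plus sidecars
#'
#' Writes `dtm.mtx` (coordinate format), `vocabulary.txt` (one term per
#' line, matrix column order) and `doc_ids.txt` (one id per line, row order)
#' into `dir`.
#'
#' @param dtm a `dtm`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dtm <- function(dtm, dir) {
  stopifnot(inherits(dtm, "dtm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dtm$counts, file.path(dir, "dtm.mtx"))
  writeLines(dtm$vocabulary$term, file.path(dir, "vocabulary.txt"))
  writeLines(dtm$doc_ids, file.path(dir, "doc_ids.txt"))
  if (length(dtm$dropped_doc_ids)) {
    writeLines(dtm$dropped_doc_ids, file.path(dir, "dropped_doc_ids.txt"))
  }
  invisible(dir)
}

#' Read a document-term matrix written by [write_dtm()]
#'
#' @param dir directory containing `dtm.mtx`, `vocabulary.txt`,
#'   `doc_ids.txt`.
#' @return a `dtm`.
#' @export
read_dtm <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "dtm.mtx")),
                        "CsparseMatrix")
  terms <- readLines(file.path(dir, "vocabulary.txt"))
  doc_ids <- readLines(file.path(dir, "doc_ids.txt"))
  dimnames(counts) <- list(doc_ids, terms)
  dropped_path <- file.path(dir, "dropped_doc_ids.txt")
  dropped <- if (file.exists(dropped_path)) readLines(dropped_path) else character(0)
  structure(list(
    counts = counts,
    vocabulary = data.frame(term = terms, index = seq_along(terms),
                            freq = as.integer(Matrix::colSums(counts)),
                            stringsAsFactors = FALSE),
    doc_ids = doc_ids,
    N_d = setNames(as.integer(Matrix::rowSums(counts)), doc_ids),
    dropped_doc_ids = dropped
  ), class = "dtm")
}
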