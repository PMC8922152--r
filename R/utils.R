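#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed report tables here use the
#' conventional round-half-up at a fixed number of decimals (e.g. 20.35 ->
#' 20.4, not 20.3).
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cosine similarity between two vectors
#' @keywords internal
cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Derive a stage-specific child seed from a global seed
#'
#' Deterministic mixing of the global seed with a stage name, so every
#' pipeline stage gets its own reproducible random stream and stages can be
#' re-run in isolation. Result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
child_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483587)
}

#' Sample from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha concentration vector (all entries > 0).
#' @return n x length(alpha) matrix, rows on the simplex.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  # guard against all-zero rows from tiny concentrations
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- rep(alpha / sum(alpha), each = sum(zero))
  x / rowSums(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stopf(...)
  invisible(TRUE)
}
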