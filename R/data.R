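# Synthetic data and the packaged worked-example fixture.

#' Generate synthetic data
#'
#' Reproducible draws from the two sampling models: i.i.d. Bernoulli(theta)
#' 0/1 sequences or i.i.d. normal observations with known variance.  The
#' global RNG state is left untouched; the same `seed` always yields the
#' same sequence.
#'
#' @param family `"bernoulli"` or `"normal"`.
#' @param n Number of observations (>= 1).
#' @param theta Bernoulli success probability, strictly in (0, 1).
#' @param mean,sigma_sq Normal mean and (known) variance.
#' @param seed Integer seed; required.
#' @return Numeric vector of length `n`.
#' @examples
#' generate_data("bernoulli", n = 20, theta = 0.5, seed = 1)
#' @export
generate_data <- function(family = c("bernoulli", "normal"), n,
                          theta = NULL, mean = 0, sigma_sq = 1, seed) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (n < 1L) stopf("'n' must be >= 1")
  if (missing(seed)) stopf("'seed' is required")
  if (family == "bernoulli") {
    if (is.null(theta) || !is.finite(theta) || theta <= 0 || theta >= 1)
      stopf("'theta' must lie strictly in (0, 1)")
    withr::with_seed(as.integer(seed), stats::rbinom(n, 1L, theta))
  } else {
    if (!is.finite(mean) || !is.finite(sigma_sq) || sigma_sq <= 0)
      stopf("'mean' must be finite and 'sigma_sq' positive")
    withr::with_seed(as.integer(seed), stats::rnorm(n, mean, sqrt(sigma_sq)))
  }
}

#' The packaged 20-toss proportion example
#'
#' The worked-example dataset used throughout the documentation and tests:
#' twenty Bernoulli observations with eight ones (mean 0.400).  The same
#' sequence ships as a plain-text digit string in
#' `system.file("extdata", "proportion_example.txt", package = "relbelief")`.
#'
#' @return Integer vector of length 20 (sum 8).
#' @export
example_proportion_data <- function() {
  c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
    1L, 1L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L)
}

#' Read observations from a file or inline string
#'
#' Accepts a numeric vector (returned as is), a bare 0/1 digit string such
#' as `"11000000001111010010"` (split into single observations), or a path
#' to a plain-text/CSV file with one observation per line (a single-line
#' digit string file is also accepted).
#'
#' @param x Numeric vector, digit string, or file path.
#' @return Numeric vector of observations.
#' @export
read_observations <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stopf("'x' must be a numeric vector, a digit string, or a file path")
  if (grepl("^[01]+$", x)) return(as.numeric(strsplit(x, "")[[1L]]))
  if (!file.exists(x)) stopf("file '%s' not found (and not a 0/1 digit string)", x)
  lines <- trimws(readLines(x, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 1L && grepl("^[01]+$", lines))
    return(as.numeric(strsplit(lines, "")[[1L]]))
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    stopf("non-numeric value at line %d of '%s'", which(is.na(vals))[1L], x)
  vals
}
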