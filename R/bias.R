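# Pre-experimental bias: prior predictive probabilities, computed before any
# data are seen, that the evidence will point the wrong way.  Everything
# runs over the minimal sufficient statistic: by the Savage-Dickey identity
# the relative belief ratio of psi0 depends on the data only through the
# predictive densities of T, which collapses the Bernoulli sum from 2^n
# data vectors to n + 1 lattice points.

#' Relative belief ratio as a function of the sufficient statistic
#'
#' The Savage-Dickey identity: RB(psi0 | x) equals the conditional prior
#' predictive density of the data given psi0 divided by the marginal prior
#' predictive density.  For the Bernoulli family this is the Binomial(n,
#' psi0) pmf over the beta-binomial pmf at the success count `t` — exact,
#' and identical to the posterior/prior density ratio of
#' [relative_belief_ratio()].  For the normal family it is the ratio of the
#' two normal densities of the sample mean.
#'
#' @param model Conjugate model (its data fields are ignored; `n` below
#'   governs the sample size).
#' @param psi0 Hypothesized parameter value.
#' @param t Value(s) of the sufficient statistic.
#' @param n Sample size (defaults to the model's `n`).  `n = 0` returns 1.
#' @return Nonnegative ratio(s), vectorised over `t`.
#' @examples
#' m <- beta_bernoulli(4, 4)
#' rb_of_sufficient_statistic(m, 0.5, t = 8, n = 20)  # 1.421
#' @export
rb_of_sufficient_statistic <- function(model, psi0, t, n = model$n) {
  stopifnot(inherits(model, "rb_model"))
  if (n == 0L) return(rep(1, length(t)))
  if (model$family == "bernoulli") {
    if (!is.finite(psi0) || psi0 < 0 || psi0 > 1)
      stopf("'psi0' must lie in [0, 1]")
    if (any(t < 0 | t > n | t != round(t)))
      stopf("'t' must be an integer count in 0..n")
    lm <- .lbetabinom(t, n, model$alpha0, model$beta0)
    if (any(!is.finite(lm)))
      stopf("marginal prior predictive mass is zero at t")
    exp(stats::dbinom(t, n, psi0, log = TRUE) - lm)
  } else {
    v1 <- model$sigma_sq / n
    v0 <- model$tau0_sq + v1
    exp(stats::dnorm(t, psi0, sqrt(v1), log = TRUE) -
        stats::dnorm(t, model$mu0, sqrt(v0), log = TRUE))
  }
}

# Roots of log RB(psi0 | t) = 0 in t for the normal family: the log ratio is
# a downward quadratic in t (the conditional predictive variance sigma^2/n
# is strictly smaller than the marginal's tau0^2 + sigma^2/n), so
# {RB > 1} is the interval between the roots, possibly empty.  Degenerate
# (near-linear) algebra is handled analytically as well.
.normal_rb_gt1_interval <- function(model, psi0, n) {
  v1 <- model$sigma_sq / n
  v0 <- model$tau0_sq + v1
  A <- (v1 - v0) / (2 * v0 * v1)                      # < 0
  B <- psi0 / v1 - model$mu0 / v0
  C <- -psi0^2 / (2 * v1) + model$mu0^2 / (2 * v0) + 0.5 * log(v0 / v1)
  if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) {
      return(if (C > 0) c(-Inf, Inf) else c(NA_real_, NA_real_))
    }
    r <- -C / B
    return(if (B > 0) c(r, Inf) else c(-Inf, r))
  }
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(c(NA_real_, NA_real_))        # RB <= 1 everywhere
  sq <- sqrt(disc)
  sort(c((-B + sq) / (2 * A), (-B - sq) / (2 * A)))
}

#' A priori bias against a hypothesis
#'
#' The prior probability that evidence *for* `psi0` will not be obtained
#' when `psi0` is true: data are generated from the conditional prior
#' predictive given `psi0` and the event is `{RB(psi0 | T) <= 1}`.  A large
#' value means the prior is stacked against the hypothesis, so a subsequent
#' report of evidence against it carries little force.
#'
#' Exact: a finite lattice sum for the Bernoulli family; for the normal
#' family the event is an interval in the sample mean obtained from the
#' quadratic log-density difference, evaluated with normal distribution
#' functions.  `n = 0` returns 1 (RB is identically 1 and the `<=`
#' convention makes the event certain).
#'
#' @param model Conjugate model (prior only is used).
#' @param psi0 Hypothesized value.
#' @param n Sample size (defaults to the model's `n`).
#' @return A probability.
#' @examples
#' bias_against(beta_bernoulli(4, 4), psi0 = 0.5, n = 20)  # 0.2632
#' @export
bias_against <- function(model, psi0, n = model$n) {
  stopifnot(inherits(model, "rb_model"))
  if (n == 0L) return(1)
  if (model$family == "bernoulli") {
    s <- 0:n
    lr <- stats::dbinom(s, n, psi0, log = TRUE) -
      .lbetabinom(s, n, model$alpha0, model$beta0)
    sum(stats::dbinom(s, n, psi0)[lr <= .rb_tie_tol])
  } else {
    iv <- .normal_rb_gt1_interval(model, psi0, n)
    if (anyNA(iv)) return(1)
    sd1 <- sqrt(model$sigma_sq / n)
    1 - (stats::pnorm(iv[2L], psi0, sd1) - stats::pnorm(iv[1L], psi0, sd1))
  }
}

#' A priori bias in favor of a hypothesis
#'
#' The prior probability that evidence *against* `psi0` will not be obtained
#' when the true value is a meaningfully different `psi0'`: data are
#' generated from the conditional prior predictive given each deviation
#' value and the event is `{RB(psi0 | T) > 1}` (strict, following the
#' worked convention; the complementary `<=` belongs to the bias-against
#' event).  Large values mean the prior manufactures evidence for `psi0`
#' even when it is false by the stated margin; the value tends to decrease
#' as the deviation grows and as `n` grows.
#'
#' @param model Conjugate model (prior only is used).
#' @param psi0 Hypothesized value.
#' @param deviations Alternative true values, each different from `psi0`.
#' @param n Sample size (defaults to the model's `n`).
#' @return Named vector of probabilities, one per deviation.
#' @examples
#' bias_in_favor(beta_bernoulli(4, 4), 0.5, c(0.45, 0.55), n = 20)
#' @export
bias_in_favor <- function(model, psi0, deviations, n = model$n) {
  stopifnot(inherits(model, "rb_model"))
  if (length(deviations) == 0L) stopf("'deviations' must be nonempty")
  if (any(deviations == psi0)) stopf("deviations must differ from 'psi0'")
  out <- vapply(deviations, function(d) {
    if (n == 0L) return(0)
    if (model$family == "bernoulli") {
      if (d < 0 || d > 1) stopf("deviation %g outside [0, 1]", d)
      s <- 0:n
      lr <- stats::dbinom(s, n, psi0, log = TRUE) -
        .lbetabinom(s, n, model$alpha0, model$beta0)
      sum(stats::dbinom(s, n, d)[lr > .rb_tie_tol])
    } else {
      iv <- .normal_rb_gt1_interval(model, psi0, n)
      if (anyNA(iv)) return(0)
      sd1 <- sqrt(model$sigma_sq / n)
      stats::pnorm(iv[2L], d, sd1) - stats::pnorm(iv[1L], d, sd1)
    }
  }, 0)
  names(out) <- format(deviations)
  out
}

#' Pre-experimental bias report
#'
#' Convenience wrapper computing [bias_against()] at `psi0` and
#' [bias_in_favor()] at `psi0 +/- delta` (deviations falling outside the
#' parameter space are dropped with a warning) for a given design sample
#' size.
#'
#' @param model Conjugate model.
#' @param psi0 Hypothesized value.
#' @param delta Smallest difference of practical importance.
#' @param n Sample size.
#' @return An `rb_bias` report.
#' @export
bias_report <- function(model, psi0, delta, n = model$n) {
  stopifnot(inherits(model, "rb_model"))
  if (!is.numeric(delta) || delta <= 0) stopf("'delta' must be positive")
  dev <- c(psi0 - delta, psi0 + delta)
  if (model$family == "bernoulli") {
    ok <- dev > 0 & dev < 1
    if (!all(ok)) {
      warning(sprintf("deviation(s) %s outside (0, 1) dropped",
                      paste(format(dev[!ok]), collapse = ", ")), call. = FALSE)
      dev <- dev[ok]
    }
    if (length(dev) == 0L) stopf("no admissible deviation at delta = %g", delta)
  }
  structure(
    list(psi0 = psi0, n = n, delta = delta,
         bias_against = bias_against(model, psi0, n),
         deviations = dev,
         bias_in_favor = bias_in_favor(model, psi0, dev, n),
         method = "exact-sum", model = model),
    class = "rb_bias")
}

#' @export
print.rb_bias <- function(x, ...) {
  cat(sprintf("A priori bias at psi0 = %.3f (n = %d)\n", x$psi0, x$n))
  cat(sprintf("  bias against : %.3f\n", x$bias_against))
  for (i in seq_along(x$deviations))
    cat(sprintf("  bias in favor at %.3f : %.3f\n",
                x$deviations[i], x$bias_in_favor[i]))
  invisible(x)
}

#' Sample size controlling both biases
#'
#' Scans `n = 0, 1, ..., n_max` for the smallest sample size whose bias
#' against `psi0` and bias in favor at `psi0 +/- delta` are all at or below
#' their targets.  A linear scan is used deliberately: on the discrete
#' sufficient-statistic lattice the biases need not be exactly monotone in
#' `n`, so bisection could overshoot.  The full trace is returned so design
#' curves can be plotted.
#'
#' @param model Conjugate model (prior only is used).
#' @param psi0 Hypothesized value.
#' @param delta Smallest practically important deviation.
#' @param max_bias_against,max_bias_in_favor Targets in `(0, 1]`.
#' @param n_max Upper bound of the scan.
#' @return An `rb_design`: `n` (smallest qualifying size, `NA` if none),
#'   `found`, and the `trace` data frame.
#' @examples
#' design_sample_size(beta_bernoulli(4, 4), 0.5, 0.25,
#'                    max_bias_against = 0.3, max_bias_in_favor = 0.1,
#'                    n_max = 60)
#' @export
design_sample_size <- function(model, psi0, delta, max_bias_against,
                               max_bias_in_favor, n_max = 500L) {
  stopifnot(inherits(model, "rb_model"))
  if (max_bias_against <= 0 || max_bias_against > 1 ||
      max_bias_in_favor <= 0 || max_bias_in_favor > 1)
    stopf("bias targets must lie in (0, 1]")
  dev <- c(psi0 - delta, psi0 + delta)
  if (model$family == "bernoulli") dev <- dev[dev > 0 & dev < 1]
  if (length(dev) == 0L) stopf("no admissible deviation at delta = %g", delta)
  ns <- 0:n_max
  ba <- vapply(ns, function(n) bias_against(model, psi0, n), 0)
  bf <- t(vapply(ns, function(n)
    if (n == 0L) rep(0, length(dev)) else bias_in_favor(model, psi0, dev, n),
    numeric(length(dev))))
  ok <- ba <= max_bias_against & apply(bf <= max_bias_in_favor, 1L, all)
  n_star <- if (any(ok)) ns[which(ok)[1L]] else NA_integer_
  trace <- data.frame(n = ns, bias_against = ba)
  for (j in seq_along(dev))
    trace[[paste0("bias_in_favor_", format(dev[j]))]] <- bf[, j]
  trace$qualifies <- ok
  structure(
    list(n = n_star, found = !is.na(n_star), psi0 = psi0, delta = delta,
         targets = c(against = max_bias_against, in_favor = max_bias_in_favor),
         trace = trace),
    class = "rb_design")
}

#' @export
print.rb_design <- function(x, ...) {
  if (x$found) {
    cat(sprintf(
      "Smallest n with bias against <= %.3g and bias in favor <= %.3g at psi0 = %.3f +/- %.3g: n = %d\n",
      x$targets[["against"]], x$targets[["in_favor"]], x$psi0, x$delta, x$n))
  } else {
    cat(sprintf("No n <= %d meets the bias targets; see $trace\n",
                max(x$trace$n)))
  }
  invisible(x)
}
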