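#' Bernoulli model with a beta prior
#'
#' Bundles a `beta(alpha0, beta0)` prior with `n` i.i.d. Bernoulli(theta)
#' observations summarised by their minimal sufficient statistic `s`, the
#' count of ones.  All downstream relative belief quantities for this family
#' are available in closed form through the conjugate update
#' `beta(alpha0 + s, beta0 + n - s)`.
#'
#' Either supply `data` (a 0/1 vector) or the pair `n`, `s` directly.  With
#' neither, the model carries no data (`n = 0`) and every relative belief
#' ratio is identically 1.
#'
#' @param alpha0,beta0 Positive prior shape parameters.
#' @param data Optional numeric vector of 0s and 1s.
#' @param n,s Optional sample size and success count (used when `data` is
#'   not given).
#' @return An object of class `c("beta_bernoulli", "rb_model")`.
#' @examples
#' m <- beta_bernoulli(4, 4, data = example_proportion_data())
#' posterior_hyperparams(m)   # beta(12, 16)
#' relative_belief_ratio(m, 0.5)
#' @seealso [normal_known_var()], [relative_belief_ratio()],
#'   [assess_evidence()]
#' @export
beta_bernoulli <- function(alpha0, beta0, data = NULL, n = NULL, s = NULL) {
  if (!is.numeric(alpha0) || length(alpha0) != 1L || !is.finite(alpha0) || alpha0 <= 0)
    stopf("'alpha0' must be a single positive number")
  if (!is.numeric(beta0) || length(beta0) != 1L || !is.finite(beta0) || beta0 <= 0)
    stopf("'beta0' must be a single positive number")
  if (!is.null(data)) {
    s <- sufficient_statistic(data, "bernoulli")
    n <- length(data)
  } else {
    n <- as.integer(n %||% 0L)
    s <- as.integer(s %||% 0L)
  }
  if (n < 0) stopf("'n' must be nonnegative")
  if (s < 0 || s > n) stopf("'s' must satisfy 0 <= s <= n (got s = %d, n = %d)", s, n)
  structure(
    list(family = "bernoulli", alpha0 = alpha0, beta0 = beta0, n = n, s = s),
    class = c("beta_bernoulli", "rb_model")
  )
}

#' Normal model with known variance and a normal prior
#'
#' Bundles a `N(mu0, tau0_sq)` prior on the mean of a `N(mu, sigma_sq)`
#' sampling model (variance known) with `n` observations summarised by the
#' sample mean `xbar`, the minimal sufficient statistic.
#'
#' @param mu0 Prior mean.
#' @param tau0_sq Positive prior variance.
#' @param sigma_sq Known positive sampling variance.
#' @param data Optional numeric data vector.
#' @param n,xbar Optional sample size and sample mean (used when `data` is
#'   not given).  `n = 0` is the no-data identity case.
#' @return An object of class `c("normal_normal", "rb_model")`.
#' @examples
#' m <- normal_known_var(0, 10, 1, n = 25, xbar = 0.3)
#' relative_belief_ratio(m, 0)
#' @export
normal_known_var <- function(mu0, tau0_sq, sigma_sq, data = NULL,
                             n = NULL, xbar = NULL) {
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0))
    stopf("'mu0' must be a single finite number")
  if (!is.numeric(tau0_sq) || length(tau0_sq) != 1L || !is.finite(tau0_sq) || tau0_sq <= 0)
    stopf("'tau0_sq' must be a single positive number")
  if (!is.numeric(sigma_sq) || length(sigma_sq) != 1L || !is.finite(sigma_sq) || sigma_sq <= 0)
    stopf("'sigma_sq' must be a single positive number")
  if (!is.null(data)) {
    xbar <- sufficient_statistic(data, "normal")
    n <- length(data)
  } else {
    n <- as.integer(n %||% 0L)
    xbar <- xbar %||% NA_real_
  }
  if (n < 0) stopf("'n' must be nonnegative")
  if (n > 0 && !is.finite(xbar)) stopf("'xbar' is required when n > 0")
  structure(
    list(family = "normal", mu0 = mu0, tau0_sq = tau0_sq, sigma_sq = sigma_sq,
         n = n, xbar = xbar),
    class = c("normal_normal", "rb_model")
  )
}

#' Minimal sufficient statistic of a sample
#'
#' The count of ones for the Bernoulli family, the sample mean for the
#' normal (known variance) family.  All relative belief inference, the bias
#' computations, and the prior-data conflict check depend on the data only
#' through this statistic.
#'
#' @param data Nonempty numeric vector; strictly 0/1 for `"bernoulli"`.
#' @param family `"bernoulli"` or `"normal"`.
#' @return The statistic: an integer count or a mean.
#' @examples
#' sufficient_statistic(c(1, 1, 0, 1), "bernoulli")  # 3
#' sufficient_statistic(c(1.2, 0.8, 1.0), "normal")  # 1
#' @export
sufficient_statistic <- function(data, family = c("bernoulli", "normal")) {
  family <- match.arg(family)
  if (!is.numeric(data) || length(data) == 0L)
    stopf("'data' must be a nonempty numeric vector")
  if (anyNA(data)) stopf("'data' contains missing values")
  if (family == "bernoulli") {
    bad <- which(data != 0 & data != 1)
    if (length(bad))
      stopf("Bernoulli data must be 0/1; offending value %g at index %d",
            data[bad[1L]], bad[1L])
    sum(as.integer(data))
  } else {
    mean(data)
  }
}

#' Posterior hyperparameters of a conjugate model
#'
#' @param model A [beta_bernoulli()] or [normal_known_var()] model.
#' @return For the Bernoulli family, `c(shape1, shape2)` of the posterior
#'   beta; for the normal family, `c(mean, var)` of the posterior normal.
#' @export
posterior_hyperparams <- function(model) UseMethod("posterior_hyperparams")

#' @export
posterior_hyperparams.beta_bernoulli <- function(model) {
  c(shape1 = model$alpha0 + model$s, shape2 = model$beta0 + model$n - model$s)
}

#' @export
posterior_hyperparams.normal_normal <- function(model) {
  if (model$n == 0L) return(c(mean = model$mu0, var = model$tau0_sq))
  prec <- 1 / model$tau0_sq + model$n / model$sigma_sq
  v <- 1 / prec
  m <- v * (model$mu0 / model$tau0_sq + model$n * model$xbar / model$sigma_sq)
  c(mean = m, var = v)
}

# log prior / posterior densities of theta under a conjugate model
.log_prior_density <- function(model, theta) {
  switch(model$family,
    bernoulli = stats::dbeta(theta, model$alpha0, model$beta0, log = TRUE),
    normal = stats::dnorm(theta, model$mu0, sqrt(model$tau0_sq), log = TRUE))
}

.log_posterior_density <- function(model, theta) {
  h <- posterior_hyperparams(model)
  switch(model$family,
    bernoulli = stats::dbeta(theta, h[[1L]], h[[2L]], log = TRUE),
    normal = stats::dnorm(theta, h[[1L]], sqrt(h[[2L]]), log = TRUE))
}

# posterior / prior cdf and quantile functions (used by the grid engine
# and the exact refinement of strength and regions)
.posterior_cdf <- function(model) {
  h <- posterior_hyperparams(model)
  switch(model$family,
    bernoulli = function(q) stats::pbeta(q, h[[1L]], h[[2L]]),
    normal = function(q) stats::pnorm(q, h[[1L]], sqrt(h[[2L]])))
}

.prior_cdf <- function(model) {
  switch(model$family,
    bernoulli = function(q) stats::pbeta(q, model$alpha0, model$beta0),
    normal = function(q) stats::pnorm(q, model$mu0, sqrt(model$tau0_sq)))
}

.posterior_quantile <- function(model) {
  h <- posterior_hyperparams(model)
  switch(model$family,
    bernoulli = function(p) stats::qbeta(p, h[[1L]], h[[2L]]),
    normal = function(p) stats::qnorm(p, h[[1L]], sqrt(h[[2L]])))
}

.prior_quantile <- function(model) {
  switch(model$family,
    bernoulli = function(p) stats::qbeta(p, model$alpha0, model$beta0),
    normal = function(p) stats::qnorm(p, model$mu0, sqrt(model$tau0_sq)))
}

# open parameter space as a numeric interval used for root bracketing
.param_space <- function(model) {
  switch(model$family,
    bernoulli = c(1e-12, 1 - 1e-12),
    normal = {
      h <- posterior_hyperparams(model)
      sd_wide <- sqrt(max(model$tau0_sq, h[[2L]]))
      centre <- range(model$mu0, h[[1L]])
      c(centre[1L] - 50 * sd_wide, centre[2L] + 50 * sd_wide)
    })
}

#' Exact relative belief ratio of a conjugate model
#'
#' The relative belief ratio RB(theta | x) is the posterior density divided
#' by the prior density at `theta`: the factor by which the data changed the
#' belief that `theta` is the true value.  RB > 1 is evidence in favour,
#' RB < 1 evidence against.  Both conjugate backends evaluate the ratio in
#' log space (differences of `dbeta`/`dnorm` log densities), so it is stable
#' for sample sizes where the gamma-function ratios of the textbook formula
#' overflow.
#'
#' For the Bernoulli family `theta` must lie strictly inside (0, 1): at the
#' endpoints the prior density is 0 or infinite for general shapes and the
#' ratio is not defined.  A model with `n = 0` returns 1 everywhere.
#'
#' @param model A [beta_bernoulli()] or [normal_known_var()] model.
#' @param theta Parameter value(s) at which to evaluate the ratio.
#' @param log Return the log ratio?
#' @return Nonnegative ratio(s), vectorised over `theta`.
#' @examples
#' m <- beta_bernoulli(4, 4, n = 20, s = 8)
#' relative_belief_ratio(m, 0.5)   # 1.421: evidence in favour of 1/2
#' @export
relative_belief_ratio <- function(model, theta, log = FALSE) {
  UseMethod("relative_belief_ratio")
}

#' @export
relative_belief_ratio.beta_bernoulli <- function(model, theta, log = FALSE) {
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 1))
    stopf("'theta' must lie strictly inside (0, 1)")
  lr <- if (model$n == 0L) rep(0, length(theta)) else
    .log_posterior_density(model, theta) - .log_prior_density(model, theta)
  if (log) lr else exp(lr)
}

#' @export
relative_belief_ratio.normal_normal <- function(model, theta, log = FALSE) {
  if (any(!is.finite(theta))) stopf("'theta' must be finite")
  lr <- if (model$n == 0L) rep(0, length(theta)) else
    .log_posterior_density(model, theta) - .log_prior_density(model, theta)
  if (log) lr else exp(lr)
}

# beta-binomial log pmf: the marginal (prior predictive) of the success
# count s when theta ~ beta(alpha0, beta0)
.lbetabinom <- function(s, n, alpha0, beta0) {
  lchoose(n, s) + lbeta(s + alpha0, n - s + beta0) - lbeta(alpha0, beta0)
}

#' Prior predictive of the minimal sufficient statistic
#'
#' For the Bernoulli family this is the beta-binomial distribution of the
#' success count; for the normal family it is `N(mu0, tau0_sq + sigma_sq/n)`
#' for the sample mean.  This distribution (`M_T`) is the ingredient used by
#' [prior_data_conflict()] and by the Savage-Dickey denominator in the bias
#' computations; it is deliberately distinct from the posterior used for
#' inference.
#'
#' @param model Conjugate model.
#' @param n Sample size (defaults to the model's own `n`; must be >= 1).
#' @return A `suffstat_dist` object: for a discrete statistic, `support` and
#'   `mass` (summing to 1); for a continuous one, the `mean`, `sd` and a
#'   `density` function.
#' @examples
#' pp <- prior_predictive(beta_bernoulli(1, 1, n = 5))
#' pp$mass   # uniform 1/6 on 0..5
#' @export
prior_predictive <- function(model, n = model$n) UseMethod("prior_predictive")

#' @export
prior_predictive.beta_bernoulli <- function(model, n = model$n) {
  if (n < 1) stopf("'n' must be >= 1 for a prior predictive")
  s <- 0:n
  suffstat_dist(kind = "discrete", support = s,
                mass = exp(.lbetabinom(s, n, model$alpha0, model$beta0)))
}

#' @export
prior_predictive.normal_normal <- function(model, n = model$n) {
  if (n < 1) stopf("'n' must be >= 1 for a prior predictive")
  m <- model$mu0
  sd <- sqrt(model$tau0_sq + model$sigma_sq / n)
  suffstat_dist(kind = "continuous", mean = m, sd = sd,
                density = function(t) stats::dnorm(t, m, sd))
}

#' Conditional prior predictive of the statistic given the parameter value
#'
#' With the parameter of interest the identity map, conditioning the prior
#' predictive on theta = `psi0` gives the sampling distribution of the
#' statistic: Binomial(`n`, `psi0`) for the success count, or
#' `N(psi0, sigma_sq/n)` for the sample mean.
#'
#' @param model Conjugate model.
#' @param psi0 Parameter value; in `[0, 1]` for the Bernoulli family.
#' @param n Sample size (defaults to the model's own `n`).
#' @return A `suffstat_dist` object.
#' @export
conditional_predictive <- function(model, psi0, n = model$n) {
  UseMethod("conditional_predictive")
}

#' @export
conditional_predictive.beta_bernoulli <- function(model, psi0, n = model$n) {
  if (n < 1) stopf("'n' must be >= 1")
  if (!is.finite(psi0) || psi0 < 0 || psi0 > 1)
    stopf("'psi0' must lie in [0, 1] for the Bernoulli family")
  s <- 0:n
  suffstat_dist(kind = "discrete", support = s, mass = stats::dbinom(s, n, psi0))
}

#' @export
conditional_predictive.normal_normal <- function(model, psi0, n = model$n) {
  if (n < 1) stopf("'n' must be >= 1")
  if (!is.finite(psi0)) stopf("'psi0' must be finite")
  sd <- sqrt(model$sigma_sq / n)
  suffstat_dist(kind = "continuous", mean = psi0, sd = sd,
                density = function(t) stats::dnorm(t, psi0, sd))
}

#' Distribution of a sufficient statistic
#'
#' Light container for the prior predictive or conditional predictive of the
#' minimal sufficient statistic.  Discrete distributions carry an ordered
#' support with probability masses; continuous (normal) ones carry the mean,
#' standard deviation and a density function.
#'
#' @param kind `"discrete"` or `"continuous"`.
#' @param support,mass Support values and matching masses (discrete).
#' @param mean,sd,density Normal parameters and density (continuous).
#' @return A `suffstat_dist` object.
#' @export
suffstat_dist <- function(kind = c("discrete", "continuous"),
                          support = NULL, mass = NULL,
                          mean = NULL, sd = NULL, density = NULL) {
  kind <- match.arg(kind)
  if (kind == "discrete") {
    stopifnot(length(support) == length(mass), all(mass >= 0))
    if (abs(sum(mass) - 1) > 1e-6)
      stopf("discrete masses must sum to 1 (got %.8f)", sum(mass))
    if (is.unsorted(support)) {
      o <- order(support)
      support <- support[o]; mass <- mass[o]
    }
  } else {
    stopifnot(is.function(density), is.finite(mean), is.finite(sd), sd > 0)
  }
  structure(list(kind = kind, support = support, mass = mass,
                 mean = mean, sd = sd, density = density),
            class = "suffstat_dist")
}

#' @export
print.suffstat_dist <- function(x, ...) {
  if (x$kind == "discrete") {
    cat(sprintf("Discrete sufficient-statistic distribution on %d points [%g, %g]\n",
                length(x$support), min(x$support), max(x$support)))
  } else {
    cat(sprintf("Continuous (normal) sufficient-statistic distribution: mean %g, sd %g\n",
                x$mean, x$sd))
  }
  invisible(x)
}
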