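# Independent oracles used across the suite.  They deliberately avoid the
# package's own code paths: gamma-function formulas instead of dbeta
# differences, quadrature instead of the closed-form beta-binomial,
# enumeration instead of the lattice sums.

# worked-example configuration: beta(4, 4) prior, 20 tosses, 8 ones
example_model <- function() beta_bernoulli(4, 4, data = example_proportion_data())

# density-ratio oracle via explicit gamma functions:
# RB(theta) = [G(a0)G(b0)/G(a0+b0)] [G(n+a0+b0)/(G(s+a0)G(n-s+b0))] theta^s (1-theta)^(n-s)
oracle_rb_gamma <- function(theta, a0, b0, n, s) {
  exp(lgamma(a0) + lgamma(b0) - lgamma(a0 + b0) +
      lgamma(n + a0 + b0) - lgamma(s + a0) - lgamma(n - s + b0) +
      s * log(theta) + (n - s) * log(1 - theta))
}

# quadrature oracle for the beta-binomial mass at s
oracle_betabinom_quad <- function(s, n, a0, b0) {
  stats::integrate(function(th)
    choose(n, s) * th^s * (1 - th)^(n - s) * stats::dbeta(th, a0, b0),
    0, 1, rel.tol = 1e-12)$value
}

# brute-force bias oracle: full enumeration over the statistic lattice,
# with the marginal recomputed by quadrature
oracle_bias <- function(a0, b0, psi0, gen, n, direction = c("against", "in_favor")) {
  direction <- match.arg(direction)
  s <- 0:n
  marg <- vapply(s, oracle_betabinom_quad, 0, n = n, a0 = a0, b0 = b0)
  rb <- stats::dbinom(s, n, psi0) / marg
  w <- stats::dbinom(s, n, gen)
  if (direction == "against") sum(w[rb <= 1]) else sum(w[rb > 1])
}

# sort-and-sum oracle for the discrete prior-data conflict tail
oracle_conflict_tail <- function(mass, i_obs) {
  sum(sort(mass)[sort(mass) <= mass[i_obs]])
}

# hand-built two-cell belief for forced-arithmetic cases
make_belief <- function(grid, prior, post, width = diff(grid)[1]) {
  edges <- c(grid - width / 2, grid[length(grid)] + width / 2)
  structure(list(grid = grid, edges = edges, width = width,
                 prior_mass = prior, posterior_mass = post,
                 model = NULL, warnings = character()),
            class = "rb_belief")
}

# random beta-Bernoulli configurations for property sweeps
random_configs <- function(m, seed = 424242) {
  withr::with_seed(seed, {
    data.frame(
      a0 = stats::runif(m, 0.5, 10),
      b0 = stats::runif(m, 0.5, 10),
      n = sample(0:40, m, replace = TRUE)
    ) |> transform(s = stats::rbinom(m, n, 0.5),
                   psi0 = stats::runif(m, 0.05, 0.95))
  })
}
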