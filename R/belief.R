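# The model-agnostic relative belief engine.  Everything here operates on a
# discretized prior/posterior pair; the conjugate backends feed it exact cdf
# differences, the Monte Carlo path feeds it binned draws.

#' Discretize a conjugate model onto a grid
#'
#' Builds the paired prior/posterior cell masses on which the generic
#' relative belief machinery operates.  Cell masses are exact differences of
#' the distribution functions at the cell edges, then renormalized over the
#' grid.  The default bounds cover the central `1 - 1e-8` mass region of the
#' prior and posterior combined; if the requested bounds capture less than
#' `1 - 1e-6` of either distribution a warning is recorded in the object.
#'
#' @param model A [beta_bernoulli()] or [normal_known_var()] model.
#' @param grid_size Number of cells (>= 2); default 4096.
#' @param bounds Optional interval `c(lo, hi)` inside the parameter space.
#' @return An object of class `rb_belief`: `grid` (cell midpoints), `edges`,
#'   `width`, `prior_mass`, `posterior_mass`, the originating `model`, and
#'   any `warnings`.
#' @examples
#' b <- discretize(beta_bernoulli(4, 4, n = 20, s = 8), grid_size = 512)
#' sum(b$prior_mass); sum(b$posterior_mass)
#' @export
discretize <- function(model, grid_size = 4096L, bounds = NULL) {
  stopifnot(inherits(model, "rb_model"))
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stopf("'grid_size' must be >= 2")
  Fp <- .prior_cdf(model); Fq <- .posterior_cdf(model)
  Qp <- .prior_quantile(model); Qq <- .posterior_quantile(model)
  eps <- 1e-8
  if (is.null(bounds)) {
    lo <- min(Qp(eps / 2), Qq(eps / 2))
    hi <- max(Qp(1 - eps / 2), Qq(1 - eps / 2))
    bounds <- c(lo, hi)
  }
  if (length(bounds) != 2L || bounds[1L] >= bounds[2L])
    stopf("'bounds' must be an increasing interval")
  if (model$family == "bernoulli") {
    bounds[1L] <- max(bounds[1L], 0)
    bounds[2L] <- min(bounds[2L], 1)
  }
  edges <- seq(bounds[1L], bounds[2L], length.out = grid_size + 1L)
  prior_mass <- diff(Fp(edges))
  posterior_mass <- diff(Fq(edges))
  warnings <- character()
  cap_p <- sum(prior_mass); cap_q <- sum(posterior_mass)
  if (cap_p < 1 - 1e-6 || cap_q < 1 - 1e-6) {
    warnings <- sprintf(
      "bounds capture only %.8f of the prior and %.8f of the posterior mass",
      cap_p, cap_q)
    warning(warnings, call. = FALSE)
  }
  prior_mass <- pmax(prior_mass, 0) / cap_p
  posterior_mass <- pmax(posterior_mass, 0) / cap_q
  structure(
    list(grid = (edges[-1L] + edges[-length(edges)]) / 2,
         edges = edges, width = diff(edges)[1L],
         prior_mass = prior_mass, posterior_mass = posterior_mass,
         model = model, warnings = warnings),
    class = "rb_belief")
}

#' @export
print.rb_belief <- function(x, ...) {
  cat(sprintf("Discretized belief: %d cells on [%g, %g] (width %.3g)\n",
              length(x$grid), x$edges[1L], x$edges[length(x$edges)], x$width))
  invisible(x)
}

#' Relative belief function on a discretized belief
#'
#' Cellwise ratio of posterior to prior mass.  Cells with zero prior mass are
#' flagged as undefined rather than silently set to 0; posterior mass on a
#' zero-prior cell violates absolute continuity and is an error.
#'
#' @param belief An [discretize()] / [mc_marginal_belief()] `rb_belief`.
#' @return An object of class `rb_function`: `grid`, `edges`, `width`, `rb`
#'   (NA on undefined cells) and `defined` (logical mask).
#' @export
relative_belief <- function(belief) {
  stopifnot(inherits(belief, "rb_belief"))
  defined <- belief$prior_mass > 0
  if (any(belief$posterior_mass > 0 & !defined))
    stopf("posterior mass found on a cell with zero prior mass")
  rb <- rep(NA_real_, length(belief$grid))
  rb[defined] <- belief$posterior_mass[defined] / belief$prior_mass[defined]
  structure(
    list(grid = belief$grid, edges = belief$edges, width = belief$width,
         rb = rb, defined = defined),
    class = "rb_function")
}

#' @export
print.rb_function <- function(x, ...) {
  cat(sprintf("Relative belief function on %d cells; max RB %.4g at %.4g\n",
              length(x$grid), max(x$rb, na.rm = TRUE),
              x$grid[which.max(x$rb)]))
  invisible(x)
}

#' Least relative surprise estimate
#'
#' The grid value maximizing the relative belief ratio: the value with the
#' most evidence in its favour.  Ties (within the relative tie tolerance)
#' are broken to the smallest grid value and flagged via the `"tied"`
#' attribute.
#'
#' @param rbf An `rb_function`.
#' @return The maximizing parameter value, with attribute `tied` (logical).
#' @export
lrse <- function(rbf) {
  stopifnot(inherits(rbf, "rb_function"))
  if (!any(rbf$defined)) stopf("relative belief function defined on no cell")
  rb <- rbf$rb
  m <- max(rb, na.rm = TRUE)
  at <- which(rbf$defined & .rb_eq(rb, m))
  structure(rbf$grid[at[1L]], tied = length(at) > 1L)
}

#' Evidence-ordered (relative belief) credible region
#'
#' The gamma-credible region is the set of values whose relative belief
#' ratio is at least `c`, where `c` is the smallest threshold whose region
#' has posterior content at least `gamma`.  Because the region is ordered by
#' evidence, any value with more evidence than a member is itself a member,
#' and the least relative surprise estimate always lies inside.  On a grid
#' exact content `gamma` is generally unattainable, so the attained content
#' (>= `gamma`) is reported.
#'
#' @param rbf An `rb_function`.
#' @param belief The matching `rb_belief`.
#' @param gamma Requested posterior content in `[0, 1]`.
#' @return An `rb_region`: `intervals` (two-column matrix of outer cell-edge
#'   endpoints), `threshold` (the attained `c`), `content`, `gamma`, and the
#'   logical cell mask `cells`.
#' @export
credible_region <- function(rbf, belief, gamma) {
  stopifnot(inherits(rbf, "rb_function"), inherits(belief, "rb_belief"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stopf("'gamma' must be a probability")
  rb <- rbf$rb
  def <- rbf$defined
  post <- belief$posterior_mass
  # c = inf{ k : Pi(RB <= k | x) >= 1 - gamma }, over the attained rb values
  lev <- rb[def]
  o <- order(lev)
  cs <- cumsum(post[def][o])
  ls <- lev[o]
  pos <- which(!duplicated(ls, fromLast = TRUE))  # last index of each level
  u <- ls[pos]
  Fk <- cs[pos]
  ci <- which(Fk >= 1 - gamma - 1e-12)[1L]
  if (is.na(ci)) ci <- length(u)
  cthr <- u[ci]
  cells <- def & (rb >= cthr * (1 - .rb_tie_tol) - .rb_tie_tol * (cthr == 0))
  content <- sum(post[cells])
  # merge runs of selected cells into maximal intervals, outer cell edges
  r <- rle(cells)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  intervals <- cbind(lo = rbf$edges[starts[keep]], hi = rbf$edges[ends[keep] + 1L])
  structure(
    list(intervals = intervals, threshold = cthr, content = content,
         gamma = gamma, cells = cells),
    class = "rb_region")
}

#' @export
print.rb_region <- function(x, ...) {
  cat(sprintf("%.3g-relative belief credible region (attained content %.4f):\n",
              x$gamma, x$content))
  apply(x$intervals, 1L, function(iv)
    cat(sprintf("  (%.3f, %.3f)\n", iv[1L], iv[2L])))
  invisible(x)
}

#' Strength of the evidence at a hypothesized value
#'
#' The posterior probability that the true value has a relative belief ratio
#' no greater than that of `psi0`.  This calibrates the ratio: when
#' RB(psi0) > 1, a strength near 1 says few values are better supported, so
#' the evidence in favour is strong; when RB(psi0) < 1 a small strength says
#' most values are better supported and the evidence against is strong.  The
#' posterior mass of the exact-tie set `{RB = RB(psi0)}` is also returned;
#' on a continuum it bounds the strength from below.
#'
#' @param rbf An `rb_function`.
#' @param belief The matching `rb_belief`.
#' @param psi0 Hypothesized value; must fall on a cell with positive prior
#'   mass.
#' @return A list: `strength`, `tie_mass`, `rb_at_psi0` (the grid-cell
#'   ratio), and `cell` (the index of the cell containing `psi0`).
#' @export
strength <- function(rbf, belief, psi0) {
  stopifnot(inherits(rbf, "rb_function"), inherits(belief, "rb_belief"))
  i <- .locate_cell(rbf, psi0)
  rb0 <- rbf$rb[i]
  le <- rbf$defined & .rb_le(rbf$rb, rb0)
  tie <- rbf$defined & .rb_eq(rbf$rb, rb0)
  list(strength = sum(belief$posterior_mass[le]),
       tie_mass = sum(belief$posterior_mass[tie]),
       rb_at_psi0 = rb0, cell = i)
}

.locate_cell <- function(rbf, psi0) {
  edges <- rbf$edges
  if (!is.finite(psi0) || psi0 < edges[1L] || psi0 > edges[length(edges)])
    stopf("'psi0' = %g lies outside the discretized range [%g, %g]",
          psi0, edges[1L], edges[length(edges)])
  i <- findInterval(psi0, edges, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(rbf$grid))
  if (!rbf$defined[i])
    stopf("'psi0' = %g falls on a cell with zero prior mass", psi0)
  i
}

#' Bayes factor of a hypothesis set of cells
#'
#' Ratio of posterior to prior odds of the set; equals the relative belief
#' ratio of the set divided by that of its complement.  When either the set
#' or its complement has zero prior mass the odds are undefined and
#' `NA_real_` is returned (the relative belief ratio itself remains the
#' appropriate limiting measure of evidence for a single continuous point).
#'
#' @param belief An `rb_belief`.
#' @param cells Logical mask or integer indices of the hypothesis cells.
#' @return The Bayes factor, or `NA_real_` when undefined.
#' @export
bayes_factor <- function(belief, cells) {
  stopifnot(inherits(belief, "rb_belief"))
  if (is.logical(cells)) {
    stopifnot(length(cells) == length(belief$grid))
  } else {
    cells <- seq_along(belief$grid) %in% cells
  }
  p <- sum(belief$prior_mass[cells])
  q <- sum(belief$posterior_mass[cells])
  if (p <= 0 || p >= 1) return(NA_real_)
  if (q >= 1) return(Inf)
  (q / (1 - q)) / (p / (1 - p))
}

#' Monte Carlo belief for a marginal parameter
#'
#' Generic sampling path for an arbitrary parameter of interest
#' `psi = psi_map(theta)`: the prior of psi is estimated by binning prior
#' draws of theta mapped through `psi_map`; the posterior by
#' importance-weighting the same draws with the likelihood of the fixed
#' data, then normalizing.  Deterministic given `seed` (the global RNG state
#' is preserved).
#'
#' @param prior_sampler Function of one argument `m` returning `m` draws of
#'   theta from the prior.
#' @param likelihood Function mapping theta to a nonnegative likelihood
#'   value at the observed data (any fixed multiple will do).
#' @param psi_map Map from theta to the parameter of interest (default
#'   identity).
#' @param bins Number of cells for the psi grid.
#' @param draws Number of prior draws (>= `bins`).
#' @param seed Integer seed; required.
#' @return An `rb_belief` with an `ess` field (effective sample size of the
#'   importance weights); a warning is recorded when ESS < 50.
#' @examples
#' m <- beta_bernoulli(4, 4, n = 20, s = 8)
#' b <- mc_marginal_belief(
#'   prior_sampler = function(k) rbeta(k, 4, 4),
#'   likelihood = function(th) th^8 * (1 - th)^12,
#'   bins = 64, draws = 1e4, seed = 7)
#' @export
mc_marginal_belief <- function(prior_sampler, likelihood, psi_map = identity,
                               bins = 512L, draws = 1e5L, seed) {
  stopifnot(is.function(prior_sampler), is.function(likelihood),
            is.function(psi_map))
  bins <- as.integer(bins); draws <- as.integer(draws)
  if (draws < bins) stopf("'draws' must be at least 'bins'")
  if (missing(seed)) stopf("'seed' is required for the Monte Carlo path")
  res <- withr::with_seed(as.integer(seed), {
    theta <- prior_sampler(draws)
    w <- likelihood(theta)
    list(psi = psi_map(theta), w = w)
  })
  if (any(!is.finite(res$w)) || any(res$w < 0))
    stopf("likelihood returned nonfinite or negative values")
  rng <- range(res$psi)
  pad <- diff(rng) * 1e-9 + 1e-12
  edges <- seq(rng[1L] - pad, rng[2L] + pad, length.out = bins + 1L)
  idx <- findInterval(res$psi, edges, rightmost.closed = TRUE)
  prior_mass <- tabulate(idx, nbins = bins) / draws
  wn <- res$w / sum(res$w)
  posterior_mass <- vapply(seq_len(bins), function(b) sum(wn[idx == b]), 0)
  ess <- sum(res$w)^2 / sum(res$w^2)
  warnings <- character()
  if (ess < 50) {
    warnings <- sprintf("effective sample size of importance weights is %.1f (< 50)", ess)
    warning(warnings, call. = FALSE)
  }
  structure(
    list(grid = (edges[-1L] + edges[-length(edges)]) / 2, edges = edges,
         width = diff(edges)[1L], prior_mass = prior_mass,
         posterior_mass = posterior_mass, model = NULL,
         ess = ess, warnings = warnings),
    class = "rb_belief")
}
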