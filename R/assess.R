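# High-level evidence assessment: ties the grid engine to the closed-form
# conjugate backends and packages the result as a report.

#' Assess the evidence for a hypothesized parameter value
#'
#' Runs the full relative belief analysis for `H0: theta = psi0` under a
#' conjugate model: the relative belief ratio at `psi0` (the evidence), its
#' direction, the strength calibration (posterior probability that the true
#' value has no more evidence than `psi0`), the least relative surprise
#' estimate, the `gamma`-relative belief credible region, and a companion
#' Bayes factor for the grid cell containing `psi0`.
#'
#' Grid quantities come from [discretize()] at `grid_size` cells.  With
#' `refine = TRUE` (default) the strength, the region endpoints and the
#' estimate are additionally refined by root-finding on the closed-form
#' relative belief curve with exact distribution functions, removing the
#' grid resolution from the reported numbers; both sets are kept in the
#' report.
#'
#' @param model A [beta_bernoulli()] or [normal_known_var()] model carrying
#'   data.
#' @param psi0 Hypothesized parameter value.
#' @param gamma Credible-region content (default 0.95).
#' @param grid_size Number of grid cells (default 4096).
#' @param bounds Optional discretization bounds.
#' @param refine Refine grid quantities with exact root-finding?
#' @return An object of class `rb_evidence`.  Key fields: `rb` (exact
#'   ratio at `psi0`), `direction`, `strength`, `tie_mass`, `lrse`,
#'   `region` (two-column matrix), `attained_content`, `bayes_factor`.
#' @examples
#' m <- beta_bernoulli(4, 4, data = example_proportion_data())
#' ev <- assess_evidence(m, psi0 = 0.5, gamma = 0.95)
#' ev
#' @export
assess_evidence <- function(model, psi0, gamma = 0.95, grid_size = 4096L,
                            bounds = NULL, refine = TRUE) {
  stopifnot(inherits(model, "rb_model"))
  belief <- discretize(model, grid_size = grid_size, bounds = bounds)
  rbf <- relative_belief(belief)
  rb0 <- relative_belief_ratio(model, psi0)
  st <- strength(rbf, belief, psi0)
  est <- lrse(rbf)
  reg <- credible_region(rbf, belief, gamma)
  strength_val <- st$strength
  region <- reg$intervals
  content <- reg$content
  est_val <- as.numeric(est)
  if (refine && model$n > 0L) {
    strength_val <- .strength_exact(model, psi0)
    est_val <- .lrse_exact(model) %||% est_val
    if (gamma > 0 && gamma < 1) {
      reg_ex <- .region_exact(model, gamma)
      if (!is.null(reg_ex)) {
        region <- reg_ex$intervals
        content <- reg_ex$content
      }
    }
  }
  structure(
    list(psi0 = psi0, rb = rb0, direction = .rb_direction(rb0),
         strength = strength_val, tie_mass = st$tie_mass,
         grid_strength = st$strength, grid_rb = st$rb_at_psi0,
         lrse = est_val, lrse_tied = isTRUE(attr(est, "tied")),
         grid_lrse = as.numeric(est),
         region = region, gamma = gamma, attained_content = content,
         threshold = reg$threshold,
         bayes_factor = bayes_factor(belief, st$cell == seq_along(belief$grid)),
         grid_size = length(belief$grid), refined = refine && model$n > 0L,
         warnings = belief$warnings,
         model = model, belief = belief, rbf = rbf),
    class = "rb_evidence")
}

# Interval {theta : log RB(theta) > lrb0} inside the parameter space; the
# relative belief curve of a conjugate model with data is unimodal, so the
# level set is a single interval (possibly touching a space boundary).
.rb_level_interval <- function(model, lrb0) {
  sp <- .param_space(model)
  mode <- .lrse_exact(model)
  if (is.null(mode)) mode <- mean(sp)
  f <- function(t) relative_belief_ratio(model, t, log = TRUE) - lrb0
  fmode <- f(mode)
  if (fmode <= 0) return(NULL)  # level at or above the maximum
  lo <- if (f(sp[1L]) >= 0) sp[1L] else
    stats::uniroot(f, c(sp[1L], mode), tol = 1e-12)$root
  hi <- if (f(sp[2L]) >= 0) sp[2L] else
    stats::uniroot(f, c(mode, sp[2L]), tol = 1e-12)$root
  c(lo, hi)
}

# Exact strength: 1 - posterior content of the open interval where the
# relative belief ratio exceeds RB(psi0).
.strength_exact <- function(model, psi0) {
  lrb0 <- relative_belief_ratio(model, psi0, log = TRUE)
  iv <- .rb_level_interval(model, lrb0)
  if (is.null(iv)) return(1)  # psi0 attains the maximum evidence
  Fq <- .posterior_cdf(model)
  1 - (Fq(iv[2L]) - Fq(iv[1L]))
}

# Closed-form maximizer of the relative belief ratio (NULL when it sits on
# a parameter-space boundary, where the grid value is used instead).
.lrse_exact <- function(model) {
  if (model$n == 0L) return(NULL)
  if (model$family == "bernoulli") {
    if (model$s == 0L || model$s == model$n) return(NULL)
    return(model$s / model$n)  # RB is proportional to the likelihood of theta
  }
  h <- posterior_hyperparams(model)
  vp <- h[[2L]]; v0 <- model$tau0_sq
  if (vp >= v0) return(NULL)  # degenerate: log ratio not concave
  (h[[1L]] / vp - model$mu0 / v0) / (1 / vp - 1 / v0)
}

# Exact gamma-region: solve for the threshold whose level set has posterior
# content gamma, then report its endpoints.
.region_exact <- function(model, gamma) {
  mode <- .lrse_exact(model)
  if (is.null(mode)) return(NULL)
  Fq <- .posterior_cdf(model)
  lmax <- relative_belief_ratio(model, mode, log = TRUE)
  content_at <- function(lc) {
    iv <- .rb_level_interval(model, lc)
    if (is.null(iv)) return(0)
    Fq(iv[2L]) - Fq(iv[1L])
  }
  lo_lc <- lmax - 60
  if (content_at(lo_lc) < gamma) return(NULL)  # pathological; fall back to grid
  lc <- stats::uniroot(function(l) content_at(l) - gamma,
                       c(lo_lc, lmax - 1e-10), tol = 1e-12)$root
  iv <- .rb_level_interval(model, lc)
  list(intervals = cbind(lo = iv[1L], hi = iv[2L]),
       content = content_at(lc), threshold = exp(lc))
}

#' @export
print.rb_evidence <- function(x, ...) {
  cat("Relative belief evidence assessment\n")
  cat(sprintf("  H0: psi = %.3f\n", x$psi0))
  cat(sprintf("  RB(psi0 | x)      : %.3f  (evidence %s)\n", x$rb, x$direction))
  cat(sprintf("  strength          : %.3f  (posterior tie mass %.3g)\n",
              x$strength, x$tie_mass))
  cat(sprintf("  LRSE              : %.3f%s\n", x$lrse,
              if (x$lrse_tied) "  [tied maximum]" else ""))
  cat(sprintf("  %.2f-credible region (content %.3f):\n",
              x$gamma, x$attained_content))
  apply(x$region, 1L, function(iv)
    cat(sprintf("    (%.3f, %.3f)\n", iv[1L], iv[2L])))
  if (is.finite(x$bayes_factor))
    cat(sprintf("  Bayes factor (psi0 cell): %.3f\n", x$bayes_factor))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n    ")
  invisible(x)
}

#' Plot a relative belief curve with its strength construction
#'
#' Draws RB(theta | x) over the discretization grid, a horizontal line at
#' RB(psi0 | x), and shades the tail cells where the ratio does not exceed
#' it — the posterior content of the shaded set is the strength.
#'
#' @param x An `rb_evidence` report.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rb_evidence <- function(x, ...) {
  rbf <- x$rbf
  graphics::plot(rbf$grid, rbf$rb, type = "l", lwd = 2,
                 xlab = expression(theta), ylab = "RB", ...)
  graphics::abline(h = 1, col = "grey60", lty = 3)
  graphics::abline(h = x$grid_rb, col = "red3", lty = 2)
  sel <- rbf$defined & .rb_le(rbf$rb, x$grid_rb)
  if (any(sel))
    graphics::points(rbf$grid[sel], rbf$rb[sel], pch = ".", col = "red3")
  graphics::abline(v = x$psi0, col = "blue3", lty = 2)
  graphics::legend("topright", bty = "n", lty = c(2, 2), col = c("red3", "blue3"),
                   legend = c(sprintf("RB(psi0) = %.3f", x$rb),
                              sprintf("psi0 = %.3f", x$psi0)))
  invisible(x)
}

#' Serialize an evidence report to JSON
#'
#' @param report An `rb_evidence` report.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "rb_evidence"))
  obj <- list(
    psi0 = report$psi0, rb = report$rb, direction = report$direction,
    strength = report$strength, tie_mass = report$tie_mass,
    lrse = report$lrse,
    region = unname(lapply(seq_len(nrow(report$region)), function(i)
      c(report$region[i, 1L], report$region[i, 2L]))),
    gamma = report$gamma, attained_content = report$attained_content,
    bayes_factor = if (is.finite(report$bayes_factor)) report$bayes_factor else NULL,
    warnings = report$warnings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
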