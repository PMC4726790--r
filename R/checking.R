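# Prior-data conflict: the principle of empirical criticism applied to the
# prior.  The joint distribution of (theta, data) factors through a minimal
# sufficient statistic T as  prior x model = posterior x M_T x P(.|T):
# the posterior drives inference, the conditional P(.|T) drives model
# checking (out of scope here), and the prior predictive M_T of T is the
# piece that checks the prior — the three activities are never confounded.

#' Prior-data conflict check
#'
#' Computes the tail probability, in the prior predictive distribution of
#' the minimal sufficient statistic, of observing a statistic value no more
#' probable than the one observed: `M_T(m_T(t) <= m_T(t_obs))`.  A value
#' near 0 says the observed statistic sits where the prior predictive puts
#' almost no mass — the data arose from a parameter region the prior
#' disbelieves — and indicates prior-data conflict.  A value of 1 says the
#' statistic is maximally typical.
#'
#' For a discrete predictive this is the lowest-predictive-mass tail: the
#' masses are sorted and all values whose mass is at most (ties included)
#' that of `t_obs` are summed.  For the continuous normal predictive the
#' equivalent lowest-density tail is two-sided and available in closed form,
#' `2 * pnorm(-|t_obs - mean| / sd)`.
#'
#' The verdict is advisory: the tail probability is the primary output and
#' the cutoff is configurable.  A conflict should prompt reconsideration of
#' the prior, not a silent abort of inference.
#'
#' @param predictive A [prior_predictive()] `suffstat_dist`.
#' @param t_obs Observed statistic value.  A discrete value outside the
#'   support yields tail probability 0 with a warning.
#' @param threshold Advisory cutoff (default 0.05).
#' @return An `rb_conflict` report: `t_obs`, `tail_probability`,
#'   `threshold`, `verdict` (`"conflict"` / `"no-conflict"`).
#' @examples
#' pp <- prior_predictive(beta_bernoulli(4, 4), n = 20)
#' prior_data_conflict(pp, t_obs = 8)
#' @export
prior_data_conflict <- function(predictive, t_obs, threshold = 0.05) {
  stopifnot(inherits(predictive, "suffstat_dist"))
  if (!is.numeric(t_obs) || length(t_obs) != 1L || !is.finite(t_obs))
    stopf("'t_obs' must be a single finite number")
  if (predictive$kind == "discrete") {
    i <- which(abs(predictive$support - t_obs) < 1e-9)
    if (length(i) == 0L) {
      warning(sprintf("t_obs = %g is outside the predictive support", t_obs),
              call. = FALSE)
      tail <- 0
    } else {
      p0 <- predictive$mass[i[1L]]
      tail <- sum(predictive$mass[predictive$mass <= p0 * (1 + 1e-12)])
    }
  } else {
    tail <- 2 * stats::pnorm(-abs(t_obs - predictive$mean) / predictive$sd)
  }
  tail <- min(max(tail, 0), 1)
  structure(
    list(t_obs = t_obs, tail_probability = tail, threshold = threshold,
         verdict = if (tail < threshold) "conflict" else "no-conflict",
         factor = "M_T (prior predictive of the minimal sufficient statistic)"),
    class = "rb_conflict")
}

#' @export
print.rb_conflict <- function(x, ...) {
  cat(sprintf("Prior-data conflict check at t = %g\n", x$t_obs))
  cat(sprintf("  tail probability: %.4f (cutoff %.3g) -> %s\n",
              x$tail_probability, x$threshold, x$verdict))
  invisible(x)
}
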