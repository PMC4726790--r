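# The two-state worked example: a binary class (guilty/innocent,
# infected/healthy) observed through a binary trait.  Everything is in
# closed form, which makes it the cleanest illustration of why evidence
# (the relative belief ratio) and its strength must be reported together:
# a rare class with an informative trait always yields evidence *for* the
# positive class, but the strength exposes that evidence as weak — the
# protection against the prosecutor's fallacy.

#' Two-state trait classification setup
#'
#' A population splits into a positive class of proportion `epsilon` and a
#' negative class of proportion `1 - epsilon`; a binary trait occurs at
#' rate `psi1` among the negative class and `psi2` among the positive
#' class.  Observing the trait updates the two-point prior
#' `(1 - epsilon, epsilon)`.
#'
#' @param epsilon Prior proportion of the positive class, in (0, 1).
#' @param psi1 Trait rate among the negative class, in (0, 1).
#' @param psi2 Trait rate among the positive class, in (0, 1).
#' @param labels Length-2 character vector naming the negative and positive
#'   classes.
#' @return A `two_state` setup object.
#' @examples
#' ts <- two_state(0.01, 0.01, 0.99)
#' rb_class(ts, "positive")   # 50: strong evidence ...
#' posterior_class_probability(ts)  # 0.5: ... that is far from proof
#' @export
two_state <- function(epsilon, psi1, psi2,
                      labels = c("negative", "positive")) {
  for (nm in c("epsilon", "psi1", "psi2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stopf("'%s' must lie strictly in (0, 1)", nm)
  }
  stopifnot(length(labels) == 2L)
  structure(list(epsilon = epsilon, psi1 = psi1, psi2 = psi2,
                 labels = labels),
            class = "two_state")
}

#' Marginal probability of the trait
#'
#' `(1 - epsilon) * psi1 + epsilon * psi2`: the overall trait rate in the
#' population, and the prior predictive probability of observing the trait.
#'
#' @param setup A [two_state()] setup.
#' @return A probability.
#' @export
marginal_trait_probability <- function(setup) {
  stopifnot(inherits(setup, "two_state"))
  (1 - setup$epsilon) * setup$psi1 + setup$epsilon * setup$psi2
}

#' Posterior probability of the positive class given the trait
#'
#' `epsilon * psi2 / ((1 - epsilon) * psi1 + epsilon * psi2)`; converges to
#' 0 as `epsilon -> 0` with the trait rates fixed, however informative the
#' trait.
#'
#' @param setup A [two_state()] setup.
#' @return A probability.
#' @export
posterior_class_probability <- function(setup) {
  stopifnot(inherits(setup, "two_state"))
  setup$epsilon * setup$psi2 / marginal_trait_probability(setup)
}

#' Relative belief ratio of a class given the trait
#'
#' `psi2 / m` for the positive class and `psi1 / m` for the negative class,
#' with `m` the marginal trait probability.  The positive ratio exceeds 1
#' exactly when `psi2 > psi1` (the trait is informative), and then the
#' negative ratio is below 1: observing an informative trait is always
#' evidence for the positive class, no matter how small `epsilon`.
#'
#' @param setup A [two_state()] setup.
#' @param class `"positive"` or `"negative"`.
#' @return A nonnegative ratio.
#' @export
rb_class <- function(setup, class = c("positive", "negative")) {
  stopifnot(inherits(setup, "two_state"))
  class <- match.arg(class)
  m <- marginal_trait_probability(setup)
  if (class == "positive") setup$psi2 / m else setup$psi1 / m
}

#' Evidence report for the two-state problem
#'
#' Full relative belief analysis on the two-point parameter space: the
#' point estimate is the class with the larger relative belief ratio; the
#' `gamma`-credible region applies the evidence-ordered threshold rule to
#' the two points (as `epsilon -> 0` at fixed `gamma` the region grows to
#' both classes — the estimate loses all accuracy, which is the formal
#' protection against convicting on weak evidence).  Because the space has
#' only two points, the strength of `H0: positive` is reported both as the
#' general calibration (posterior probability of `{RB <= RB(positive)}`)
#' and as the plain posterior probability of the class; with two values the
#' latter is the more direct reading, and neither is suppressed.
#'
#' @param setup A [two_state()] setup.
#' @param gamma Credible content in (0, 1).
#' @return A `two_state_evidence` report.
#' @export
two_state_evidence <- function(setup, gamma = 0.95) {
  stopifnot(inherits(setup, "two_state"))
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1)
    stopf("'gamma' must lie in (0, 1)")
  e <- setup$epsilon
  prior <- c(1 - e, e)
  m <- marginal_trait_probability(setup)
  post <- c((1 - e) * setup$psi1, e * setup$psi2) / m
  rb <- post / prior
  names(prior) <- names(post) <- names(rb) <- setup$labels
  est <- setup$labels[which.max(rb)]
  # evidence-ordered region: c = inf{k : P(RB <= k | trait) >= 1 - gamma}
  o <- order(rb)
  Fk <- cumsum(post[o])
  ci <- which(Fk >= 1 - gamma - 1e-12)[1L]
  cthr <- rb[o][ci]
  region <- setup$labels[rb >= cthr * (1 - .rb_tie_tol)]
  rb_pos <- rb[2L]
  strength_eq1 <- sum(post[.rb_le(rb, rb_pos)])
  structure(
    list(setup = setup, prior = prior, posterior = post, rb = rb,
         estimate = est, region = region, gamma = gamma,
         attained_content = sum(post[setup$labels %in% region]),
         rb_positive = rb_pos,
         direction = .rb_direction(rb_pos),
         strength = strength_eq1,
         posterior_probability = post[[2L]]),
    class = "two_state_evidence")
}

#' @export
print.two_state_evidence <- function(x, ...) {
  s <- x$setup
  cat(sprintf("Two-state evidence (epsilon = %.3g, psi1 = %.3g, psi2 = %.3g)\n",
              s$epsilon, s$psi1, s$psi2))
  cat(sprintf("  RB(%s) = %.3f (%s), RB(%s) = %.3f\n",
              s$labels[2L], x$rb[[2L]], x$direction, s$labels[1L], x$rb[[1L]]))
  cat(sprintf("  estimate: %s\n", x$estimate))
  cat(sprintf("  %.2f-region: {%s} (content %.3f)\n", x$gamma,
              paste(x$region, collapse = ", "), x$attained_content))
  cat(sprintf("  strength of H0 '%s': %.3f; posterior probability: %.3f\n",
              s$labels[2L], x$strength, x$posterior_probability))
  invisible(x)
}
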