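# Shared numerical conventions.
#
# Relative belief ratios are compared with a *relative* tolerance: floating
# point ties (e.g. the exact symmetry RB(theta) = RB(1 - theta) under a
# symmetric prior) must be treated as ties or the strength calibration flips
# on symmetric inputs.

.rb_tie_tol <- 1e-9

# direction of evidence with the neutral band around RB = 1
.rb_direction <- function(rb) {
  if (abs(rb - 1) <= .rb_tie_tol) "neutral" else if (rb > 1) "favor" else "against"
}

# rb <= rb0 and rb == rb0 under the relative tie tolerance
.rb_le <- function(rb, rb0) rb <= rb0 * (1 + .rb_tie_tol) + .rb_tie_tol * (rb0 == 0)
.rb_eq <- function(rb, rb0) abs(rb - rb0) <= .rb_tie_tol * max(rb0, 1e-300)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
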