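#' Escape-probability learning update
#'
#' One learning event for an individual that escaped a predator attack. With
#' accelerating learning the escape probability grows by a proportion of its
#' current value, `min(cap, p * (1 + rate))`: successive updates give ever
#' larger absolute gains until the cap binds. With decelerating learning it
#' grows by a proportion of the remaining headroom, `p + rate * (cap - p)`:
#' gains shrink as the cap is approached and the cap is never exceeded.
#'
#' The update never decreases `p` (for `rate >= 0`) and never exceeds `cap`.
#' Vectorized over `p`.
#'
#' @param p Current escape probability (or vector thereof).
#' @param mode `"accelerating"` or `"decelerating"`.
#' @param rate Learning rate, a proportion `>= 0`.
#' @param cap Upper bound on the escape probability, in (0, 1).
#' @return Updated escape probability, same length as `p`.
#' @examples
#' learn_update(0.5, "accelerating", 0.1, 0.99)  # 0.55
#' learn_update(0.5, "decelerating", 0.1, 0.99)  # 0.549
#' @export
learn_update <- function(p, mode = c("accelerating", "decelerating"),
                         rate, cap) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, cap > 0, cap < 1, all(p <= cap), all(p >= 0))
  q <- if (mode == "accelerating") p * (1 + rate) else p + rate * (cap - p)
  pmin(q, cap)
}
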