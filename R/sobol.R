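# 1-D Sobol low-discrepancy sequence (Gray-code variant), used to schedule
# perturbation delays more uniformly than pseudo-random draws.

SOBOL_BITS <- 30L

#' One-dimensional Gray-code Sobol sequence
#'
#' Deterministic low-discrepancy sequence on \[0, 1). In one dimension the
#' direction numbers are the dyadic fractions 1/2, 1/4, ..., and the
#' Gray-code update XORs the previous integer state with the direction
#' number indexed by the lowest zero bit of the running counter. The first
#' elements are 0.5, 0.75, 0.25, 0.375, ...
#'
#' @param n Number of points to emit.
#' @param skip Number of initial points to discard (burn-in of the sequence).
#' @return Numeric vector of `n` values in \[0, 1).
#' @export
sobol_sequence <- function(n, skip = 0) {
  stopifnot(n >= 0, skip >= 0)
  total <- n + skip
  out <- numeric(total)
  x <- 0L
  v <- bitwShiftL(1L, SOBOL_BITS - seq_len(SOBOL_BITS))  # 2^(29), 2^(28), ...
  for (i in seq_len(total)) {
    c <- lowest_zero_bit(i - 1L)
    x <- bitwXor(x, v[c])
    out[i] <- x / 2^SOBOL_BITS
  }
  if (skip > 0) out <- out[-seq_len(skip)]
  out
}

lowest_zero_bit <- function(m) {
  c <- 1L
  while (bitwAnd(m, 1L) == 1L) {
    m <- bitwShiftR(m, 1L)
    c <- c + 1L
  }
  c
}

#' Sobol perturbation scheduler
#'
#' Stateful wrapper around [sobol_sequence()] used by the closed loop: emits
#' one delay (a phase in \[0, 1)) per scheduled perturbation, one
#' perturbation every `period_aps` APs. The first `skip` sequence points are
#' discarded once, at construction.
#'
#' @param skip Initial Sobol points to discard.
#' @param period_aps Deliver one pulse every this many APs (>= 2).
#' @return A `sobol_scheduler` list with fields `index`, `skip`,
#'   `period_aps`, and internal integer state.
#' @export
sobol_scheduler <- function(skip = 16, period_aps = 6) {
  stopifnot(period_aps >= 2)
  x <- 0L
  v <- bitwShiftL(1L, SOBOL_BITS - seq_len(SOBOL_BITS))
  for (i in seq_len(skip)) x <- bitwXor(x, v[lowest_zero_bit(i - 1L)])
  structure(
    list(index = as.integer(skip), skip = as.integer(skip),
         period_aps = as.integer(period_aps), state = x),
    class = "sobol_scheduler"
  )
}

#' Next scheduled delay from a Sobol scheduler
#'
#' Functional update: returns the next delay (phase in \[0, 1)) together with
#' the advanced scheduler. Two schedulers with the same `skip` and index emit
#' identical streams.
#'
#' @param sched A [sobol_scheduler()].
#' @return A list with elements `delay` and `scheduler`.
#' @export
sobol_next_delay <- function(sched) {
  stopifnot(inherits(sched, "sobol_scheduler"))
  v <- bitwShiftL(1L, SOBOL_BITS - seq_len(SOBOL_BITS))
  x <- bitwXor(sched$state, v[lowest_zero_bit(sched$index)])
  sched$state <- x
  sched$index <- sched$index + 1L
  list(delay = x / 2^SOBOL_BITS, scheduler = sched)
}
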