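# Beta-binomial probability functions, all in log space (log-beta /
# log-gamma); depths run to ~1e4 so factorials are never evaluated directly.

.check_bb_args <- function(x, size, params) {
  if (!inherits(params, "bb_params")) {
    stop("'params' must be a bb_params object")
  }
  if (!is.numeric(size) || any(size < 1) || any(size != floor(size))) {
    stop("'size' (sequencing depth N) must be a positive integer")
  }
  if (!is.numeric(x) || any(x != floor(x))) {
    stop("'x' must be an integer count")
  }
  if (any(x < 0) || any(x > size)) {
    stop("count 'x' must satisfy 0 <= x <= size")
  }
  invisible(TRUE)
}

#' Beta-binomial log probability mass
#'
#' Log of `choose(N, x) * B(x + a, N - x + b) / B(a, b)`, the probability of
#' observing `x` reads of an OTU among `N` total reads when the OTU
#' proportion itself varies between replicates according to a
#' `Beta(a, b)` distribution.
#'
#' @param x Integer count(s), `0 <= x <= size`.
#' @param size Sequencing depth N (total reads), a positive integer.
#' @param params A [bb_params] object.
#' @return Log-probability, vectorized over `x` (and `size` if of matching
#'   length).
#' @examples
#' bb_log_pmf(2, 10, bb_params(1, 1))  # log(1/11): uniform on 0..10
#' @export
bb_log_pmf <- function(x, size, params) {
  .check_bb_args(x, size, params)
  # ascending-difference form of the log beta ratio; stable up to the
  # near-binomial regime of huge (a + b)
  lchoose(size, x) + .lgamma_inc(params$a, x) +
    .lgamma_inc(params$b, size - x) -
    .lgamma_inc(params$a + params$b, size)
}

#' Probability of a zero count
#'
#' `P(X = 0) = B(a, b + N) / B(a, b)`, evaluated in log space. One minus
#' this value is the detection probability underlying the critical
#' proportion: an OTU is "detected" when its count is nonzero.
#'
#' @inheritParams bb_log_pmf
#' @return Probability in (0, 1), vectorized over `size`.
#' @export
bb_prob_zero <- function(size, params) {
  .check_bb_args(0, size, params)
  exp(.lgamma_inc(params$b, size) -
        .lgamma_inc(params$a + params$b, size))
}

#' Inclusive upper tail probability
#'
#' `P(X >= x)` under the beta-binomial distribution, the one-sided p-value
#' of the lung-enrichment outlier test. Computed by log-space summation of
#' the pmf over `x..N`; inclusive, so `x = 0` returns exactly 1.
#'
#' @inheritParams bb_log_pmf
#' @param x A single integer count.
#' @return Probability in (0, 1].
#' @export
bb_upper_tail <- function(x, size, params) {
  if (length(x) != 1L || length(size) != 1L) {
    stop("'x' and 'size' must be single values")
  }
  .check_bb_args(x, size, params)
  if (x == 0) {
    return(1)
  }
  k <- x:size
  lp <- bb_log_pmf(k, size, params)
  m <- max(lp)
  min(exp(m + log(sum(exp(lp - m)))), 1)
}

#' Sample beta-binomial counts
#'
#' Draws counts by compounding: a Beta(a, b) proportion per draw, then a
#' binomial count at the given depth.
#'
#' @param n Number of draws.
#' @param size Sequencing depth (single integer, or vector of length `n`).
#' @param params A [bb_params] object.
#' @return Integer vector of length `n`.
#' @export
rbb <- function(n, size, params) {
  .check_bb_args(0, size, params)
  rbinom(n, size, rbeta(n, params$a, params$b))
}
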