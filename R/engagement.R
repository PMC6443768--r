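#' Engagement probability after consecutive abstentions
#'
#' A cooperator who was exploited by a neighbor abstains from playing that
#' neighbor for a while.  After `t - 1` consecutive abstentions she agrees to
#' play again with probability `p_t = 1 - (1 - delta_d)^t`, the probability
#' that the exploiter has revised strategy at least once since the
#' exploitation, judged at the reciprocity-biased rate `delta_d`.  The state
#' index `t = 0` denotes full engagement and has `p_0 = 1` by convention
#' (cooperation is reciprocated immediately).
#'
#' @param t abstention-state index, integer `>= 0` (vectorized).
#' @param delta_d reciprocity-biased update rate in (0, 1).
#' @return `p_t`, strictly increasing in `t` with limit 1.
#' @examples
#' engagement_probability(0:3, 0.05)
#' @export
engagement_probability <- function(t, delta_d) {
  stopifnot(is.numeric(delta_d), length(delta_d) == 1L,
            delta_d > 0, delta_d < 1)
  if (any(t < 0) || any(t != floor(t))) {
    stop("`t` must contain non-negative integers")
  }
  ifelse(t == 0, 1, 1 - (1 - delta_d)^t)
}

#' Distribution of abstention-period lengths
#'
#' Probability that a cooperator abstains exactly `a` consecutive rounds
#' before going back to play an exploiter:
#' `delta_d` for `a = 0` and
#' `(1 - delta_d)^(a (a + 1) / 2) * (1 - (1 - delta_d)^(a + 1))` for
#' `a > 0` (the product of the successive abstention probabilities
#' `1 - p_t`, `t = 1, ..., a`, times the final engagement `p_{a+1}`).
#'
#' @param a abstention length, integer `>= 0` (vectorized).
#' @inheritParams engagement_probability
#' @return `Prob(a)`.
#' @examples
#' abstention_pmf(0:4, 0.05)
#' sum(abstention_pmf(0:500, 0.05)) # the law is normalized
#' @export
abstention_pmf <- function(a, delta_d) {
  stopifnot(is.numeric(delta_d), length(delta_d) == 1L,
            delta_d > 0, delta_d < 1)
  if (any(a < 0) || any(a != floor(a))) {
    stop("`a` must contain non-negative integers")
  }
  q <- 1 - delta_d
  ifelse(a == 0, delta_d, q^(a * (a + 1) / 2) * (1 - q^(a + 1)))
}

#' Mean abstention-period length
#'
#' The mean `<a>` of [abstention_pmf()].  No closed form is available; the
#' series `sum a * Prob(a)` is accumulated until the residual tail mass
#' drops below `tail_tol`.  The half-Gaussian factor
#' `(1 - delta_d)^(a(a+1)/2)` makes the tail collapse fast, so only
#' `O(1/sqrt(delta_d))` terms are needed.  `<a>` decreases monotonically in
#' `delta_d`, and the map `delta_d <-> <a>` is one-to-one (see
#' [delta_d_from_mean()]).
#'
#' @inheritParams engagement_probability
#' @param tail_tol residual tail mass at which the series is truncated.
#' @return The mean, with the number of terms used attached as attribute
#'   `"terms"`.
#' @examples
#' mean_abstention_length(0.05) # about 4.57 rounds
#' @export
mean_abstention_length <- function(delta_d, tail_tol = 1e-12) {
  stopifnot(is.numeric(delta_d), length(delta_d) == 1L,
            delta_d > 0, delta_d < 1, tail_tol > 0)
  q <- 1 - delta_d
  # (1-dd)^(a(a+1)/2) < tail_tol  bounds the tail; solve the quadratic in a
  L <- log(tail_tol) / log(q)
  a_max <- ceiling((-1 + sqrt(1 + 8 * L)) / 2) + 2
  repeat {
    a <- 0:a_max
    pmf <- abstention_pmf(a, delta_d)
    if (1 - sum(pmf) < tail_tol) break
    a_max <- a_max * 2L
  }
  structure(sum(a * pmf), terms = length(a))
}

#' Invert the mean abstention length
#'
#' Numeric inverse of [mean_abstention_length()]: the biased update rate
#' `delta_d` whose abstention-length distribution has the requested mean.
#' Well defined because the mean is strictly decreasing in `delta_d`.
#'
#' @param a_mean target mean abstention length, positive.
#' @return `delta_d` in (0, 1).
#' @export
delta_d_from_mean <- function(a_mean) {
  stopifnot(is.numeric(a_mean), length(a_mean) == 1L, a_mean > 0)
  f <- function(x) as.numeric(mean_abstention_length(x)) - a_mean
  lo <- 1e-8
  if (f(1 - 1e-9) > 0 || f(lo) < 0) stop("`a_mean` outside the attainable range")
  uniroot(f, c(lo, 1 - 1e-9), tol = 1e-12)$root
}

#' Sample abstention-period lengths
#'
#' Draws lengths by the sequential mechanism the agents use: after `t - 1`
#' abstentions, abstain once more with probability `1 - p_t`.  The empirical
#' distribution converges to [abstention_pmf()].  Uses R's global RNG, so
#' `set.seed()` makes draws reproducible.
#'
#' @param n number of samples.
#' @inheritParams engagement_probability
#' @return Integer vector of `n` abstention lengths.
#' @export
sample_abstention_length <- function(n, delta_d) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  stopifnot(delta_d > 0, delta_d < 1)
  n <- as.integer(n)
  a <- integer(n)
  active <- rep(TRUE, n)
  t <- 1L
  while (any(active)) {
    idx <- which(active)
    p_t <- 1 - (1 - delta_d)^t
    plays <- runif(length(idx)) < p_t
    a[idx[plays]] <- t - 1L
    active[idx[plays]] <- FALSE
    t <- t + 1L
  }
  a
}
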