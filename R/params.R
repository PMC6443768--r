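#' Model parameters
#'
#' Bundles and validates the parameters of the model: the prisoner's-dilemma
#' return `r` (benefit-to-cost ratio, the cost `c = 1` being the monetary
#' unit), the strategy-update rate `delta` (per-round revision probability;
#' `1/delta` is the agents' inertia), the direct-reciprocity strength `d`,
#' and the predictive horizon `h`.  The derived reciprocity-biased update
#' rate is `delta_d = (1 - d) * delta`: cooperators decide whether to resume
#' play with a past exploiter as if the exploiter revised strategy at rate
#' `delta_d` rather than `delta`, so `d > 0` (super-normal reciprocity)
#' lengthens abstention periods and `d < 0` (sub-normal) shortens them.
#'
#' Admissible reciprocity lies strictly inside `(d_min, d_max)` with
#' `d_min = -(1/delta - 1)` (no reciprocity, `delta_d = 1`, unconditional
#' cooperation) and `d_max = 1` (broken links, `delta_d = 0`); both extremes
#' are rejected.  A warning (not an error) is issued when `delta * h > 0.3`,
#' the regime in which forecasts ignoring neighbors' strategy revisions stop
#' being a good approximation.
#'
#' @param r PD return (benefit-to-cost ratio), positive.
#' @param delta strategy-update probability per game round, in (0, 1).
#' @param d direct-reciprocity strength, strictly inside `(d_min, d_max)`;
#'   `d = 0` is normal reciprocity.
#' @param h predictive horizon: integer number of future rounds `>= 1`, or
#'   `Inf` for the infinite-horizon decision rule of the closed-form
#'   persistence condition (see [remain_C_threshold()]).
#' @param gain_noise_sd,decision_flip_prob bounded-rationality knobs, see
#'   [perturb_rationality()].  Defaults 0 recover the exact model.
#' @return An object of class `"pd_params"`: a list with the inputs plus the
#'   derived `delta_d`, `d_min`, `d_max`.
#' @examples
#' p <- model_params(r = 3, delta = 0.05, d = 0, h = 2)
#' p$delta_d
#' @export
model_params <- function(r, delta = 0.05, d = 0, h = 2,
                         gain_noise_sd = 0, decision_flip_prob = 0) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  if (r <= 0) stop("`r` (PD return b/c) must be positive")
  stopifnot(is.numeric(delta), length(delta) == 1L)
  if (delta <= 0 || delta >= 1) stop("`delta` must lie strictly in (0, 1)")
  d_min <- -(1 / delta - 1)
  d_max <- 1
  stopifnot(is.numeric(d), length(d) == 1L)
  if (d <= d_min || d >= d_max) {
    stop(sprintf(
      "`d` must lie strictly inside (d_min, d_max) = (%.6g, 1); the extremes are unadmissible",
      d_min
    ))
  }
  delta_d <- (1 - d) * delta
  stopifnot(delta_d > 0, delta_d < 1)
  if (!(is.infinite(h) && h > 0)) {
    if (!is.numeric(h) || length(h) != 1L || h < 1 || h != as.integer(h)) {
      stop("`h` must be a positive integer or Inf")
    }
    h <- as.integer(h)
    if (delta * h > 0.3 + 1e-9) {
      warning(sprintf(
        "delta * h = %.3g > 0.3: forecasts that freeze neighbors' strategies become unreliable",
        delta * h
      ))
    }
  } else {
    h <- Inf
  }
  stopifnot(gain_noise_sd >= 0)
  if (decision_flip_prob < 0 || decision_flip_prob >= 0.5) {
    stop("`decision_flip_prob` must lie in [0, 0.5)")
  }
  structure(
    list(
      r = r, delta = delta, d = d, h = h,
      delta_d = delta_d, d_min = d_min, d_max = d_max,
      gain_noise_sd = gain_noise_sd,
      decision_flip_prob = decision_flip_prob
    ),
    class = "pd_params"
  )
}

#' @export
print.pd_params <- function(x, ...) {
  cat("PD model parameters\n")
  cat(sprintf("  r = %g (benefit-to-cost, c = 1)\n", x$r))
  cat(sprintf("  delta = %g (update rate; inertia 1/delta = %g rounds)\n",
              x$delta, 1 / x$delta))
  cat(sprintf("  d = %g in (%.4g, 1)  ->  delta_d = %g\n",
              x$d, x$d_min, x$delta_d))
  cat(sprintf("  h = %s (predictive horizon)\n", format(x$h)))
  cat(sprintf("  mean abstention length <a> = %.4g rounds\n",
              mean_abstention_length(x$delta_d)))
  if (x$gain_noise_sd > 0 || x$decision_flip_prob > 0) {
    cat(sprintf("  bounded rationality: gain noise sd = %g, flip prob = %g\n",
                x$gain_noise_sd, x$decision_flip_prob))
  }
  invisible(x)
}

#' Bounded-rationality perturbation of the revision rule
#'
#' Returns a copy of `params` whose revision decisions are perturbed: each
#' computed expected gain is multiplied by `(1 + e)` with
#' `e ~ N(0, gain_noise_sd^2)` (a computation-error model), and the final
#' keep/switch decision is inverted with probability `decision_flip_prob`
#' (an irrationality model).  Setting both to zero recovers the exact model,
#' and in that case simulation trajectories are bit-identical to the
#' unperturbed ones at equal seeds (no extra random draws are consumed).
#' With a positive flip probability neither monomorphic state is absorbing,
#' so simulations run to their round limit.
#'
#' @param params a [model_params()] object.
#' @param gain_noise_sd standard deviation of the multiplicative gain noise,
#'   `>= 0`.
#' @param decision_flip_prob probability of inverting a revision decision,
#'   in `[0, 0.5)`.
#' @return A `"pd_params"` object with the two knobs set.
#' @export
perturb_rationality <- function(params, gain_noise_sd = 0,
                                decision_flip_prob = 0) {
  stopifnot(inherits(params, "pd_params"))
  model_params(
    r = params$r, delta = params$delta, d = params$d, h = params$h,
    gain_noise_sd = gain_noise_sd, decision_flip_prob = decision_flip_prob
  )
}
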