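#' What a revising agent can infer about her neighbors
#'
#' Perception derives exclusively from the pair of directed abstention
#' counters on each edge.  For a revising cooperator `i`: `t_ij > 0` means
#' `j` exploited her at their last played interaction, so `j` is considered
#' a defector in state `t_ij` (possibly wrongly, if `j` has changed since);
#' `t_ij = 0` with `t_ji > 0` means `j` is a cooperator abstaining from `i`,
#' correctly perceived a C in state `t_ji`; both zero means mutual
#' cooperation at the last round, a C in state 0.  For a revising defector:
#' `t_ji > 0` identifies an exploited (hence cooperating) neighbor in state
#' `t_ji`, and `t_ji = 0` a fellow defector -- defectors have full
#' information, cooperators can only under-count their C-neighbors.
#'
#' @param state a `"pd_state"`.
#' @param agent node index.
#' @return A data frame with one row per neighbor: `neighbor`, `perceived`
#'   (`"C"`/`"D"`), and the `state` index seeding the forecast recursions.
#' @export
perceive_neighbors <- function(state, agent) {
  stopifnot(inherits(state, "pd_state"))
  net <- state$network
  if (agent < 1 || agent > net$N) stop("unknown agent index")
  nbs <- net$adj[[agent]]
  out <- data.frame(neighbor = nbs, perceived = character(length(nbs)),
                    state = integer(length(nbs)))
  own_C <- state$strategy[agent] == "C"
  for (k in seq_along(nbs)) {
    tt <- .state_t(state, agent, nbs[k])
    if (own_C) {
      if (tt["t_ij"] > 0L) {
        out$perceived[k] <- "D"; out$state[k] <- tt["t_ij"]
      } else {
        out$perceived[k] <- "C"; out$state[k] <- tt["t_ji"]
      }
    } else {
      if (tt["t_ji"] > 0L) {
        out$perceived[k] <- "C"; out$state[k] <- tt["t_ji"]
      } else {
        out$perceived[k] <- "D"; out$state[k] <- 0L
      }
    }
  }
  out
}

#' Forecast recursions over the predictive horizon
#'
#' `forecast_play_with_defector()` gives the probabilities
#' `P_CD^1, ..., P_CD^h` that a cooperator plays a (presumed permanent)
#' defector at each round of the horizon, from the recursion
#' `P^{t+1} = P^t delta_d + (1 - P^t)((1 - delta_d) P^t + delta_d)`
#' initialized at `P^1 = p_{t_init}`: a played round means exploitation and
#' re-engagement at `p_1 = delta_d`, an abstained round advances the
#' engagement by one state.  The sequence converges to the infinite-horizon
#' limit [p_cd_limit()] from any initialization.
#'
#' `forecast_play_with_cooperator()` gives `P_CC^1, ..., P_CC^h` for a
#' neighbor known to be a cooperator currently in abstention state `t_ji`:
#' `P^{t+1} = P^t + (1 - P^t) p_{t_ji + t}`, since once the neighbor plays
#' and finds cooperation she re-engages fully and plays ever after.
#'
#' @param t_init,t_ji initial abstention-state index (`>= 0`; state 0 is
#'   full engagement, `p_0 = 1`).
#' @param delta_d reciprocity-biased update rate in (0, 1).
#' @param h horizon, integer `>= 1`.
#' @return Numeric vector of length `h`.
#' @examples
#' forecast_play_with_defector(0, 0.05, h = 2) # c(1, 0.05)
#' forecast_play_with_cooperator(1, 0.05, h = 2) # c(0.05, 0.142625)
#' @export
forecast_play_with_defector <- function(t_init, delta_d, h) {
  stopifnot(h >= 1, h == floor(h), t_init >= 0)
  P <- engagement_probability(t_init, delta_d)
  out <- numeric(h)
  out[1L] <- P
  for (t in seq_len(h - 1L)) {
    P <- P * delta_d + (1 - P) * ((1 - delta_d) * P + delta_d)
    out[t + 1L] <- P
  }
  out
}

#' @rdname forecast_play_with_defector
#' @export
forecast_play_with_cooperator <- function(t_ji, delta_d, h) {
  stopifnot(h >= 1, h == floor(h), t_ji >= 0)
  P <- engagement_probability(t_ji, delta_d)
  out <- numeric(h)
  out[1L] <- P
  for (t in seq_len(h - 1L)) {
    P <- P + (1 - P) * engagement_probability(t_ji + t, delta_d)
    out[t + 1L] <- P
  }
  out
}

#' Infinite-horizon exploitation probability
#'
#' The limit `P_CD^inf` of [forecast_play_with_defector()]: the probability
#' that a cooperator who remains C forever gets exploited in a far-future
#' round by a neighbor who remains D forever.  Closed form
#' `(sqrt(4 delta_d - 3 delta_d^2) - delta_d) / (2 (1 - delta_d))`,
#' increasing from 0 to 1 with `delta_d` and approximately
#' `sqrt(delta_d)` for small `delta_d`; equals 1 at `delta_d = 1`
#' (no reciprocity).
#'
#' @param delta_d reciprocity-biased update rate in (0, 1].
#' @return `P_CD^inf`.
#' @export
p_cd_limit <- function(delta_d) {
  stopifnot(is.numeric(delta_d), all(delta_d > 0), all(delta_d <= 1))
  ifelse(delta_d == 1, 1,
         0.5 * (sqrt(4 * delta_d - 3 * delta_d^2) - delta_d) / (1 - delta_d))
}

# Horizon-summed forecast tables Sum_t P_CC^t(s) and Sum_t P_CD^t(s) for all
# states s = 0..t_cap at once (vectorized over s); single source of truth for
# both the R-level gains and the compiled simulation core.
.forecast_tables <- function(delta_d, h, t_cap) {
  s <- 0:t_cap
  p <- engagement_probability(s, delta_d)
  P <- p; SCD <- P
  for (t in seq_len(h - 1L)) {
    P <- P * delta_d + (1 - P) * ((1 - delta_d) * P + delta_d)
    SCD <- SCD + P
  }
  P <- p; SCC <- P
  for (t in seq_len(h - 1L)) {
    pn <- 1 - (1 - delta_d)^(s + t) # p_{s+t}; s + t >= 1 so no p_0 case
    P <- P + (1 - P) * pn
    SCC <- SCC + P
  }
  list(p = p, scc = SCC, scd = SCD, t_cap = t_cap)
}

# counters are clamped where the engagement probability is 1 up to 1e-12
.t_cap_for <- function(delta_d, tol = 1e-12) {
  min(200000L, as.integer(ceiling(log(tol) / log(1 - delta_d))) + 1L)
}

.sum_forecast <- function(fun, state0, delta_d, h) sum(fun(state0, delta_d, h))

#' Expected payoff gain of switching strategy
#'
#' The heart of the predictive update rule.  A revising cooperator compares
#' the income expected over the next `h` rounds from remaining C with that
#' from behaving as D, neighbor strategies frozen at their perceived values:
#'
#' `gain_C = -r * S + sum_CC + sum_CD(D-neighbors)`, where
#' `S = sum_CC - sum_CD(C-neighbors)` aggregates, over perceived
#' cooperators, the horizon sums of [forecast_play_with_cooperator()] minus
#' [forecast_play_with_defector()] (each initialized at the neighbor's
#' engagement state `t_ji` toward the reviser), and the last term sums the
#' defector forecast at the reviser's own state `t_ij` over perceived
#' defectors.  Positive means the cooperator expects to gain by defecting.
#'
#' A revising defector evaluates `gain_D = r * S - sum_CC - k_D *
#' sum_CD(1)`, the defector forecasts toward her D-neighbors starting at
#' state 1 because, on switching, she would engage them at `p_1 = delta_d`
#' to avoid immediate exploitation.  Positive means the defector expects to
#' gain by cooperating.
#'
#' For `h = 1` the two forecasts coincide at their initialization, so
#' `gain_C > 0` and `gain_D < 0` whatever `r` and the neighborhood: myopic
#' best response always defects.  For `h >= 2` and at least one perceived
#' C-neighbor both gains are affine in `r`, decreasing (C) and increasing
#' (D), which is what creates the persistence and fixation thresholds.
#'
#' @param perceptions data frame from [perceive_neighbors()] (columns
#'   `perceived` and `state`).
#' @param r PD return.
#' @param h horizon, finite integer `>= 1`.
#' @param delta_d reciprocity-biased update rate.
#' @return The expected gain (cost units over the whole horizon).
#' @export
expected_gain_C <- function(perceptions, r, h, delta_d) {
  stopifnot(is.finite(h), h >= 1)
  isC <- perceptions$perceived == "C"
  scc <- sum(vapply(perceptions$state[isC], .sum_forecast,
                    numeric(1), fun = forecast_play_with_cooperator,
                    delta_d = delta_d, h = h))
  scd_c <- sum(vapply(perceptions$state[isC], .sum_forecast,
                      numeric(1), fun = forecast_play_with_defector,
                      delta_d = delta_d, h = h))
  scd_d <- sum(vapply(perceptions$state[!isC], .sum_forecast,
                      numeric(1), fun = forecast_play_with_defector,
                      delta_d = delta_d, h = h))
  -r * (scc - scd_c) + scc + scd_d
}

#' @rdname expected_gain_C
#' @export
expected_gain_D <- function(perceptions, r, h, delta_d) {
  stopifnot(is.finite(h), h >= 1)
  isC <- perceptions$perceived == "C"
  scc <- sum(vapply(perceptions$state[isC], .sum_forecast,
                    numeric(1), fun = forecast_play_with_cooperator,
                    delta_d = delta_d, h = h))
  scd_c <- sum(vapply(perceptions$state[isC], .sum_forecast,
                      numeric(1), fun = forecast_play_with_defector,
                      delta_d = delta_d, h = h))
  k_D <- sum(!isC)
  r * (scc - scd_c) - scc -
    k_D * sum(forecast_play_with_defector(1L, delta_d, h))
}

#' Revise one agent's strategy
#'
#' Computes the relevant expected gain from the agent's perceptions and
#' switches strategy iff it is strictly positive (a tie keeps the current
#' strategy); side effects on the engagement counters are applied through
#' [apply_strategy_change()].  With `h = Inf` the closed-form condition of
#' [remain_C_threshold()] is used instead: a cooperator remains C iff
#' `r >= threshold(k, k_C)` and a defector switches to C iff
#' `r > threshold(k, k_C)` (the strict/non-strict pair is the
#' keep-on-tie convention); an agent perceiving no cooperating neighbor
#' defects, or stays a defector, unconditionally.
#'
#' @param state a `"pd_state"`.
#' @param agent node index.
#' @param params a [model_params()] object.
#' @return List with `decision` (`"keep"` or `"switch"`), the `gain` (NA
#'   for `h = Inf`), and the updated `state`.
#' @export
revise <- function(state, agent, params) {
  stopifnot(inherits(state, "pd_state"), inherits(params, "pd_params"))
  per <- perceive_neighbors(state, agent)
  own <- state$strategy[agent]
  k_C <- sum(per$perceived == "C")
  if (is.infinite(params$h)) {
    gain <- NA_real_
    if (k_C == 0L) {
      switch_now <- own == "C"
    } else {
      thr <- remain_C_threshold(nrow(per), k_C, params$delta_d)
      switch_now <- if (own == "C") params$r < thr else params$r > thr
    }
  } else {
    gain <- if (own == "C") {
      expected_gain_C(per, params$r, params$h, params$delta_d)
    } else {
      expected_gain_D(per, params$r, params$h, params$delta_d)
    }
    g <- gain
    if (params$gain_noise_sd > 0) g <- g * (1 + stats::rnorm(1, 0, params$gain_noise_sd))
    switch_now <- g > 0
    if (params$decision_flip_prob > 0 && runif(1) < params$decision_flip_prob) {
      switch_now <- !switch_now
    }
  }
  if (switch_now) {
    state <- apply_strategy_change(state, agent, if (own == "C") "D" else "C")
  }
  list(decision = if (switch_now) "switch" else "keep",
       gain = gain, state = state)
}

#' Infinite-horizon persistence threshold
#'
#' With an infinite predictive horizon, a cooperator of degree `k`
#' perceiving `k_C` cooperating neighbors remains C if and only if
#' `r > 1 + (k / k_C) * P / (1 - P)` with `P = ` [p_cd_limit()]; the
#' defector-to-cooperator switch obeys the same condition.  `k_C = 0` gives
#' no finite threshold (such an agent always defects), returned as `Inf`.
#'
#' @param k degree (`k >= k_C`).
#' @param k_C perceived number of cooperating neighbors.
#' @param delta_d reciprocity-biased update rate.
#' @return The `r`-threshold.
#' @export
remain_C_threshold <- function(k, k_C, delta_d) {
  stopifnot(k >= 1, k_C >= 0, k >= k_C)
  if (k_C == 0) return(Inf)
  P <- p_cd_limit(delta_d)
  1 + (k / k_C) * P / (1 - P)
}

#' Fixation thresholds
#'
#' `fixation_threshold_infinite()` is the harshest case of
#' [remain_C_threshold()] -- the node of maximal degree with a single
#' perceived cooperating neighbor -- and guarantees, for an infinite
#' horizon, that every cooperator keeps cooperating and every defector with
#' a C-neighbor switches: `R = 1 + k_max * P / (1 - P)`.
#'
#' `fixation_threshold_bound()` is its finite-horizon counterpart, computed
#' numerically: both expected gains are affine in `r` for a fixed
#' neighborhood, so for the worst-case neighborhood (degree `k_max`, one
#' perceived cooperator, abstention states chosen adversarially over the
#' reachable set -- C-neighbor states in `{0, 1}`, D-neighbor states up to
#' the engagement saturation point) the zero of each gain is solved and the
#' largest is returned.  It approaches the infinite-horizon value as `h`
#' grows and is conservative with respect to the empirically estimated
#' `r_fix` of [sweep_return()].
#'
#' @param k_max maximal degree in the network.
#' @param delta_d reciprocity-biased update rate.
#' @param h horizon, integer `>= 2`.
#' @param state_tol saturation tolerance bounding the adversarial
#'   D-neighbor state range.
#' @return The threshold return.
#' @examples
#' fixation_threshold_infinite(4, 0.05) # about 2.03
#' @export
fixation_threshold_infinite <- function(k_max, delta_d) {
  stopifnot(k_max >= 1)
  P <- p_cd_limit(delta_d)
  1 + k_max * P / (1 - P)
}

#' @rdname fixation_threshold_infinite
#' @export
fixation_threshold_bound <- function(k_max, h, delta_d, state_tol = 1e-6) {
  stopifnot(is.finite(h), h >= 2, h == floor(h), k_max >= 1)
  t_adv <- as.integer(ceiling(log(state_tol) / log(1 - delta_d)))
  tab <- .forecast_tables(delta_d, as.integer(h), max(t_adv, 2L))
  scd_max <- max(tab$scd[2:(t_adv + 1L)]) # adversarial D-neighbor state
  worst <- -Inf
  for (tc in 0:1) {
    scc <- tab$scc[tc + 1L]
    scd <- tab$scd[tc + 1L]
    denom <- scc - scd
    stopifnot(denom > 0) # holds for h >= 2
    r_keep_C <- (scc + (k_max - 1) * scd_max) / denom
    r_switch_D <- (scc + (k_max - 1) * tab$scd[2L]) / denom
    worst <- max(worst, r_keep_C, r_switch_D)
  }
  worst
}

#' Threshold report
#'
#' One table row per requested maximal degree: the infinite-horizon
#' exploitation probability, the infinite-horizon fixation threshold, and
#' the finite-horizon bound.
#'
#' @inheritParams fixation_threshold_infinite
#' @param h horizon (finite) used for the bound.
#' @return A data frame with columns `k_max`, `h`, `delta_d`, `P_CD_inf`,
#'   `R_fix_inf`, `R_fix_bound`.
#' @export
threshold_report <- function(k_max, h, delta_d) {
  data.frame(
    k_max = k_max, h = h, delta_d = delta_d,
    P_CD_inf = p_cd_limit(delta_d),
    R_fix_inf = vapply(k_max, fixation_threshold_infinite, numeric(1),
                       delta_d = delta_d),
    R_fix_bound = vapply(k_max, fixation_threshold_bound, numeric(1),
                         h = h, delta_d = delta_d)
  )
}
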