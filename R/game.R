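#' Stage payoffs of a single pairwise encounter
#'
#' With cost `c = 1` and benefit `b = r`, a played PD gives `(r - 1, r - 1)`
#' to mutual cooperation, `(-1, r)` to a cooperator facing a defector, and
#' `(0, 0)` to mutual defection.  Abstention (action `"A"`) costs and yields
#' nothing to either opponent, whatever the other action.
#'
#' @param action_i,action_j actions in `"C"`, `"D"`, `"A"`.
#' @param r PD return.
#' @return Numeric vector `c(payoff_i, payoff_j)`.
#' @examples
#' stage_payoffs("C", "D", r = 3) # c(-1, 3)
#' @export
stage_payoffs <- function(action_i, action_j, r) {
  acts <- c("C", "D", "A")
  if (!(action_i %in% acts) || !(action_j %in% acts)) {
    stop("actions must be one of 'C', 'D', 'A'")
  }
  stopifnot(r > 0)
  if (action_i == "A" || action_j == "A") return(c(0, 0))
  pay <- function(a, b) {
    if (a == "C" && b == "C") r - 1 else if (a == "C") -1 else if (b == "C") r else 0
  }
  c(pay(action_i, action_j), pay(action_j, action_i))
}

#' Population state
#'
#' Bundles the per-agent strategies with the dynamic engagement weights of
#' the static network.  Engagement is stored sparsely as directed abstention
#' counters `t_ij >= 0` per edge (one per direction), with
#' `p_ij = engagement_probability(t_ij, delta_d)`; counters start at 0
#' (full engagement, `p = 1`) on every edge.  Invariants maintained by
#' [play_round()] and [apply_strategy_change()]: counters exist only on
#' network edges; on every edge at least one direction is 0; defectors hold
#' counter 0 toward all neighbors.
#'
#' @param network a [pd_network()].
#' @param strategies `"pd_strategies"` object or `"C"`/`"D"` character vector.
#' @return A `"pd_state"` object: `network`, `strategy`, directed counters
#'   `t_fwd`/`t_bwd` (aligned with `network$edges`), `round`, and the
#'   per-agent payoffs of the last played round.
#' @export
population_state <- function(network, strategies) {
  stopifnot(inherits(network, "pd_network"))
  s <- if (inherits(strategies, "pd_strategies")) strategies$strategy else strategies
  stopifnot(length(s) == network$N, all(s %in% c("C", "D")))
  m <- nrow(network$edges)
  structure(
    list(
      network = network, strategy = s,
      t_fwd = integer(m), t_bwd = integer(m),
      round = 0L, payoffs = numeric(network$N)
    ),
    class = "pd_state"
  )
}

#' @export
print.pd_state <- function(x, ...) {
  cat(sprintf("pd_state: round %d, %d/%d C's, %d inhibited directed edges\n",
              x$round, sum(x$strategy == "C"), x$network$N,
              sum(x$t_fwd > 0) + sum(x$t_bwd > 0)))
  invisible(x)
}

# directed counter lookup used by the prediction module
.state_t <- function(state, i, j) {
  e <- which((state$network$edges[, 1L] == min(i, j)) &
               (state$network$edges[, 2L] == max(i, j)))
  if (!length(e)) stop("no edge between ", i, " and ", j)
  if (i < j) c(t_ij = state$t_fwd[e], t_ji = state$t_bwd[e])
  else c(t_ij = state$t_bwd[e], t_ji = state$t_fwd[e])
}

#' Check the engagement-matrix invariants
#'
#' Errors if a directed counter is negative, if both directions of an edge
#' are inhibited at once, or if a defector holds a nonzero counter.
#'
#' @param state a `"pd_state"`.
#' @return `state`, invisibly.
#' @export
validate_state <- function(state) {
  stopifnot(inherits(state, "pd_state"))
  if (any(state$t_fwd < 0) || any(state$t_bwd < 0)) stop("negative abstention counter")
  if (any(state$t_fwd > 0 & state$t_bwd > 0)) {
    stop("edge with both directions inhibited (p_ij < 1 and p_ji < 1)")
  }
  isD <- state$strategy == "D"
  if (any(state$t_fwd[isD[state$network$edges[, 1L]]] > 0) ||
      any(state$t_bwd[isD[state$network$edges[, 2L]]] > 0)) {
    stop("defector holding a nonzero abstention counter")
  }
  invisible(state)
}

#' Play one game round
#'
#' For every edge, the direction with a nonzero counter (at most one, by the
#' edge invariant) draws participation with probability `p_t`; the PD is
#' played iff both sides participate (a fully engaged side, counter 0,
#' always participates).  Payoffs follow [stage_payoffs()] with actions
#' equal to current strategies, abstention replacing a cooperator's action
#' when she does not participate.  Counters then update: a cooperator
#' exploited in a played interaction resets her counter to 1
#' (`p_1 = delta_d`); one who abstained increments it; one whose played
#' opponent cooperated resets it to 0 to reciprocate; a cooperator facing an
#' abstaining opponent learns nothing and keeps her counter.  Per-round
#' payoffs are not accumulated across rounds.
#'
#' This is the readable reference implementation used for worked examples
#' and invariant tests; long simulations go through the compiled engine in
#' [run_evolution()].
#'
#' @param state a `"pd_state"`.
#' @param params a [model_params()] object.
#' @return The updated state; `state$payoffs` holds this round's payoffs.
#' @export
play_round <- function(state, params) {
  stopifnot(inherits(state, "pd_state"), inherits(params, "pd_params"))
  dd <- params$delta_d
  r <- params$r
  net <- state$network
  pay <- numeric(net$N)
  s <- state$strategy
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges[e, 1L]; j <- net$edges[e, 2L]
    t_ij <- state$t_fwd[e]; t_ji <- state$t_bwd[e]
    part_i <- if (t_ij > 0L) runif(1) < engagement_probability(t_ij, dd) else TRUE
    part_j <- if (t_ji > 0L) runif(1) < engagement_probability(t_ji, dd) else TRUE
    played <- part_i && part_j
    if (played) {
      pp <- stage_payoffs(s[i], s[j], r)
      pay[i] <- pay[i] + pp[1L]
      pay[j] <- pay[j] + pp[2L]
    }
    # counter updates (cooperators only; defectors stay fully engaged)
    if (s[i] == "C") {
      state$t_fwd[e] <- if (!part_i) t_ij + 1L
        else if (played && s[j] == "D") 1L
        else if (played) 0L
        else t_ij # opponent abstained: no information gained
    }
    if (s[j] == "C") {
      state$t_bwd[e] <- if (!part_j) t_ji + 1L
        else if (played && s[i] == "D") 1L
        else if (played) 0L
        else t_ji
    }
  }
  state$payoffs <- pay
  state$round <- state$round + 1L
  state
}

#' Apply a strategy change and its engagement side effects
#'
#' Switching C to D resets all the agent's outgoing counters to 0 (a
#' defector always plays).  Switching D to C sets counter 1
#' (`p_1 = delta_d`) toward neighbors she perceives as defectors -- those
#' not currently abstaining from her, `t_ji = 0` -- to avoid immediate
#' re-exploitation, and 0 toward neighbors perceived as cooperators.  A
#' no-op change leaves the state untouched.  Both rules preserve the
#' one-side-engaged edge invariant.
#'
#' @param state a `"pd_state"`.
#' @param agent node index.
#' @param new_strategy `"C"` or `"D"`.
#' @return The updated state.
#' @export
apply_strategy_change <- function(state, agent, new_strategy) {
  stopifnot(inherits(state, "pd_state"))
  stopifnot(new_strategy %in% c("C", "D"))
  if (agent < 1 || agent > state$network$N) stop("unknown agent index")
  if (state$strategy[agent] == new_strategy) return(state)
  edges <- state$network$edges
  on_fwd <- which(edges[, 1L] == agent)
  on_bwd <- which(edges[, 2L] == agent)
  if (new_strategy == "D") {
    state$t_fwd[on_fwd] <- 0L
    state$t_bwd[on_bwd] <- 0L
  } else {
    # toward perceived defectors (their counter toward the agent is 0) set p_1
    state$t_fwd[on_fwd] <- ifelse(state$t_bwd[on_fwd] > 0L, 0L, 1L)
    state$t_bwd[on_bwd] <- ifelse(state$t_fwd[on_bwd] > 0L, 0L, 1L)
  }
  state$strategy[agent] <- new_strategy
  state
}
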