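#' Run the evolutionary dynamics
#'
#' The full asynchronous loop, executed by the compiled core: every round
#' all edges are played (participation drawn per [play_round()]'s rules),
#' the engagement counters are updated, then every agent is independently
#' flagged for revision with probability `delta`; flagged agents decide
#' from the common post-round state and all switches are applied
#' simultaneously, with the engagement side effects of
#' [apply_strategy_change()].
#'
#' The run stops early at the all-D state (always absorbing) or at the
#' all-C state once every counter is back to 0 and the remain-C condition
#' holds for every node at the run's horizon (then all-C is absorbing);
#' otherwise it continues to `max_rounds`.  With `force_continue = TRUE`
#' the loop always runs the full `max_rounds`, which is how the absorption
#' tests verify that nothing moves.  Identical seeds give identical
#' trajectories.  With bounded-rationality knobs active (see
#' [perturb_rationality()]) no state is absorbing and no early stop is
#' applied.
#'
#' @param network a [pd_network()].
#' @param strategies initial strategies (`"pd_strategies"` or `"C"`/`"D"`
#'   vector).
#' @param params a [model_params()] object (finite or infinite `h`).
#' @param max_rounds round budget.
#' @param seed optional integer seed.
#' @param record keep the per-round trajectory (fraction of C's, mean
#'   payoffs by strategy, inhibited directed-edge count)?
#' @param force_continue disable early stopping.
#' @return A `"pd_trajectory"` object.
#' @examples
#' net <- build_lattice("ring4", 20)
#' init <- assign_initial_strategies(net, "random", 2, seed = 1)
#' run_evolution(net, init, model_params(r = 5, h = 2), max_rounds = 500, seed = 1)
#' @export
run_evolution <- function(network, strategies, params, max_rounds = 10000,
                          seed = NULL, record = TRUE, force_continue = FALSE) {
  res <- .run_core(network, strategies, params, max_rounds, seed,
                   record = record,
                   stop_mode = if (force_continue) 2L else 0L)
  .as_trajectory(res, network, params)
}

# shared launcher for run_evolution and the experiment estimators
.run_core <- function(network, strategies, params, max_rounds, seed,
                      record, stop_mode) {
  stopifnot(inherits(network, "pd_network"), inherits(params, "pd_params"))
  s <- if (inherits(strategies, "pd_strategies")) strategies$strategy else strategies
  stopifnot(length(s) == network$N, all(s %in% c("C", "D")))
  stopifnot(max_rounds >= 1)
  if (!is.null(seed)) set.seed(seed)
  dd <- params$delta_d
  t_cap <- .t_cap_for(dd)
  if (is.infinite(params$h)) {
    ptab <- engagement_probability(0:t_cap, dd)
    scc <- scd <- numeric(t_cap + 1L) # unused in infinite-horizon mode
    P <- p_cd_limit(dd)
    rho <- P / (1 - P)
    allc <- params$r >= 1 + rho # keep-on-tie convention
    hmode <- 1L
  } else {
    tab <- .forecast_tables(dd, params$h, t_cap)
    ptab <- tab$p; scc <- tab$scc; scd <- tab$scd
    rho <- 0
    # with all counters 0 every neighbor is a state-0 cooperator and the
    # per-neighbor gain of defecting is degree-independent
    allc <- (-params$r * (scc[1L] - scd[1L]) + scc[1L]) <= 0
    hmode <- 0L
  }
  .sim_run_cpp(
    network$csr$xadj, network$csr$adjn, network$csr$rev,
    as.integer(s == "C"),
    params$r, params$delta, ptab, scc, scd,
    hmode, rho, allc,
    as.integer(max_rounds), as.integer(stop_mode),
    params$gain_noise_sd, params$decision_flip_prob,
    record
  )
}

.as_trajectory <- function(res, network, params) {
  structure(
    list(
      frac_C = res$frac_C, pay_C = res$pay_C, pay_D = res$pay_D,
      inhibited = res$inhibited,
      rounds = res$rounds,
      absorbed = c("none", "all-D", "all-C")[res$absorbed + 1L],
      absorption_round = if (res$absorption_round > 0) res$absorption_round else NA_integer_,
      final_frac_C = res$final_frac_C,
      final_strategy = ifelse(res$final_strategy == 1L, "C", "D"),
      final_t = res$final_t,
      network = network, params = params
    ),
    class = "pd_trajectory"
  )
}

#' @export
print.pd_trajectory <- function(x, ...) {
  cat(sprintf("pd_trajectory: %d rounds, final C-fraction %.3f, absorbed: %s",
              x$rounds, x$final_frac_C, x$absorbed))
  if (!is.na(x$absorption_round)) cat(sprintf(" (round %d)", x$absorption_round))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.pd_trajectory <- function(x, ...) {
  if (is.null(x$frac_C)) stop("trajectory was run with record = FALSE")
  data.frame(
    round = seq_len(x$rounds),
    fraction_C = x$frac_C,
    mean_payoff_C = x$pay_C,
    mean_payoff_D = x$pay_D,
    inhibited_edges = x$inhibited
  )
}
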