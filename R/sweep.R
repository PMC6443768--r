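#' Network specification for repeated generation
#'
#' Experiment runners regenerate random networks per replicate; a network
#' spec captures the generator and its arguments.  Lattices are
#' deterministic and are built once.
#'
#' @param spec either a [pd_network()] (used as-is) or a list with `kind =
#'   "lattice"` (`type`, `N`) or `kind = "random"` (`model`, `N`,
#'   `mean_degree`, optional `transitivity`).
#' @param seed seed forwarded to random generators.
#' @return A [pd_network()].
#' @export
network_from_spec <- function(spec, seed = NULL) {
  if (inherits(spec, "pd_network")) return(spec)
  stopifnot(is.list(spec), !is.null(spec$kind))
  switch(spec$kind,
    lattice = build_lattice(spec$type, spec$N),
    random = build_random_network(
      spec$model, spec$N,
      mean_degree = if (is.null(spec$mean_degree)) 4 else spec$mean_degree,
      seed = seed,
      transitivity = if (is.null(spec$transitivity)) 0 else spec$transitivity
    ),
    stop("unknown network spec kind: ", spec$kind)
  )
}

.is_random_spec <- function(spec) is.list(spec) && identical(spec$kind, "random")

#' Sweep the PD return and estimate the invasion and fixation thresholds
#'
#' Runs the evolutionary dynamics over a grid of returns `r`, with
#' `replicates` independent initializations per grid point.  For random
#' network models the network is regenerated for every replicate; the
#' initial cooperators are re-placed for every replicate in all cases.  Two
#' empirical thresholds summarize the sweep: `r_inv`, the smallest grid `r`
#' whose mean final cooperation fraction exceeds the initial fraction
#' (cooperation invades and persists on average), and `r_fix`, the smallest
#' grid `r` at which every replicate is absorbed at all-C (cooperation
#' always fixates).  Runs that end unabsorbed with final fraction above 0.2
#' are flagged as slow-fixation candidates -- they typically converge to
#' all-C on a longer timescale, while unabsorbed runs below 0.2 are
#' stalemates or long-term fluctuations.
#'
#' @param network_spec fixed [pd_network()] or spec list, see
#'   [network_from_spec()].
#' @param r_grid increasing grid of PD returns.
#' @param replicates initializations per grid point.
#' @param params a [model_params()] object (its `r` is ignored).
#' @param max_rounds per-run round budget.
#' @param placement placement scheme for [assign_initial_strategies()].
#' @param initial_fraction fraction of initial cooperators.
#' @param seed master seed; expanded into per-replicate network, placement
#'   and run seeds so that components can be re-run independently.
#' @return A `"pd_sweep"` object: per-run `results` data frame, per-`r`
#'   `summary` (mean final fraction, shares of replicates at 0, at 1 and in
#'   between, slow-fixation count), and the estimated `r_inv`, `r_fix`
#'   (`NA` when the grid does not reach them).
#' @export
sweep_return <- function(network_spec, r_grid, replicates, params,
                         max_rounds = 10000,
                         placement = "random", initial_fraction = 0.01,
                         seed = NULL) {
  if (!length(r_grid)) stop("empty r grid")
  stopifnot(!is.unsorted(r_grid), replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  fixed_net <- if (!.is_random_spec(network_spec)) {
    network_from_spec(network_spec)
  } else NULL
  seeds <- matrix(sample.int(.Machine$integer.max - length(r_grid) - 1L,
                             3L * replicates),
                  ncol = 3L) # network / placement / run streams
  rows <- vector("list", length(r_grid) * replicates)
  n_row <- 0L
  for (rep in seq_len(replicates)) {
    net <- if (is.null(fixed_net)) {
      network_from_spec(network_spec, seed = seeds[rep, 1L])
    } else fixed_net
    count_C <- max(1L, round(initial_fraction * net$N))
    init <- assign_initial_strategies(net, placement, count_C,
                                      seed = seeds[rep, 2L])
    for (g in seq_along(r_grid)) {
      p <- model_params(r = r_grid[g], delta = params$delta, d = params$d,
                        h = params$h,
                        gain_noise_sd = params$gain_noise_sd,
                        decision_flip_prob = params$decision_flip_prob)
      res <- .run_core(net, init, p, max_rounds,
                       seed = seeds[rep, 3L] + g, record = FALSE,
                       stop_mode = 0L)
      n_row <- n_row + 1L
      rows[[n_row]] <- data.frame(
        r = r_grid[g], replicate = rep,
        final_fraction = res$final_frac_C,
        absorbed = c("none", "all-D", "all-C")[res$absorbed + 1L],
        absorption_round = ifelse(res$absorption_round > 0,
                                  res$absorption_round, NA_integer_),
        initial_fraction = count_C / net$N,
        isolated_C_fraction = init$frac_isolated_C
      )
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$r), function(df) {
    data.frame(
      r = df$r[1L],
      mean_final = mean(df$final_fraction),
      share_all_D = mean(df$absorbed == "all-D"),
      share_all_C = mean(df$absorbed == "all-C"),
      share_interior = mean(df$absorbed == "none"),
      slow_fixation = sum(df$absorbed == "none" & df$final_fraction > 0.2)
    )
  }))
  init_frac <- mean(results$initial_fraction)
  inv_idx <- which(summ$mean_final > init_frac)
  fix_idx <- which(summ$share_all_C == 1)
  structure(
    list(
      results = results, summary = summ,
      r_inv = if (length(inv_idx)) summ$r[min(inv_idx)] else NA_real_,
      r_fix = if (length(fix_idx)) summ$r[min(fix_idx)] else NA_real_,
      initial_fraction = init_frac,
      params = params, replicates = replicates
    ),
    class = "pd_sweep"
  )
}

#' @export
print.pd_sweep <- function(x, ...) {
  cat(sprintf("pd_sweep over r in [%g, %g] (%d points x %d replicates)\n",
              min(x$summary$r), max(x$summary$r), nrow(x$summary),
              x$replicates))
  cat(sprintf("  r_inv = %s (mean final fraction first exceeds %.3g)\n",
              format(x$r_inv), x$initial_fraction))
  cat(sprintf("  r_fix = %s (all replicates absorbed at all-C)\n",
              format(x$r_fix)))
  invisible(x)
}

#' Fixation probability from a single cooperating seed
#'
#' Monte Carlo estimate of the probability that the population reaches
#' all-C when exactly one node starts as a cooperator.  For returns above
#' the fixation threshold and a slow update rate, fixation from a single
#' seed of degree `k` occurs roughly with the first-mover race probability
#' `1 - 1/(k + 1)` (the seed defects at her first revision, but a
#' neighbor's switch to C usually comes first); on a star the central seed
#' fixates with probability about `1/2 + 1/(2N)` at the ring's
#' infinite-horizon threshold.
#'
#' @param network a [pd_network()].
#' @param seed_node the initial cooperator.
#' @param params a [model_params()] object.
#' @param replicates Monte Carlo replicates.
#' @param max_rounds per-run budget (runs are expected to absorb earlier).
#' @param seed master seed.
#' @return List with the estimate `p_hat`, its binomial standard error
#'   `se`, counts, and the share of runs not absorbed within the budget.
#' @export
estimate_single_seed_fixation <- function(network, seed_node, params,
                                          replicates = 2000,
                                          max_rounds = 30000, seed = NULL) {
  stopifnot(inherits(network, "pd_network"))
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, replicates)
  init <- rep("D", network$N)
  init[seed_node] <- "C"
  n_fix <- 0L; n_open <- 0L
  for (b in seq_len(replicates)) {
    res <- .run_core(network, init, params, max_rounds,
                     seed = run_seeds[b], record = FALSE, stop_mode = 0L)
    if (res$absorbed == 2L) n_fix <- n_fix + 1L
    if (res$absorbed == 0L) n_open <- n_open + 1L
  }
  p_hat <- n_fix / replicates
  list(p_hat = p_hat,
       se = sqrt(p_hat * (1 - p_hat) / replicates),
       n_fixed = n_fix, replicates = replicates,
       unabsorbed_share = n_open / replicates)
}

#' First-mover race from a single cooperating seed
#'
#' Runs the dynamics from a single cooperator until the first strategy
#' change anywhere in the network and reports how often a
#' defector-to-cooperator switch happens strictly before the seed defects
#' (simultaneous first switches count as a loss).  For small `delta` and
#' `r` above threshold, this race is won with probability about
#' `1 - 1/(k + 1)`, `k` the seed's degree.
#'
#' @inheritParams estimate_single_seed_fixation
#' @return List with the win frequency `p_hat`, its binomial `se`, and the
#'   count of runs with no flip within the budget.
#' @export
estimate_invasion_race <- function(network, seed_node, params,
                                   replicates = 2000, max_rounds = 100000,
                                   seed = NULL) {
  stopifnot(inherits(network, "pd_network"))
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, replicates)
  init <- rep("D", network$N)
  init[seed_node] <- "C"
  n_win <- 0L; n_none <- 0L
  for (b in seq_len(replicates)) {
    res <- .run_core(network, init, params, max_rounds,
                     seed = run_seeds[b], record = FALSE, stop_mode = 1L)
    dc <- res$first_DC_round; cd <- res$first_CD_round
    if (dc < 0 && cd < 0) n_none <- n_none + 1L
    else if (dc > 0 && (cd < 0 || dc < cd)) n_win <- n_win + 1L
  }
  p_hat <- n_win / replicates
  list(p_hat = p_hat,
       se = sqrt(p_hat * (1 - p_hat) / replicates),
       n_win = n_win, replicates = replicates,
       no_flip_share = n_none / replicates)
}
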