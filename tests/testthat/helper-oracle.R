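# Brute-force play-tree oracle for the expected-gain formulas.
#
# Enumerates, branch by branch, the play/abstain outcome tree of a revising
# agent against one frozen neighbor, using only the engagement law
# p_t = 1 - (1 - delta_d)^t (p_0 = 1) and the counter bookkeeping rules:
# a played round against a defector resets the abstaining side to state 1,
# an abstained round advances it by one state, and a cooperator who meets
# cooperation re-engages fully (plays ever after).  Independent of the
# package's forecast recursions and gain formulas.

oracle_p <- function(s, dd) if (s == 0) 1 else 1 - (1 - dd)^s

# expected number of played rounds over `h` rounds when every played round
# ends in exploitation (abstaining side resets to state 1)
oracle_plays_exploit <- function(s, dd, h) {
  if (h == 0) return(0)
  p <- oracle_p(s, dd)
  p * (1 + oracle_plays_exploit(1, dd, h - 1)) +
    (1 - p) * oracle_plays_exploit(s + 1, dd, h - 1)
}

# expected number of played rounds when the first played round restores full
# engagement (mutual cooperation): all remaining rounds are played
oracle_plays_coop <- function(s, dd, h) {
  if (h == 0) return(0)
  p <- oracle_p(s, dd)
  p * h + (1 - p) * oracle_plays_coop(s + 1, dd, h - 1)
}

# `per`: data.frame(perceived = "C"/"D", state = integer), as produced by
# perceive_neighbors().  Positive gain = the reviser expects to profit from
# switching strategy.
oracle_gain_C <- function(per, r, h, dd) {
  gain <- 0
  for (q in seq_len(nrow(per))) {
    s <- per$state[q]
    if (per$perceived[q] == "C") {
      stay <- (r - 1) * oracle_plays_coop(s, dd, h)     # mutual cooperation
      switch_ <- r * oracle_plays_exploit(s, dd, h)     # exploit the C
      gain <- gain + switch_ - stay
    } else {
      stay <- -1 * oracle_plays_exploit(s, dd, h)       # keep getting exploited
      gain <- gain + 0 - stay                            # D vs D earns nothing
    }
  }
  gain
}

oracle_gain_D <- function(per, r, h, dd) {
  gain <- 0
  for (q in seq_len(nrow(per))) {
    s <- per$state[q]
    if (per$perceived[q] == "C") {
      stay <- r * oracle_plays_exploit(s, dd, h)        # keep exploiting the C
      switch_ <- (r - 1) * oracle_plays_coop(s, dd, h)  # cooperate instead
      gain <- gain + switch_ - stay
    } else {
      # on switching she engages fellow defectors at p_1 and loses the cost
      gain <- gain + (-1) * oracle_plays_exploit(1, dd, h) - 0
    }
  }
  gain
}

# random perceived neighborhood for property tests
random_neighborhood <- function(max_k = 8, max_state = 6, force_C = FALSE) {
  k <- sample.int(max_k, 1)
  perceived <- sample(c("C", "D"), k, replace = TRUE)
  if (force_C && !any(perceived == "C")) perceived[1] <- "C"
  state <- integer(k)
  for (q in seq_len(k)) {
    state[q] <- if (perceived[q] == "D") sample.int(max_state, 1)
    else sample(0:max_state, 1)
  }
  data.frame(neighbor = seq_len(k), perceived = perceived, state = state)
}

# assemble a pd_state with prescribed directed counters (validated)
make_state <- function(net, strat, t_fwd = NULL, t_bwd = NULL) {
  st <- population_state(net, strat)
  if (!is.null(t_fwd)) st$t_fwd <- as.integer(t_fwd)
  if (!is.null(t_bwd)) st$t_bwd <- as.integer(t_bwd)
  validate_state(st)
  st
}

# locate a 2x2 block (a 4-cycle) on a von Neumann torus
find_square_block <- function(net) {
  for (v in seq_len(net$N)) {
    nbs <- net$adj[[v]]
    for (a_i in seq_along(nbs)) {
      for (b_i in seq_along(nbs)) {
        if (b_i <= a_i) next
        a <- nbs[a_i]; b <- nbs[b_i]
        w <- setdiff(intersect(net$adj[[a]], net$adj[[b]]), v)
        if (length(w)) return(c(v, a, w[1], b))
      }
    }
  }
  stop("no 4-cycle found")
}
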