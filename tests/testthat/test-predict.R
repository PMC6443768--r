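dd <- 0.05

test_that("perception derives from the counter pair exactly as specified", {
  net <- pd_network(rbind(c(1, 2), c(1, 3), c(1, 4)), 4)
  # C reviser: t_1j = 3 -> perceived D in state 3; t_1j = 0, t_j1 = 2 ->
  # perceived C in state 2; both 0 -> C in state 0
  st <- make_state(net, c("C", "D", "C", "C"),
                   t_fwd = c(3L, 0L, 0L), t_bwd = c(0L, 2L, 0L))
  per <- perceive_neighbors(st, 1)
  expect_equal(per$perceived, c("D", "C", "C"))
  expect_equal(per$state, c(3L, 2L, 0L))
  # D reviser with all t_ji = 0 perceives defectors everywhere
  stD <- make_state(net, c("D", "D", "D", "D"))
  expect_true(all(perceive_neighbors(stD, 1)$perceived == "D"))
  # D reviser sees exploited C's through their abstention
  stE <- make_state(net, c("D", "C", "D", "D"),
                    t_fwd = c(0L, 0L, 0L), t_bwd = c(4L, 0L, 0L))
  perE <- perceive_neighbors(stE, 1)
  expect_equal(perE$perceived, c("C", "D", "D"))
  expect_equal(perE$state[1], 4L)
})

test_that("defector forecast starts at p_t, has the closed-form fixed point, and converges", {
  expect_equal(forecast_play_with_defector(0, dd, 2), c(1, dd))
  # initialization at the fixed point gives a constant sequence
  Pinf <- p_cd_limit(dd)
  f <- function(P) P * dd + (1 - P) * ((1 - dd) * P + dd)
  expect_equal(f(Pinf), Pinf, tolerance = 1e-14)
  # convergence from any initialization
  for (t0 in c(0, 1, 4, 60)) {
    seqs <- forecast_play_with_defector(t0, dd, 1000)
    expect_lt(abs(seqs[1000] - Pinf), 1e-6)
  }
})

test_that("cooperator forecast is nondecreasing and absorbed at full engagement", {
  expect_equal(forecast_play_with_cooperator(0, 0.3, 4), rep(1, 4))
  expect_equal(forecast_play_with_cooperator(1, dd, 2), c(0.05, 0.142625))
  for (t0 in c(0, 1, 5)) {
    s <- forecast_play_with_cooperator(t0, dd, 50)
    expect_true(all(diff(s) >= 0))
    expect_lt(abs(s[50] - 1), 0.05)
    # dominates the defector forecast from the same state (strictly from
    # step 2 when not already at 1)
    expect_true(all(s - forecast_play_with_defector(t0, dd, 50) >= -1e-14))
  }
})

test_that("expected gains reproduce the hand-derived affine forms", {
  per <- data.frame(neighbor = 1, perceived = "C", state = 0L)
  for (r in c(1, 3, 6)) {
    expect_equal(expected_gain_C(per, r, 2, dd), 2 - 0.95 * r, tolerance = 1e-12)
  }
  perD <- data.frame(neighbor = 1, perceived = "C", state = 1L)
  for (r in c(2, 4.06, 5)) {
    expect_equal(expected_gain_D(perD, r, 2, dd), 0.0475 * r - 0.192625,
                 tolerance = 1e-12)
  }
})

test_that("gain formulas equal the play-tree oracle where the recursion is branch-exact", {
  set.seed(1)
  for (case in 1:40) {
    per <- random_neighborhood()
    r <- runif(1, 1, 8)
    for (h in 1:2) {
      expect_lt(abs(expected_gain_C(per, r, h, dd) - oracle_gain_C(per, r, h, dd)),
                1e-12)
      expect_lt(abs(expected_gain_D(per, r, h, dd) - oracle_gain_D(per, r, h, dd)),
                1e-12)
    }
    # the cooperator-side recursion is exact at any horizon: all-C
    # neighborhoods at state 0 agree at h = 3 too
    per0 <- data.frame(neighbor = 1:2, perceived = "C", state = 0L)
    expect_lt(abs(expected_gain_C(per0, r, 3, dd) - oracle_gain_C(per0, r, 3, dd)),
              1e-12)
  }
})

test_that("myopic best response always favors defection", {
  set.seed(2)
  for (case in 1:200) {
    per <- random_neighborhood()
    r <- runif(1, 1, 10)
    expect_gt(expected_gain_C(per, r, 1, dd), 0)
    expect_lt(expected_gain_D(per, r, 1, dd), 0)
  }
  # agents perceiving no cooperating neighbor defect at any horizon
  perD <- data.frame(neighbor = 1:3, perceived = "D", state = c(1L, 2L, 9L))
  for (r in c(1, 10, 1000)) {
    expect_gt(expected_gain_C(perD, r, 4, dd), 0)
    expect_lt(expected_gain_D(perD, r, 4, dd), 0)
  }
})

test_that("closed-form limit behaves as the exploitation probability", {
  expect_equal(p_cd_limit(1), 1)
  expect_equal(p_cd_limit(dd), 0.2046043, tolerance = 1e-6)
  ddg <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(p_cd_limit(ddg)) > 0))
  expect_lt(abs(p_cd_limit(1e-4) - sqrt(1e-4)) / sqrt(1e-4), 0.02)
  expect_error(p_cd_limit(0))
})

test_that("persistence threshold is linear in k/k_C with the star worst case", {
  P <- p_cd_limit(dd)
  rho <- P / (1 - P)
  expect_equal(remain_C_threshold(4, 4, dd), 1 + rho)
  expect_equal(remain_C_threshold(99, 1, dd), 1 + 99 * rho) # star center
  expect_identical(remain_C_threshold(4, 0, dd), Inf)
  ratios <- c(1, 1.5, 2, 4, 10)
  thr <- vapply(ratios, function(q) remain_C_threshold(q * 2, 2, dd), numeric(1))
  expect_true(all(diff(thr) > 0))
  expect_equal(fixation_threshold_infinite(4, dd),
               remain_C_threshold(4, 1, dd))
  expect_equal(fixation_threshold_infinite(4, dd), 2.028944, tolerance = 1e-6)
  # vanishing delta_d removes the cost of reciprocity entirely
  expect_lt(abs(fixation_threshold_infinite(10, 1e-10) - 1), 1e-3)
  k <- 2:10
  expect_true(all(diff(vapply(k, fixation_threshold_infinite, numeric(1),
                              delta_d = dd)) > 0))
})

test_that("finite-horizon fixation bound approaches the closed form and shrinks with h", {
  hs <- c(2, 3, 5, 10, 30, 100, 400)
  bounds <- vapply(hs, function(h) fixation_threshold_bound(4, h, dd), numeric(1))
  expect_true(all(diff(bounds) < 0))
  expect_lt(abs(bounds[length(hs)] - fixation_threshold_infinite(4, dd)), 0.05)
  expect_gt(fixation_threshold_bound(8, 5, dd), fixation_threshold_bound(4, 5, dd))
  expect_error(fixation_threshold_bound(4, 1, dd))
})

test_that("revision switches on strictly positive gain and keeps ties", {
  # D facing a single abstaining C at state 1, h = 2: gain = 0.0475 r - 0.192625
  net <- pd_network(rbind(c(1, 2)), 2)
  stD <- make_state(net, c("D", "C"), t_fwd = 0L, t_bwd = 1L)
  out <- revise(stD, 1, model_params(r = 5, delta = 0.05, h = 2))
  expect_equal(out$decision, "switch")
  expect_equal(out$state$strategy[1], "C")
  validate_state(out$state)
  out2 <- revise(stD, 1, model_params(r = 3, delta = 0.05, h = 2))
  expect_equal(out2$decision, "keep")
  # infinite horizon: exact threshold equality keeps the current strategy
  stC <- make_state(net, c("C", "C"))
  thr <- remain_C_threshold(1, 1, dd)
  tie <- revise(stC, 1, model_params(r = thr, delta = 0.05, h = Inf))
  expect_equal(tie$decision, "keep")
  below <- revise(stC, 1, model_params(r = thr - 1e-9, delta = 0.05, h = Inf))
  expect_equal(below$decision, "switch")
  # h = 1 cooperator surrounded by cooperators defects
  net4 <- pd_network(rbind(c(1, 2), c(1, 3)), 3)
  stCC <- make_state(net4, c("C", "C", "C"))
  expect_equal(revise(stCC, 1, model_params(r = 6, delta = 0.05, h = 1))$decision,
               "switch")
})

test_that("threshold report collects the analytic quantities", {
  rep_ <- threshold_report(c(4, 8), h = 3, delta_d = dd)
  expect_equal(nrow(rep_), 2L)
  expect_equal(rep_$P_CD_inf, rep(p_cd_limit(dd), 2))
  expect_true(all(rep_$R_fix_bound >= rep_$R_fix_inf))
})
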