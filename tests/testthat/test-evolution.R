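test_that("trajectories are fully determined by the seed", {
  net <- build_lattice("square4", 100)
  init <- assign_initial_strategies(net, "random", 5, seed = 3)
  p <- model_params(r = 4, delta = 0.05, h = 2)
  a <- run_evolution(net, init, p, max_rounds = 400, seed = 77)
  b <- run_evolution(net, init, p, max_rounds = 400, seed = 77)
  expect_identical(a$frac_C, b$frac_C)
  expect_identical(a$final_strategy, b$final_strategy)
  expect_identical(a$final_t, b$final_t)
  c_ <- run_evolution(net, init, p, max_rounds = 400, seed = 78)
  expect_false(identical(a$frac_C, c_$frac_C))
})

test_that("all-D is absorbing and an isolated cooperator defects when she revises", {
  net <- build_lattice("ring4", 30)
  p <- model_params(r = 2, delta = 0.05, h = 2)
  allD <- run_evolution(net, rep("D", 30), p, max_rounds = 200, seed = 1)
  expect_equal(allD$absorbed, "all-D")
  expect_true(all(allD$frac_C == 0))
  # single C, r below any switch threshold: first flip is her defection
  init <- rep("D", 30); init[7] <- "C"
  one <- run_evolution(net, init, model_params(r = 1.2, delta = 0.05, h = 2),
                       max_rounds = 2000, seed = 2)
  expect_equal(one$absorbed, "all-D")
})

test_that("all-C is recognized as absorbing when the remain-C condition holds", {
  net <- build_lattice("ring4", 30)
  p <- model_params(r = 3, delta = 0.05, h = 2) # above the h=2 remain threshold
  tr <- run_evolution(net, rep("C", 30), p, max_rounds = 500, seed = 4)
  expect_equal(tr$absorbed, "all-C")
  expect_equal(tr$absorption_round, 1L)
  expect_true(all(tr$frac_C == 1))
})

test_that("trajectory log exposes the per-round diagnostics", {
  net <- build_lattice("square4", 64)
  init <- assign_initial_strategies(net, "random", 3, seed = 5)
  tr <- run_evolution(net, init, model_params(r = 5, h = 2), max_rounds = 300,
                      seed = 6)
  df <- as.data.frame(tr)
  expect_named(df, c("round", "fraction_C", "mean_payoff_C", "mean_payoff_D",
                     "inhibited_edges"))
  expect_true(all(df$fraction_C >= 0 & df$fraction_C <= 1))
  expect_true(all(df$inhibited_edges >= 0))
  expect_equal(nrow(df), tr$rounds)
})

test_that("return sweep summarizes invasion and fixation over the grid", {
  spec <- list(kind = "lattice", type = "square4", N = 100)
  p <- model_params(r = 3, delta = 0.05, h = 2)
  sw <- sweep_return(spec, r_grid = c(1, 10), replicates = 5, p,
                     max_rounds = 4000, initial_fraction = 0.02, seed = 21)
  expect_s3_class(sw, "pd_sweep")
  expect_equal(nrow(sw$results), 10L)
  # r = 1: cooperation disappears in every replicate
  r1 <- subset(sw$results, r == 1)
  expect_true(all(r1$absorbed == "all-D"))
  # far above the bound, every replicate fixates
  r10 <- subset(sw$results, r == 10)
  expect_true(all(r10$absorbed == "all-C"))
  expect_equal(sw$r_fix, 10)
  expect_equal(sw$r_inv, 10)
  expect_true(is.na(sw$r_fix) || is.na(sw$r_inv) || sw$r_inv <= sw$r_fix)
  expect_error(sweep_return(spec, numeric(0), 2, p), "empty")
  # determinism of the whole sweep
  sw2 <- sweep_return(spec, r_grid = c(1, 10), replicates = 5, p,
                      max_rounds = 4000, initial_fraction = 0.02, seed = 21)
  expect_identical(sw$results, sw2$results)
})

test_that("without reciprocity cooperation never invades at any return", {
  # d -> d_min pushes delta_d -> 1: the C-strategy degenerates to
  # unconditional cooperation and defection dominates
  net <- build_lattice("square4", 100)
  init <- assign_initial_strategies(net, "random", 10, seed = 8)
  for (r in c(2, 10, 100)) {
    p <- model_params(r = r, delta = 0.05, d = -18.9, h = 2) # delta_d = 0.995
    tr <- run_evolution(net, init, p, max_rounds = 3000, seed = 9)
    expect_equal(tr$absorbed, "all-D")
  }
})

test_that("rationality knobs: zero settings are bit-identical, flips destroy absorption", {
  net <- build_lattice("square4", 64)
  init <- assign_initial_strategies(net, "random", 3, seed = 10)
  p0 <- model_params(r = 4, delta = 0.05, h = 2)
  pz <- perturb_rationality(p0, 0, 0)
  a <- run_evolution(net, init, p0, max_rounds = 500, seed = 11)
  b <- run_evolution(net, init, pz, max_rounds = 500, seed = 11)
  expect_identical(a$frac_C, b$frac_C)
  # moderate gain noise keeps fixation at high return
  pn <- perturb_rationality(p0, gain_noise_sd = 0.1)
  fix <- 0
  for (s in 1:5) {
    tr <- run_evolution(net, init, model_params(10, 0.05, 0, 2) |>
                          perturb_rationality(gain_noise_sd = 0.1),
                        max_rounds = 4000, seed = 100 + s)
    if (tr$final_frac_C == 1) fix <- fix + 1
  }
  expect_gte(fix, 4)
  # strong decision flips approach drift: run never absorbs early
  pf <- perturb_rationality(p0, decision_flip_prob = 0.4)
  tr <- run_evolution(net, rep("D", 64), pf, max_rounds = 300, seed = 12)
  expect_equal(tr$rounds, 300L)
  expect_gt(max(tr$frac_C), 0) # flips resurrect cooperators from all-D
})

test_that("single-seed race and fixation estimators are consistent on small budgets", {
  net <- build_lattice("ring4", 20)
  p <- model_params(r = 3, delta = 0.01, d = 0, h = Inf)
  race <- estimate_invasion_race(net, 1, p, replicates = 300, seed = 13)
  expect_lt(abs(race$p_hat - 0.8), 0.1)
  expect_equal(race$no_flip_share, 0)
  star <- build_random_network("star", 7)
  pf <- model_params(r = 10, delta = 0.02, d = 0, h = Inf)
  fx <- estimate_single_seed_fixation(star, 1, pf, replicates = 200,
                                      max_rounds = 20000, seed = 14)
  expect_gt(fx$p_hat, 0.3) # well above threshold the central seed often wins
  expect_lt(fx$unabsorbed_share, 0.05)
})

test_that("imitation baseline keeps monomorphic states and lets rare cooperation die", {
  net <- build_lattice("square4", 100)
  allC <- imitation_baseline_run(net, rep("C", 100), r = 3, max_rounds = 50,
                                 seed = 15)
  expect_equal(allC$absorbed, "all-C")
  ext <- 0
  for (s in 1:5) {
    init <- assign_initial_strategies(net, "random", 1, seed = 30 + s)
    im <- imitation_baseline_run(net, init, r = 8, max_rounds = 5000,
                                 seed = 40 + s)
    if (im$absorbed == "all-D") ext <- ext + 1
  }
  expect_equal(ext, 5L) # isolated unconditional C's imitate their exploiters
})
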