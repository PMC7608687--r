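test_that("Hill activation and repression match their closed forms", {
  for (K in c(0.5, 10, 300)) for (n in c(1, 2, 4)) {
    expect_equal(hill_act(0, K, n), 0)
    expect_equal(hill_act(K, K, n), 0.5)
    expect_equal(hill_rep(0, K, n), 1)
    expect_equal(hill_rep(K, K, n), 0.5)
  }
  expect_equal(round(hill_act(100 * 7, 7, 2), 4), 0.9999)
  expect_equal(hill_rep(Inf, 10, 2), 0)
  # monotonicity
  s <- seq(0, 100, length.out = 50)
  expect_true(all(diff(hill_act(s, 20, 2)) >= 0))
  expect_true(all(diff(hill_rep(s, 20, 2)) <= 0))
  expect_error(hill_act(-1, 10, 2), "must be finite and >= 0")
})

test_that("effective_repressor titrates the active pool", {
  expect_equal(effective_repressor(5, 0, 100, 2), 5)
  expect_equal(effective_repressor(5, Inf, 100, 2), 0)
  expect_equal(effective_repressor(5, 100, 100, 2), 2.5)
  expect_error(effective_repressor(-1, 0, 100, 2), ">= 0")
})

test_that("derivatives have the stated structure at edge states", {
  p0 <- morpho_params(a_R = 1e-12, b_R = 1e-12, a_F = 1e-12, b_F = 1e-12)
  d0 <- derivatives(rep(0, 6), signal_env(), p0)
  expect_true(all(abs(d0) < 1e-10))
  # no activation, no basal: cfp decays at -gamma_cfp * cfp
  pb <- morpho_params(b_F = 1e-12, b_R = 1e-12)
  st <- c(0, 0, 0, 0, 10, 0)
  d <- derivatives(st, signal_env(), pb)
  expect_equal(d[["cfp"]], -pb$g_cfp * 10, tolerance = 1e-9)
  expect_error(derivatives(c(-1, 0, 0, 0, 0, 0), signal_env(), pb),
               "non-negative")
})

test_that("one-pathway steady state matches the sequential closed form", {
  p <- default_params()
  env <- signal_env(c6 = 1e6, c12 = 0)   # saturating C6
  # the chain solves sequentially: A12 = 0 exactly, so tetR is basal, which
  # fixes luxR, which fixes the P_lux output level
  tetR <- p$b_F / p$g_tetR
  luxR <- (p$b_R + p$a_R * hill_rep(tetR, p$K_tet, p$n_tet)) / p$g_luxR
  h6 <- hill_act(1e6, p$K6, p$n6)
  cfp_ss <- (p$b_F + p$a_F * (luxR / p$luxR_ref) * h6) / p$g_cfp
  got <- terminal_state(env, p, t_end = 200)
  expect_equal(got[["tetR"]], tetR, tolerance = 1e-6)
  expect_equal(got[["luxR"]], luxR, tolerance = 1e-6)
  expect_equal(got[["cfp"]], cfp_ss, tolerance = 1e-6)
})

test_that("integration honours fixed points and solver tolerances", {
  p <- default_params()
  env <- signal_env(c6 = 500)
  eq <- find_equilibria(env, p)[[1]]$state
  tr <- integrate_circuit(eq, env, p, t_end = 10)
  expect_lt(max(abs(sweep(tr$states, 2, eq))), 1e-4 * max(eq))
  # CFP-high terminal state from zero
  term <- terminal_state(env, p)
  expect_gt(term[["cfp"]], 10 * term[["yfp"]])
  # two tolerance settings agree within 10x the looser tolerance
  t1 <- integrate_circuit(rep(0, 6), env, p, t_end = 10, rtol = 1e-6,
                          atol = 1e-8)
  t2 <- integrate_circuit(rep(0, 6), env, p, t_end = 10, rtol = 1e-10,
                          atol = 1e-12)
  rel <- max(abs(t1$states - t2$states) / (1 + abs(t2$states)))
  expect_lt(rel, 10 * 1e-6)
})

test_that("piecewise schedules chain segments continuously", {
  p <- default_params()
  sched <- list(list(t_end = 2, env = signal_env(c12 = 500)),
                list(t_end = 7, env = signal_env(c6 = 37, c12 = 100)))
  tr <- integrate_circuit(rep(0, 6), sched, p)
  expect_equal(max(tr$times), 7)
  expect_true(all(diff(tr$times) > 0))
  # matches running the two phases by hand
  a <- integrate_circuit(rep(0, 6), signal_env(c12 = 500), p, t_end = 2)
  b <- integrate_circuit(a$states[nrow(a$states), ],
                         signal_env(c6 = 37, c12 = 100), p, t_end = 5)
  expect_equal(unname(tr$states[nrow(tr$states), ]),
               unname(b$states[nrow(b$states), ]), tolerance = 1e-7)
})

test_that("trajectories stay non-negative across random conditions", {
  set.seed(42)
  for (k in 1:10) {
    env <- signal_env(c6 = 10^runif(1, -1, 3), c12 = 10^runif(1, -1, 4),
                      iptg = runif(1, 0, 20))
    y0 <- runif(6, 0, 50)
    tr <- integrate_circuit(y0, env, default_params(), t_end = 10)
    expect_true(all(tr$states >= 0))
  }
})

test_that("exclusivity and receiver contrast match the circuit design", {
  p <- default_params()
  excl_c6 <- terminal_state(signal_env(c6 = 500), p)
  excl_c12 <- terminal_state(signal_env(c12 = 500), p)
  excl_mix <- terminal_state(signal_env(c6 = 500, c12 = 500), p)
  expect_gt(excl_c6[["cfp"]], 10 * excl_c6[["yfp"]])
  expect_gt(excl_c12[["yfp"]], 10 * excl_c12[["cfp"]])
  # exclusive: the losing channel in a mixture is < 10% of its
  # single-signal level
  minor <- min(excl_mix[["cfp"]] / excl_c6[["cfp"]],
               excl_mix[["yfp"]] / excl_c12[["yfp"]])
  expect_lt(minor, 0.10)
  # receiver: both channels > 50% of their single-signal levels
  pr <- p
  pr$variant <- "receiver"
  rec_c6 <- terminal_state(signal_env(c6 = 500), pr)
  rec_c12 <- terminal_state(signal_env(c12 = 500), pr)
  rec_mix <- terminal_state(signal_env(c6 = 500, c12 = 500), pr)
  expect_gt(rec_mix[["cfp"]], 0.5 * rec_c6[["cfp"]])
  expect_gt(rec_mix[["yfp"]], 0.5 * rec_c12[["yfp"]])
})

test_that("exclusive model reduces to the receiver as K_rep -> Inf", {
  base <- default_params()
  big <- morpho_params(K_lac = 1e12, K_tet = 1e12)
  rec <- base
  rec$variant <- "receiver"
  set.seed(7)
  for (k in 1:5) {
    y <- runif(6, 0, 100)
    env <- signal_env(c6 = runif(1, 0, 500), c12 = runif(1, 0, 500))
    expect_equal(derivatives(y, env, big), derivatives(y, env, rec),
                 tolerance = 1e-9)
  }
})

test_that("trajectory CSV export round-trips", {
  tr <- integrate_circuit(rep(0, 6), signal_env(c6 = 100),
                          default_params(), t_end = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- read.csv(f)
  expect_named(df, c("t", "luxR", "lasR", "lacI", "tetR", "cfp", "yfp"))
  expect_equal(df$cfp, unname(tr$states[, "cfp"]))
})
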