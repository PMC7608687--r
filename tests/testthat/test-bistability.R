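test_that("find_equilibria counts and classifies fixed points", {
  p <- default_params()
  eq1 <- find_equilibria(signal_env(c6 = 500), p)
  expect_length(Filter(function(e) e$stability == "stable", eq1), 1)
  expect_gt(eq1[[1]]$state[["cfp"]], eq1[[1]]$state[["yfp"]])
  # denser multi-start finds nothing extra (exhaustiveness oracle)
  eq1d <- find_equilibria(signal_env(c6 = 500), p, n_starts = 160, seed = 9)
  expect_length(eq1d, length(eq1))

  eq2 <- find_equilibria(signal_env(c6 = 37, c12 = 100), p)
  stabs <- sort(vapply(eq2, `[[`, "", "stability"))
  expect_equal(stabs, c("saddle", "stable", "stable"))
  # residuals honour the tolerance and states agree with classification
  for (e in eq2) {
    expect_lt(e$residual, 1e-8 * p$a_F * 1.01)
    mx <- max(Re(e$eigenvalues))
    if (e$stability == "stable") expect_lt(mx, 0) else expect_gt(mx, 0)
  }

  # vanishing synthesis: unique equilibrium at the origin
  p0 <- morpho_params(a_R = 1e-12, b_R = 1e-12, a_F = 1e-12, b_F = 1e-12)
  eq0 <- find_equilibria(signal_env(), p0)
  expect_length(eq0, 1)
  expect_lt(max(eq0[[1]]$state), 1e-9)
  expect_equal(eq0[[1]]$stability, "stable")
})

test_that("find_equilibria is deterministic given the seed", {
  p <- default_params()
  a <- find_equilibria(signal_env(c6 = 37, c12 = 100), p, seed = 5)
  b <- find_equilibria(signal_env(c6 = 37, c12 = 100), p, seed = 5)
  expect_identical(lapply(a, `[[`, "state"), lapply(b, `[[`, "state"))
})

test_that("continuation finds no folds on a monotone single branch", {
  pr <- default_params("receiver")
  env <- signal_env(c6 = 100, c12 = 50)
  eq <- find_equilibria(env, pr)
  br <- continue_branch(env, "c6", c(1, 1000), pr,
                        start_state = eq[[1]]$state)
  expect_length(br$fold_points, 0)
  expect_true(br$complete)
  expect_true(all(br$stability == "stable"))
})

test_that("folds bracket the bistable window and have singular Jacobians", {
  p <- default_params()
  env <- signal_env(c6 = 1000, c12 = 100)
  eq <- find_equilibria(env, p)
  br <- continue_branch(env, "c6", c(1, 1000), p,
                        start_state = eq[[1]]$state)
  expect_length(br$fold_points, 2)
  # oracle: dense equilibrium counting localises the same transitions
  c6s <- 10^seq(0, 3, length.out = 61)
  counts <- vapply(c6s, function(c6)
    n_stable(signal_env(c6 = c6, c12 = 100), p), numeric(1))
  lo_true <- c6s[max(which(counts == 1 & c6s < 30))]
  step <- c6s[2] / c6s[1]
  expect_lt(abs(log(br$fold_points[1] / lo_true)), 2 * log(step))
  hi_true <- c6s[min(which(counts == 1 & c6s > 40))]
  expect_lt(abs(log(br$fold_points[2] / hi_true)), 2 * log(step))
  # defining property of a saddle-node: singular Jacobian at the fold
  for (k in seq_along(br$fold_points)) {
    env_f <- signal_env(c6 = br$fold_points[k], c12 = 100)
    J <- morphoswitch:::circuit_jacobian(br$fold_states[[k]], env_f, p)
    scale <- prod(apply(abs(J), 1, max))
    expect_lt(abs(det(J)), 1e-6 * scale)
  }
})

test_that("bistable region map: counting oracle and degenerate limits", {
  # repression constants -> Inf reduces to the receiver: empty region
  pinf <- morpho_params(K_lac = 1e12, K_tet = 1e12)
  bm0 <- map_bistable_region(log_grid(n = 8), pinf)
  expect_equal(sum(bm0$bistable), 0)
  expect_length(bm0$boundary, 0)

  p <- default_params()
  bm <- map_bistable_region(log_grid(n = 8), p, iptg = 10)
  expect_true(all(bm$counts %in% 1:3))
  i200 <- which.min(abs(log(bm$c6 / 200)))
  j2000 <- which.min(abs(log(bm$c12 / 2000)))
  i20 <- which.min(abs(log(bm$c6 / 20)))
  expect_true(bm$bistable[i200, j2000])
  expect_false(bm$bistable[i20, j2000])
  expect_gt(length(bm$boundary), 0)
})

test_that("hysteresis protocol has the stated readout structure", {
  p <- default_params(phase = "liquid")
  grid <- list(c6 = c(1, 3, 10, 37, 100, 300, 500, 1000),
               c12 = c(1, 3, 10, 50, 100, 300, 1000, 5000))
  h6 <- hysteresis_protocol("C6", grid, p)
  expect_true(all(h6$readout >= -1 & h6$readout <= 1))
  # reinforcing condition: C6-conditioned cells exposed to 500 nM C6 stay
  # strongly CFP
  expect_gt(h6$readout[grid$c6 == 500, grid$c12 == 1], 0.8)
  # monostable point erases history at long exposure
  h6l <- hysteresis_protocol("C6", grid, p, t_exposure = 60)
  h12l <- hysteresis_protocol("C12", grid, p, t_exposure = 60)
  iy <- which(grid$c6 == 1)
  jy <- which(grid$c12 == 5000)
  expect_equal(h6l$readout[iy, jy], h12l$readout[iy, jy], tolerance = 1e-3)
  expect_lt(h6l$readout[iy, jy], -0.8)
})

test_that("IPTG derepression shifts the bistable window to higher C6", {
  # adding IPTG weakens LacI, so low C6 no longer sustains bistability:
  # the window's lower fold moves up monotonically with IPTG
  p <- default_params()
  lower_fold <- function(iptg, c12) {
    c6s <- 10^seq(0, 3, length.out = 25)
    counts <- vapply(c6s, function(c6)
      n_stable(signal_env(c6 = c6, c12 = c12, iptg = iptg), p), numeric(1))
    expect_true(any(counts >= 2))
    min(c6s[counts >= 2])
  }
  for (c12 in c(100, 2000)) {
    folds <- vapply(c(0, 5, 20), lower_fold, numeric(1), c12 = c12)
    expect_true(all(diff(folds) > 0))
  }
})

test_that("grid exports write long CSV plus JSON metadata", {
  p <- default_params()
  grid <- list(c6 = 10^seq(0, 2, length.out = 8),
               c12 = 10^seq(0, 2, length.out = 8))
  h <- hysteresis_protocol("C6", grid, p, t_exposure = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(h, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 64)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$conditioning, "C6")
})
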