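test_that("generators are pure functions of their seed", {
  grid <- expand.grid(c6 = c(0, 100), c12 = c(0, 200))
  a <- generate_plate(p_liquid, grid, seed = 3)
  b <- generate_plate(p_liquid, grid, seed = 3)
  expect_identical(a, b)
  c <- generate_plate(p_liquid, grid, seed = 4)
  expect_false(identical(a$cfp, c$cfp))
  fa <- generate_flow(p_liquid, "C6", signal_env(c6 = 37, c12 = 100),
                      n_cells = 150, seed = 3)
  fb <- generate_flow(p_liquid, "C6", signal_env(c6 = 37, c12 = 100),
                      n_cells = 150, seed = 3)
  expect_identical(fa, fb)
})

test_that("noise-free plate data equal growth times per-cell model exactly", {
  grid <- data.frame(c6 = 150, c12 = 0)
  gm <- growth_model()
  d <- generate_plate(p_liquid, grid, growth = gm,
                      noise = noise_model(sd_mult = 0, background = 0),
                      seed = 1, rfp0 = 500)
  tr <- integrate_circuit(rep(0, 6), signal_env(c6 = 150), p_liquid,
                          t_end = max(d$t), dt_out = 1 / 6)
  idx <- match(round(d$t, 6), round(tr$times, 6))
  expect_equal(d$cfp, gm$od(d$t) * tr$states[idx, "cfp"], tolerance = 1e-6)
  expect_equal(d$rfp, gm$od(d$t) * 500, tolerance = 1e-9)
})

test_that("generated grids reproduce the exclusive / receiver contrast", {
  grid <- data.frame(c6 = c(500, 500), c12 = c(0, 500))
  nz <- noise_model(sd_mult = 0, background = 0)
  d_ex <- generate_plate(p_liquid, grid, noise = nz, seed = 1)
  d_rc <- generate_plate(make_receiver_params(), grid, noise = nz, seed = 1)
  last_ratio <- function(d, c12val) {
    w <- d[d$c12 == c12val, ]
    w <- w[which.max(w$t), ]
    w$yfp / w$cfp
  }
  # with both signals present the exclusive variant suppresses the minor
  # channel >= 10x more strongly than the receiver does
  expect_gt(last_ratio(d_rc, 500), 10 * last_ratio(d_ex, 500))
})

test_that("flow generator: zero heterogeneity collapses to the bulk result", {
  env <- signal_env(c6 = 37, c12 = 100)
  d <- generate_flow(p_liquid, "C6", env, n_cells = 120,
                     noise = noise_model(sd_mult = 0, cv_cell = 0), seed = 1)
  sched <- list(list(t_end = 2, env = signal_env(c6 = 500)),
                list(t_end = 7, env = env))
  bulk <- integrate_circuit(rep(0, 6), sched, p_liquid)
  bulk_end <- bulk$states[nrow(bulk$states), ]
  expect_lt(max(abs(d$cfp - bulk_end[["cfp"]])) / bulk_end[["cfp"]], 1e-6)
  expect_lt(diff(range(d$yfp)), 1e-6 * (1 + max(d$yfp)))
})

test_that("flow samples are unimodal in monostable and split in bistable", {
  deep_cfp <- signal_env(c6 = 500, c12 = 0)
  d6 <- generate_flow(p_liquid, "C6", deep_cfp, n_cells = 300, seed = 2)
  d12 <- generate_flow(p_liquid, "C12", deep_cfp, n_cells = 300, seed = 2)
  r <- function(d) (d$cfp - d$yfp) / (d$cfp + d$yfp + 1e-9)
  expect_true(all(r(d6) > 0.5))
  expect_true(all(r(d12) > 0.5))   # monostability erases history
  bist <- signal_env(c6 = 37, c12 = 100)
  b6 <- generate_flow(p_liquid, "C6", bist, n_cells = 300, seed = 3)
  b12 <- generate_flow(p_liquid, "C12", bist, n_cells = 300, seed = 3)
  expect_gt(median(r(b6)), 0)
  expect_lt(median(r(b12)), 0)
})

test_that("RFP gate discards dim cells only", {
  d <- generate_flow(p_liquid, "C6", signal_env(c6 = 100), n_cells = 400,
                     noise = noise_model(cv_cell = 0.8), seed = 5)
  expect_true(all(d$rfp >= 0.2 * 500))
  expect_lt(nrow(d), 400)
})

test_that("kymograph fixtures carry recoverable ground truth", {
  for (shape in c("static", "moving", "absent")) {
    fx <- generate_kymograph_fixture(shape, seed = 8)
    truth <- attr(fx, "truth")
    tr <- locate_boundary(normalize_channels(fx))
    v <- classify_boundary(tr, L = 10)
    expect_equal(v$label, truth$label, info = shape)
    if (shape == "moving")
      expect_equal(tr$delta_beta, truth$delta_beta, tolerance = 10 / 80)
    if (shape == "absent") expect_equal(v$dominant, "YFP")
  }
})

test_that("synthetic writers persist data plus ground truth sidecar", {
  grid <- data.frame(c6 = 10, c12 = 0)
  d <- generate_plate(p_liquid, grid, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_synthetic(d, f)
  expect_true(file.exists(paste0(f, ".truth.json")))
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$params$K6, p_liquid$K6)
  expect_equal(truth$variant, "exclusive_receiver")
})
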