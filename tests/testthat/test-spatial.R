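test_that("antiparallel initial condition has exact averages and 4x sources", {
  cfg <- spatial_config(L = 8, n_x = 64)
  ic <- make_antiparallel_ic(200, 2000, source_fraction = 0.25, config = cfg)
  expect_equal(max(ic$c6), 800)                     # 4x amplitude
  expect_equal(mean(ic$c6), 200)
  expect_equal(mean(ic$c12), 2000)
  # orientation: C12 left, C6 right
  expect_gt(ic$c12[1], 0); expect_equal(ic$c6[1], 0)
  expect_gt(ic$c6[cfg$n_x], 0); expect_equal(ic$c12[cfg$n_x], 0)
  # zero average gives a zero field
  ic0 <- make_antiparallel_ic(0, 0, config = cfg)
  expect_true(all(ic0$c6 == 0) && all(ic0$c12 == 0))
  expect_error(make_antiparallel_ic(1, 1, source_fraction = 0.6,
                                    config = cfg), "overlap")
})

test_that("initial-condition means are exact for random geometries", {
  set.seed(11)
  for (k in 1:100) {
    cfg <- spatial_config(L = runif(1, 2, 30),
                          n_x = sample(16:200, 1))
    avg <- runif(2, 0, 5000)
    frac <- runif(1, 0.05, 0.5)
    ic <- make_antiparallel_ic(avg[1], avg[2], frac, cfg)
    expect_equal(mean(ic$c6), avg[1], tolerance = 1e-10)
    expect_equal(mean(ic$c12), avg[2], tolerance = 1e-10)
    conc <- runif(1, 0, 4e4)
    f <- make_central_source_ic(conc, frac, cfg)
    expect_equal(mean(f), conc * frac, tolerance = 1e-10)
  }
})

test_that("central source window is centred", {
  cfg <- spatial_config(L = 10, n_x = 101)
  f <- make_central_source_ic(1000, 0.2, cfg)
  com <- sum(cfg$x * f) / sum(f)
  expect_lt(abs(com - cfg$L / 2), cfg$dx / 2)
  expect_true(all(make_central_source_ic(0, 0.2, cfg) == 0))
})

test_that("no-flux diffusion conserves mass and fixes uniform fields", {
  # cells with negligible synthesis: pure diffusion of the signals
  p0 <- morpho_params(a_R = 1e-12, b_R = 1e-12, a_F = 1e-12, b_F = 1e-12)
  cfg <- spatial_config(L = 6, n_x = 80, t_end = 12)
  ic <- make_antiparallel_ic(150, 900, config = cfg)
  sf <- simulate_rd(cfg, p0, ic)
  m6 <- rowMeans(sf$c6); m12 <- rowMeans(sf$c12)
  expect_lt(max(abs(m6 - 150)) / 150, 1e-6)
  expect_lt(max(abs(m12 - 900)) / 900, 1e-6)
  # uniform initial condition stays constant in time
  icu <- list(c6 = rep(40, cfg$n_x), c12 = rep(70, cfg$n_x))
  sfu <- simulate_rd(cfg, p0, icu)
  expect_lt(max(abs(sfu$c6 - 40)), 1e-9)
  expect_lt(max(abs(sfu$c12 - 70)), 1e-9)
})

test_that("long runs homogenise to the spatial average", {
  cfg <- spatial_config(L = 6, n_x = 60, t_end = 100, dt_out = 5)
  ic <- make_antiparallel_ic(200, 2000, config = cfg)
  sf <- simulate_rd(cfg, default_params(), ic)
  nt <- length(sf$times)
  expect_lt(max(abs(sf$c6[nt, ] - 200)) / 200, 0.01)
  expect_lt(max(abs(sf$c12[nt, ] - 2000)) / 2000, 0.01)
})

test_that("fields and intracellular states stay non-negative", {
  cfg <- spatial_config(L = 6, n_x = 48, t_end = 6)
  ic <- make_antiparallel_ic(50, 500, config = cfg)
  sf <- simulate_rd(cfg, default_params(), ic)
  for (comp in c("c6", "c12", "lacI", "tetR", "cfp", "yfp"))
    expect_true(all(sf[[comp]] >= 0), info = comp)
})

test_that("relay with zero gain reduces to plain diffusion", {
  cfg <- spatial_config(L = 10, n_x = 60, t_end = 6, k_relay = 0)
  p <- default_params("relay_c6_to_c12")
  sf_relay <- simulate_relay(cfg, p, primary = "C6", source_conc = 4000,
                             source_fraction = 0.2)
  src <- make_central_source_ic(4000, 0.2, cfg)
  sf_plain <- simulate_rd(cfg, p, list(c6 = src, c12 = numeric(cfg$n_x)))
  expect_equal(sf_relay$c12, sf_plain$c12)
  expect_equal(sf_relay$cfp, sf_plain$cfp)
})

test_that("relay production is one-way: primary conserved, secondary grows", {
  cfg <- spatial_config(L = 20, n_x = 100, t_end = 12)
  p <- default_params("relay_c6_to_c12")
  sf <- simulate_relay(cfg, p, primary = "C6")
  m6 <- rowMeans(sf$c6); m12 <- rowMeans(sf$c12)
  expect_lt(max(abs(m6 - m6[1])) / m6[1], 1e-6)
  expect_true(all(diff(m12) >= 0))
  expect_gt(m12[length(m12)], 0)
})

test_that("phase trajectories expose per-position paths and the mean path", {
  cfg <- spatial_config(L = 6, n_x = 48, t_end = 60, dt_out = 2)
  ic <- make_antiparallel_ic(100, 1000, config = cfg)
  sf <- simulate_rd(cfg, default_params(), ic)
  ph <- phase_trajectories(sf)
  expect_equal(ph$mean$c6, rep(100, nrow(ph$mean)), tolerance = 1e-6)
  expect_equal(ph$mean$c12, rep(1000, nrow(ph$mean)), tolerance = 1e-6)
  # homogenisation: every path terminates within 1% of the mean
  for (path in ph$paths) {
    expect_lt(abs(path$c6[nrow(path)] - 100) / 100, 0.01)
    expect_lt(abs(path$c12[nrow(path)] - 1000) / 1000, 0.01)
  }
  # relay mean path moves along the secondary axis only
  cfgr <- spatial_config(L = 20, n_x = 80, t_end = 8)
  sfr <- simulate_relay(cfgr, default_params("relay_c6_to_c12"), "C6")
  phr <- phase_trajectories(sfr)
  expect_lt(diff(range(phr$mean$c6)) / phr$mean$c6[1], 1e-6)
  expect_true(all(diff(phr$mean$c12) >= 0))
})

test_that("spatial CSV export round-trips through the kymograph reader", {
  cfg <- spatial_config(L = 4, n_x = 16, t_end = 2, dt_out = 1)
  ic <- make_antiparallel_ic(100, 1000, config = cfg)
  sf <- simulate_rd(cfg, default_params(), ic)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spatial_csv(sf, f)
  back <- read_kymograph_csv(f)
  expect_equal(back$x, sf$x)
  expect_equal(back$cfp, unname(sf$cfp), ignore_attr = TRUE)
})
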