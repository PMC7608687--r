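# Synthetic-data generators: plate-fluorometer grids, conditioning/exposure
# flow-like samples, and kymograph fixtures, all with serialised ground
# truth so downstream tests are closed-loop.

#' Logistic growth model for bulk culture
#'
#' @param od0 Initial optical density.
#' @param rate Exponential growth rate (1/h).
#' @param carrying Carrying capacity (OD units).
#' @return A `growth_model` object with an `od(t)` evaluator.
#' @export
growth_model <- function(od0 = 3e-4, rate = 0.7, carrying = 1.0) {
  if (od0 <= 0 || rate <= 0 || carrying <= od0)
    stop("growth model requires 0 < od0 < carrying and rate > 0")
  structure(list(od0 = od0, rate = rate, carrying = carrying,
                 od = function(t) {
                   carrying / (1 + ((carrying - od0) / od0) * exp(-rate * t))
                 }),
            class = "growth_model")
}

#' Measurement / heterogeneity noise model
#'
#' @param sd_mult Multiplicative lognormal sd per fluorescence read.
#' @param background Additive background (a.u.), as measured on blank
#'   wells.
#' @param cv_cell Cell-to-cell coefficient of variation of synthesis rates
#'   (flow mode).
#' @return A `noise_model` object.
#' @export
noise_model <- function(sd_mult = 0.05, background = 50, cv_cell = 0.25) {
  if (sd_mult < 0 || background < 0 || cv_cell < 0)
    stop("noise parameters must be >= 0")
  structure(list(sd_mult = sd_mult, background = background,
                 cv_cell = cv_cell),
            class = "noise_model")
}

mult_noise <- function(n, sd) {
  if (sd <= 0) rep(1, n) else rlnorm(n, meanlog = -sd^2 / 2, sdlog = sd)
}

#' Generate synthetic plate-fluorometer timecourses
#'
#' Emulates a microplate dose-response assay: for each (C6, C12) condition,
#' bulk fluorescence is the product of logistic culture density and the
#' per-cell protein level from the circuit model, with constitutive RFP,
#' multiplicative read noise and additive background. Reads every 10 min
#' for ~1000 min by default.
#'
#' @param params Ground-truth `morpho_params`.
#' @param env_grid Data frame of conditions with columns `c6`, `c12` (nM)
#'   and optional `iptg`, `atc`.
#' @param growth A [growth_model()].
#' @param noise A [noise_model()].
#' @param n_reps Replicates per condition.
#' @param seed Integer seed; output is a pure function of arguments + seed.
#' @param times Measurement times (h).
#' @param rfp0 Constitutive per-cell RFP level (a.u.).
#' @return A long data frame (class `plate_timecourse_set`) with columns
#'   `well`, `rep`, `c6`, `c12`, `iptg`, `atc`, `t`, `od`, `rfp`, `cfp`,
#'   `yfp`. Ground truth is attached as attributes `params`, `growth`,
#'   `noise`, `rfp0`, `variant`.
#' @export
generate_plate <- function(params, env_grid, growth = growth_model(),
                           noise = noise_model(), n_reps = 1, seed = 1L,
                           times = seq(0, 1000, by = 10) / 60, rfp0 = 500) {
  validate_params(params)
  if (nrow(env_grid) == 0) stop("env_grid must be non-empty")
  if (is.null(env_grid$iptg)) env_grid$iptg <- 0
  if (is.null(env_grid$atc)) env_grid$atc <- 0
  od <- growth$od(times)
  out <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(env_grid))) {
      env <- signal_env(env_grid$c6[i], env_grid$c12[i],
                        env_grid$iptg[i], env_grid$atc[i])
      tr <- .integrate_cpp(rep(0, 6), times, pack_params(params),
                           variant_code(params), env$c6, env$c12,
                           env$iptg, env$atc, 1e-8, 1e-10)
      for (r in seq_len(n_reps)) {
        nt <- length(times)
        rows[[length(rows) + 1]] <- data.frame(
          well = sprintf("c%02d_r%d", i, r), rep = r,
          c6 = env$c6, c12 = env$c12, iptg = env$iptg, atc = env$atc,
          t = times, od = od,
          rfp = od * rfp0 * mult_noise(nt, noise$sd_mult) + noise$background,
          cfp = od * tr[, 5] * mult_noise(nt, noise$sd_mult) + noise$background,
          yfp = od * tr[, 6] * mult_noise(nt, noise$sd_mult) + noise$background)
      }
    }
    do.call(rbind, rows)
  })
  structure(out, params = params, growth = growth, noise = noise,
            rfp0 = rfp0, variant = params$variant,
            class = c("plate_timecourse_set", "data.frame"))
}

#' Generate a flow-cytometry-like conditioning / exposure sample
#'
#' Each cell draws a lognormal scaling of its synthesis rates (cell-to-cell
#' CV from the noise model), runs the conditioning (500 nM of one signal,
#' 2 h from the naive state) then exposure (5 h at the target environment)
#' protocol, and reports per-cell CFP / YFP / RFP with multiplicative
#' measurement noise. Cells below the RFP gate floor are discarded,
#' standing in for RFP-positive gating.
#'
#' @param params Ground-truth `morpho_params`.
#' @param conditioning `"C6"` or `"C12"` (500 nM, 2 h by default).
#' @param exposure_env [signal_env()] applied after the wash.
#' @param n_cells Number of cells before gating (>= 100).
#' @param noise A [noise_model()]; `cv_cell` drives the heterogeneity.
#' @param seed Integer seed.
#' @param t_condition,conditioning_conc,t_exposure Protocol settings.
#' @param rfp0 Mean per-cell RFP (a.u.); gate floor is `0.2 * rfp0`.
#' @return Data frame (class `flow_sample`) with `cell`, `cfp`, `yfp`,
#'   `rfp`; ground truth attached as attributes.
#' @export
generate_flow <- function(params, conditioning = c("C6", "C12"),
                          exposure_env, n_cells = 1000,
                          noise = noise_model(), seed = 1L,
                          t_condition = 2, conditioning_conc = 500,
                          t_exposure = 5, rfp0 = 500) {
  conditioning <- match.arg(conditioning)
  validate_params(params)
  if (n_cells < 100) stop("n_cells must be >= 100")
  cv <- noise$cv_cell
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    fF <- rlnorm(n_cells, -sdlog^2 / 2, sdlog)   # output synthesis scaling
    fR <- rlnorm(n_cells, -sdlog^2 / 2, sdlog)   # receptor synthesis scaling
    base <- pack_params(params)
    pm <- matrix(rep(base, each = n_cells), nrow = n_cells)
    colnames(pm) <- .param_names
    pm[, "a_F"] <- pm[, "a_F"] * fF
    pm[, "b_F"] <- pm[, "b_F"] * fF
    pm[, "a_R"] <- pm[, "a_R"] * fR
    pm[, "b_R"] <- pm[, "b_R"] * fR
    # reference receptor level tracks the cell's own receptor capacity, so
    # the scaled promoter activity stays a fraction of capacity
    pm[, "luxR_ref"] <- pm[, "luxR_ref"] * fR
    pm[, "lasR_ref"] <- pm[, "lasR_ref"] * fR
    vc <- variant_code(params)
    cond <- c(c6 = if (conditioning == "C6") conditioning_conc else 0,
              c12 = if (conditioning == "C12") conditioning_conc else 0)
    envs1 <- matrix(rep(c(cond, exposure_env$iptg, exposure_env$atc),
                        each = n_cells), nrow = n_cells)
    y1 <- .integrate_batch_cpp(matrix(0, n_cells, 6), envs1, pm, vc,
                               t_condition)
    envs2 <- matrix(rep(c(exposure_env$c6, exposure_env$c12,
                          exposure_env$iptg, exposure_env$atc),
                        each = n_cells), nrow = n_cells)
    y2 <- .integrate_batch_cpp(y1, envs2, pm, vc, t_exposure)
    rfp <- rfp0 * rlnorm(n_cells, -sdlog^2 / 2, sdlog) *
      mult_noise(n_cells, noise$sd_mult)
    df <- data.frame(cell = seq_len(n_cells),
                     cfp = y2[, 5] * mult_noise(n_cells, noise$sd_mult),
                     yfp = y2[, 6] * mult_noise(n_cells, noise$sd_mult),
                     rfp = rfp)
    df <- df[df$rfp >= 0.2 * rfp0, , drop = FALSE]
    structure(df, params = params, conditioning = conditioning,
              exposure = exposure_env, noise = noise, rfp0 = rfp0,
              class = c("flow_sample", "data.frame"))
  })
}

#' Generate an analytic kymograph fixture with known boundary trajectory
#'
#' Builds sigmoidal antiparallel fluorescence fronts whose crossing follows
#' a prescribed trajectory: `"static"` (fixed at 0.5 L), `"moving"`
#' (linear drift from 0.3 L to 0.6 L, displacement 0.3 L), or `"absent"`
#' (single channel only). Intensities ramp up over time from a quarter of
#' full scale, so the boundary is detectable from the first frame, and
#' carry optional multiplicative noise. Ground truth (`beta`, `label`,
#' `delta_beta`) is attached.
#'
#' @param shape `"static"`, `"moving"` or `"absent"`.
#' @param grid List with `n_x`, `n_t`, `L` (mm), `t_end` (h).
#' @param seed Integer seed for the noise.
#' @param noise_sd Multiplicative lognormal sd per pixel.
#' @param front_width Sigmoid front width as a fraction of `L`.
#' @return List with `x`, `times`, `cfp`, `yfp` and a `truth` attribute
#'   carrying `beta`, `label`, `delta_beta`.
#' @export
generate_kymograph_fixture <- function(shape = c("static", "moving", "absent"),
                                       grid = list(n_x = 80, n_t = 40,
                                                   L = 10, t_end = 24),
                                       seed = 1L, noise_sd = 0.02,
                                       front_width = 0.05) {
  shape <- match.arg(shape)
  L <- grid$L
  dx <- L / grid$n_x
  xs <- (seq_len(grid$n_x) - 0.5) * dx
  ts <- seq(0, grid$t_end, length.out = grid$n_t)
  amp <- 0.25 + 0.75 * ts / grid$t_end
  w <- front_width * L
  beta <- switch(shape,
                 static = rep(0.5 * L, grid$n_t),
                 moving = seq(0.3 * L, 0.6 * L, length.out = grid$n_t),
                 absent = rep(NA_real_, grid$n_t))
  cfp <- matrix(0, grid$n_t, grid$n_x)
  yfp <- matrix(0, grid$n_t, grid$n_x)
  for (k in seq_len(grid$n_t)) {
    if (shape == "absent") {
      yfp[k, ] <- amp[k]
      cfp[k, ] <- 0
    } else {
      cfp[k, ] <- amp[k] / (1 + exp((xs - beta[k]) / w))
      yfp[k, ] <- amp[k] / (1 + exp(-(xs - beta[k]) / w))
    }
  }
  if (noise_sd > 0) {
    nz <- with_seed(seed, list(c = mult_noise(length(cfp), noise_sd),
                               y = mult_noise(length(yfp), noise_sd)))
    cfp <- cfp * matrix(nz$c, nrow(cfp))
    yfp <- yfp * matrix(nz$y, nrow(yfp))
  }
  truth <- list(beta = beta,
                label = switch(shape, static = "S", moving = "M",
                               absent = "N"),
                delta_beta = if (shape == "moving") 0.3 * L
                             else if (shape == "static") 0 else NA_real_)
  structure(list(x = xs, times = ts, cfp = cfp, yfp = yfp),
            truth = truth, class = "kymo_fixture")
}

#' Write a synthetic dataset with its ground truth sidecar
#'
#' CSV for the data plus `<path>.truth.json` holding the generating
#' parameters, so downstream fits can be checked closed-loop.
#'
#' @param x A `plate_timecourse_set` or `flow_sample`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  tr <- list(params = unclass(attr(x, "params")),
             variant = attr(x, "variant"),
             conditioning = attr(x, "conditioning"),
             rfp0 = attr(x, "rfp0"))
  jsonlite::write_json(tr[!vapply(tr, is.null, logical(1))],
                       paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
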