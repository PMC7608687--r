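# Ratiometric promoter-activity extraction and staged parameter inference
# from plate-fluorometer timecourses.

#' Ratiometric promoter activity from one plate timecourse
#'
#' Restricts a well's timecourse to the exponential-phase window (OD within
#' `od_window`), background-corrects using the blank value, and computes the
#' per-time ratio of each fluorescence channel to the constitutive RFP
#' reference. Reports the window mean ratio (primary estimate) and the
#' least-squares slope of the ratio against time (secondary estimate).
#' Because both channels share the culture density and instrument gain, the
#' ratio cancels them.
#'
#' @param tc Data frame for a single well with columns `t`, `od`, `rfp`,
#'   and the fluorescence channels.
#' @param od_window Length-2 OD bounds of the exponential-phase window.
#' @param channels Channels to quantify.
#' @param background Additive background to subtract from all fluorescence
#'   channels (blank-well value).
#' @return List per channel with `mean_ratio`, `slope`, and the `window`
#'   (time range used).
#' @export
promoter_activity <- function(tc, od_window = c(0.05, 0.3),
                              channels = c("cfp", "yfp"), background = 0) {
  need <- c("t", "od", "rfp", channels)
  if (!all(need %in% names(tc)))
    stop("timecourse must have columns ", paste(need, collapse = ", "))
  sel <- tc$od >= od_window[1] & tc$od <= od_window[2]
  well <- if (!is.null(tc$well)) tc$well[1] else "<unnamed>"
  if (!any(sel))
    stop(sprintf("well %s: OD never enters window [%g, %g]", well,
                 od_window[1], od_window[2]))
  sub <- tc[sel, , drop = FALSE]
  rfp <- sub$rfp - background
  if (any(rfp <= 0))
    stop(sprintf("well %s: non-positive background-corrected RFP in window",
                 well))
  out <- lapply(channels, function(ch) {
    ratio <- (sub[[ch]] - background) / rfp
    sl <- if (nrow(sub) > 1) unname(coef(lm(ratio ~ sub$t))[2]) else NA_real_
    list(mean_ratio = mean(ratio), slope = sl,
         window = range(sub$t))
  })
  names(out) <- channels
  out
}

.default_bounds <- list(
  a_F = c(1, 1e4), b_F = c(1e-3, 10), a_R = c(0.01, 100),
  K6 = c(1, 1e4), n6 = c(1, 4), K12 = c(1, 1e5), n12 = c(1, 4),
  K_lac = c(0.1, 1e3), n_lac = c(1, 4), K_tet = c(0.1, 1e3), n_tet = c(1, 4),
  K_iptg = c(0.1, 1e3), K_atc = c(0.1, 1e3),
  g_lacI = c(0.05, 10), g_tetR = c(0.05, 10), g_cfp = c(0.01, 5),
  g_yfp = c(0.01, 5)
)

# Predicted F/RFP curves for every condition in a plate set.
predict_ratios <- function(params, conditions, times, rfp0) {
  pv <- pack_params(params)
  vc <- variant_code(params)
  # cells start from the naive state at inoculation (t = 0), which may be
  # well before the first analysed read
  prepend <- times[1] > 0
  tt <- if (prepend) c(0, times) else times
  lapply(seq_len(nrow(conditions)), function(i) {
    m <- .integrate_cpp(rep(0, 6), tt, pv, vc,
                        conditions$c6[i], conditions$c12[i],
                        conditions$iptg[i], conditions$atc[i], 1e-6, 1e-8)
    if (prepend) m <- m[-1, , drop = FALSE]
    cbind(cfp = m[, 5] / rfp0, yfp = m[, 6] / rfp0)
  })
}

# Observed (background-corrected) F/RFP curves, averaged over replicates,
# restricted to the exponential-phase OD window.
observed_ratios <- function(data, od_window, background, rfp0) {
  conditions <- unique(data[, c("c6", "c12", "iptg", "atc")])
  rownames(conditions) <- NULL
  sel_t <- sort(unique(data$t[data$od >= od_window[1] &
                                data$od <= od_window[2]]))
  if (length(sel_t) == 0) stop("no measurements inside the OD window")
  obs <- lapply(seq_len(nrow(conditions)), function(i) {
    sub <- data[data$c6 == conditions$c6[i] & data$c12 == conditions$c12[i] &
                  data$iptg == conditions$iptg[i] &
                  data$atc == conditions$atc[i] & data$t %in% sel_t, ]
    agg_c <- tapply((sub$cfp - background) / (sub$rfp - background),
                    sub$t, mean)
    agg_y <- tapply((sub$yfp - background) / (sub$rfp - background),
                    sub$t, mean)
    # rfp-ratio scale: observed F/RFP equals protein/rfp0, so keep as-is
    cbind(cfp = as.numeric(agg_c), yfp = as.numeric(agg_y))
  })
  list(conditions = conditions, times = sel_t, obs = obs)
}

#' Fit a subset of circuit parameters to plate timecourse data
#'
#' Multi-start bounded local optimisation (L-BFGS-B on log10-transformed
#' parameters) of the summed squared error between model-predicted and
#' observed F/RFP trajectories inside the exponential-phase window.
#' Deterministic given `seed`; the best restart is returned with all
#' restart losses logged.
#'
#' @param variant Circuit variant the data were produced by.
#' @param data A `plate_timecourse_set` (or equivalent data frame).
#' @param free Character vector of parameter names to fit.
#' @param fixed A `morpho_params` supplying every non-free parameter.
#' @param bounds Named list of length-2 bounds (natural scale); defaults
#'   cover generous biophysical ranges.
#' @param od_window Exponential-phase OD window.
#' @param n_restarts Number of optimisation restarts (>= 1).
#' @param seed Integer seed.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return A `morpho_fit`: list with `params` (fitted `morpho_params`),
#'   `free`, `loss`, `restart_losses`, `uncertainty` (curvature-based sd of
#'   log10 parameters), `convergence`, `seed`.
#' @export
fit_stage <- function(variant, data, free, fixed,
                      bounds = list(), od_window = c(0.05, 0.3),
                      n_restarts = 4, seed = 1L, maxit = 300) {
  validate_params(fixed)
  if (length(intersect(free, names(fixed))) != length(free))
    stop("unknown parameter names in free: ",
         paste(setdiff(free, names(fixed)), collapse = ", "))
  background <- attr(data, "noise")$background
  if (is.null(background)) background <- 0
  rfp0 <- attr(data, "rfp0")
  if (is.null(rfp0)) stop("data must carry an rfp0 attribute (RFP per cell)")
  ob <- observed_ratios(as.data.frame(data), od_window, background, rfp0)

  # identifiability screen: each sensing parameter needs >= 2 distinct
  # levels of its signal among the conditions
  n_c6 <- length(unique(ob$conditions$c6))
  n_c12 <- length(unique(ob$conditions$c12))
  if (any(c("K6", "n6") %in% free) && n_c6 < 2)
    warning("K6/n6 requested with < 2 distinct C6 levels: ",
            "expect a flat loss surface in those directions")
  if (any(c("K12", "n12") %in% free) && n_c12 < 2)
    warning("K12/n12 requested with < 2 distinct C12 levels: ",
            "expect a flat loss surface in those directions")

  p_work <- fixed
  p_work$variant <- variant
  if (length(free) == 0) {
    pr <- predict_ratios(p_work, ob$conditions, ob$times, rfp0)
    loss0 <- sum(mapply(function(o, p) sum((o - p)^2), ob$obs, pr))
    return(structure(list(params = p_work, free = character(0), loss = loss0,
                          restart_losses = loss0, uncertainty = numeric(0),
                          convergence = 0L, seed = seed),
                     class = "morpho_fit"))
  }

  bnd <- modifyList(.default_bounds, bounds)
  miss <- setdiff(free, names(bnd))
  if (length(miss)) stop("no bounds for: ", paste(miss, collapse = ", "))
  lo <- log10(vapply(free, function(f) bnd[[f]][1], numeric(1)))
  hi <- log10(vapply(free, function(f) bnd[[f]][2], numeric(1)))

  best_seen <- list(value = Inf, par = NULL)
  loss_fn <- function(theta) {
    if (any(!is.finite(theta))) return(1e12)
    p <- p_work
    for (k in seq_along(free)) p[[free[k]]] <- unname(10^theta[k])
    p$luxR_ref <- (p$a_R + p$b_R) / p$g_luxR
    p$lasR_ref <- (p$a_R + p$b_R) / p$g_lasR
    pr <- tryCatch(predict_ratios(p, ob$conditions, ob$times, rfp0),
                   error = function(e) NULL)
    if (is.null(pr)) return(1e12)
    val <- sum(mapply(function(o, q) sum((o - q)^2), ob$obs, pr))
    if (!is.finite(val)) return(1e12)
    if (val < best_seen$value) best_seen <<- list(value = val, par = theta)
    val
  }

  starts <- with_seed(seed, {
    s <- matrix(runif(n_restarts * length(free)), n_restarts)
    t(apply(s, 1, function(u) lo + u * (hi - lo)))
  })
  if (length(free) == 1) starts <- matrix(starts, ncol = 1)
  starts[1, ] <- (lo + hi) / 2
  fits <- lapply(seq_len(n_restarts), function(r) {
    optim(starts[r, ], loss_fn, method = "L-BFGS-B", lower = lo, upper = hi,
          control = list(maxit = maxit))
  })
  losses <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(losses)]]
  # L-BFGS-B can emit non-finite parameters when the loss reaches its
  # numerical floor (noise-free data); fall back to the best point seen
  if (any(!is.finite(best$par)) || best_seen$value < best$value)
    best <- list(par = best_seen$par, value = best_seen$value,
                 convergence = best$convergence)
  p_fit <- p_work
  for (k in seq_along(free)) p_fit[[free[k]]] <- unname(10^best$par[k])
  p_fit$luxR_ref <- (p_fit$a_R + p_fit$b_R) / p_fit$g_luxR
  p_fit$lasR_ref <- (p_fit$a_R + p_fit$b_R) / p_fit$g_lasR
  validate_params(p_fit)

  unc <- tryCatch({
    H <- fd_jacobian(function(th) {
      fd_jacobian(loss_fn, th, h_rel = 1e-4)[1, ]
    }, best$par, h_rel = 1e-4)
    se <- suppressWarnings(sqrt(diag(solve((H + t(H)) / 2))))
    setNames(se, free)
  }, error = function(e) setNames(rep(NA_real_, length(free)), free))

  structure(list(params = p_fit, free = free, loss = best$value,
                 restart_losses = losses, uncertainty = unc,
                 convergence = best$convergence, seed = seed),
            class = "morpho_fit")
}

#' @export
print.morpho_fit <- function(x, ...) {
  cat(sprintf("<morpho_fit> %d free parameter(s), loss = %.4g\n",
              length(x$free), x$loss))
  if (length(x$free)) {
    v <- vapply(x$free, function(f) x$params[[f]], numeric(1))
    print(signif(v, 4))
  }
  invisible(x)
}

#' Staged parameter inference: Receiver first, then Exclusive Receiver
#'
#' Stage 1 fits the parameters shared with the plain Receiver circuit
#' (sensing constants, Hill coefficients and the output synthesis rate) to
#' Receiver-variant data; stage 2 fixes those values and fits the mutual
#' repression parameters on Exclusive Receiver data. The returned object
#' records which stage set each parameter. Growth/removal rates and the
#' inducer constants are treated as assay constants supplied via `fixed`.
#'
#' @param receiver_data Plate set generated by / from the Receiver variant
#'   (checked against its `variant` attribute).
#' @param exclusive_data Plate set from the Exclusive Receiver variant.
#' @param fixed A `morpho_params` supplying the assay constants.
#' @param free_stage1,free_stage2 Parameter names fitted in each stage.
#' @param seed,n_restarts,maxit Optimiser settings (both stages).
#' @return A `morpho_staged_fit`: list with `params` (final
#'   `morpho_params`, exclusive variant), `stage1`, `stage2` (both
#'   `morpho_fit`), and `provenance` (named character vector mapping each
#'   fitted parameter to its stage).
#' @export
staged_inference <- function(receiver_data, exclusive_data,
                             fixed = default_params(),
                             free_stage1 = c("K6", "n6", "K12", "n12", "a_F"),
                             free_stage2 = c("K_lac", "n_lac", "K_tet", "n_tet"),
                             seed = 1L, n_restarts = 4, maxit = 300) {
  v1 <- attr(receiver_data, "variant")
  v2 <- attr(exclusive_data, "variant")
  if (!is.null(v1) && v1 != "receiver")
    stop("receiver_data was generated by variant '", v1,
         "', expected 'receiver'")
  if (!is.null(v2) && v2 != "exclusive_receiver")
    stop("exclusive_data was generated by variant '", v2,
         "', expected 'exclusive_receiver'")
  if (length(intersect(free_stage1, free_stage2)))
    stop("stage 1 and stage 2 free sets must be disjoint")
  s1 <- fit_stage("receiver", receiver_data, free_stage1, fixed,
                  seed = seed, n_restarts = n_restarts, maxit = maxit)
  s2 <- fit_stage("exclusive_receiver", exclusive_data, free_stage2,
                  s1$params, seed = seed + 1L, n_restarts = n_restarts,
                  maxit = maxit)
  prov <- c(setNames(rep("stage1", length(free_stage1)), free_stage1),
            setNames(rep("stage2", length(free_stage2)), free_stage2))
  structure(list(params = s2$params, stage1 = s1, stage2 = s2,
                 provenance = prov),
            class = "morpho_staged_fit")
}

#' @export
print.morpho_staged_fit <- function(x, ...) {
  cat("<morpho_staged_fit>\n stage 1 (receiver): ")
  print(x$stage1)
  cat(" stage 2 (exclusive): ")
  print(x$stage2)
  invisible(x)
}
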