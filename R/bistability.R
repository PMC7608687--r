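# Equilibrium location, saddle-node continuation, bistable-region mapping and
# the conditioning/exposure hysteresis protocol.

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Reconstruct a consistent full state from a (lacI, tetR) pair: receptors and
# fluorescent proteins are slaved to the repressors at steady state.
state_from_repressors <- function(u, v, env, p) {
  phi_i <- hill_rep(env$iptg, p$K_iptg, p$n_iptg)
  phi_a <- hill_rep(env$atc, p$K_atc, p$n_atc)
  if (p$variant == "receiver") {
    luxR <- (p$b_R + p$a_R) / p$g_luxR
    lasR <- (p$b_R + p$a_R) / p$g_lasR
  } else {
    luxR <- (p$b_R + p$a_R * hill_rep(v * phi_a, p$K_tet, p$n_tet)) / p$g_luxR
    lasR <- (p$b_R + p$a_R * hill_rep(u * phi_i, p$K_lac, p$n_lac)) / p$g_lasR
  }
  h6 <- hill_act(env$c6, p$K6, p$n6)
  h12 <- hill_act(env$c12, p$K12, p$n12)
  A6 <- (luxR / p$luxR_ref) * (h6 + p$cross_c12 * h12)
  A12 <- (lasR / p$lasR_ref) * (h12 + p$cross_c6 * h6)
  c(luxR = luxR, lasR = lasR,
    lacI = u, tetR = v,
    cfp = (p$b_F + p$a_F * A6) / p$g_cfp,
    yfp = (p$b_F + p$a_F * A12) / p$g_yfp)
}

# One sweep of the reduced (lacI, tetR) self-consistency map.
reduced_map <- function(u, v, env, p) {
  s <- state_from_repressors(u, v, env, p)
  prod6 <- s[["cfp"]] * p$g_cfp   # shared bicistronic production
  prod12 <- s[["yfp"]] * p$g_yfp
  c(prod6 / p$g_lacI, prod12 / p$g_tetR)
}

damped_newton <- function(y0, env, params, tol, max_iter = 60) {
  y <- pmax(y0, 0)
  fy <- derivatives(y, env, params)
  for (it in seq_len(max_iter)) {
    res <- sqrt(sum(fy^2))
    if (res < tol) return(list(state = y, residual = res, converged = TRUE))
    J <- circuit_jacobian(y, env, params)
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) return(list(converged = FALSE))
    lambda <- 1
    repeat {
      ytry <- pmax(y + lambda * step, 0)
      ftry <- tryCatch(derivatives(ytry, env, params), error = function(e) NULL)
      if (!is.null(ftry) && sqrt(sum(ftry^2)) < res) {
        y <- ytry; fy <- ftry; break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) return(list(converged = FALSE))
    }
  }
  res <- sqrt(sum(fy^2))
  list(state = y, residual = res, converged = res < tol)
}

classify_equilibrium <- function(state, env, params) {
  J <- circuit_jacobian(state, env, params)
  ev <- eigen(J, only.values = TRUE)$values
  npos <- sum(Re(ev) > 0)
  stability <- if (npos == 0) "stable" else if (npos == 1) "saddle" else "unstable"
  list(stability = stability, eigenvalues = ev, jacobian = J)
}

#' Locate all equilibria of the circuit at one signal environment
#'
#' Damped-Newton refinement from a deterministic log-spaced multi-start grid
#' in (LacI, TetR) space, two fixed-point sweeps of the reduced
#' self-consistency map started from each single-pathway extreme, and
#' `n_starts` seeded random log-uniform starts. Converged roots are
#' deduplicated and classified by the eigenvalues of the analytic Jacobian.
#'
#' @param env A [signal_env()].
#' @param params A `morpho_params` object.
#' @param n_starts Number of additional random starts (>= 8).
#' @param tol Residual norm tolerance on the derivative vector (a.u./h).
#' @param seed Integer seed; the result is deterministic given it.
#' @return List of equilibria, each `list(state, stability, eigenvalues,
#'   residual, env)` with `stability` in `{"stable", "saddle", "unstable"}`,
#'   sorted by decreasing `cfp`. Empty list (with a warning) if no start
#'   converges.
#' @examples
#' eq <- find_equilibria(signal_env(c6 = 500), default_params())
#' vapply(eq, `[[`, "", "stability")
#' @export
find_equilibria <- function(env, params, n_starts = 16, tol = 1e-8,
                            seed = 1L) {
  validate_params(params)
  if (n_starts < 8) stop("n_starts must be >= 8")
  p <- params
  rep_lo <- p$b_F / max(p$g_lacI, p$g_tetR) + 1e-6
  rep_hi <- (p$b_F + p$a_F) / min(p$g_lacI, p$g_tetR)

  starts <- list()
  # single-pathway extremes pushed through the reduced map until settled
  for (init in list(c(rep_hi, rep_lo), c(rep_lo, rep_hi),
                    c(rep_lo, rep_lo), c(rep_hi, rep_hi))) {
    uv <- init
    for (k in 1:200) {
      uv_new <- reduced_map(uv[1], uv[2], env, p)
      if (max(abs(uv_new - uv) / (1 + abs(uv))) < 1e-12) break
      uv <- uv_new
    }
    starts[[length(starts) + 1]] <- uv
  }
  # deterministic log grid
  gl <- exp(seq(log(rep_lo), log(rep_hi), length.out = 4))
  for (u in gl) for (v in gl) starts[[length(starts) + 1]] <- c(u, v)
  # seeded random starts
  ru <- with_seed(seed, matrix(runif(2 * n_starts), ncol = 2))
  for (i in seq_len(n_starts))
    starts[[length(starts) + 1]] <-
      exp(log(rep_lo) + ru[i, ] * (log(rep_hi) - log(rep_lo)))

  roots <- list()
  scale_tol <- tol * max(1, p$a_F)
  for (uv in starts) {
    y0 <- state_from_repressors(uv[1], uv[2], env, p)
    sol <- damped_newton(y0, env, p, scale_tol)
    if (!isTRUE(sol$converged)) next
    dup <- FALSE
    for (r in roots) {
      d <- max(abs(sol$state - r$state) / (1 + pmax(abs(sol$state), abs(r$state))))
      if (d < 1e-4) { dup <- TRUE; break }
    }
    if (dup) next
    cls <- classify_equilibrium(sol$state, env, p)
    roots[[length(roots) + 1]] <- list(state = sol$state,
                                       stability = cls$stability,
                                       eigenvalues = cls$eigenvalues,
                                       residual = sol$residual,
                                       env = env)
  }
  if (length(roots) == 0) {
    warning("find_equilibria: no convergent start at this environment")
    return(list())
  }
  ord <- order(vapply(roots, function(r) -r$state[["cfp"]], numeric(1)))
  roots[ord]
}

count_stable <- function(env, params, ...) {
  eq <- find_equilibria(env, params, ...)
  sum(vapply(eq, function(r) r$stability == "stable", logical(1)))
}

# d(rhs)/d(theta) where theta = log10 of the continuation parameter.
env_theta_deriv <- function(state, env, params, free) {
  p <- params
  y <- as_state(state)
  h6 <- hill_act(env$c6, p$K6, p$n6)
  h12 <- hill_act(env$c12, p$K12, p$n12)
  d <- numeric(6)
  if (free == "c6") {
    dh <- log(10) * p$n6 * h6 * (1 - h6)
    dA6 <- (y["luxR"] / p$luxR_ref) * dh
    dA12 <- (y["lasR"] / p$lasR_ref) * p$cross_c6 * dh
  } else {
    dh <- log(10) * p$n12 * h12 * (1 - h12)
    dA6 <- (y["luxR"] / p$luxR_ref) * p$cross_c12 * dh
    dA12 <- (y["lasR"] / p$lasR_ref) * dh
  }
  d[3] <- p$a_F * dA6; d[5] <- p$a_F * dA6
  d[4] <- p$a_F * dA12; d[6] <- p$a_F * dA12
  d
}

set_free <- function(env, free, value) {
  env[[free]] <- value
  class(env) <- "signal_env"
  env
}

# Central-difference Jacobian of a vector function (used only by the fold
# polisher, where no analytic form is worth maintaining).
fd_jacobian <- function(fn, x, h_rel = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- h_rel * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# Polish a fold: solve f(y, p) = 0, J(y, p) w = 0, e'w = 1 by Newton.
polish_fold <- function(y0, p0, env0, free, params) {
  w0 <- {
    J <- circuit_jacobian(y0, set_free(env0, free, p0), params)
    sv <- svd(J)
    v <- sv$v[, 6]
    v / v[which.max(abs(v))]
  }
  anchor <- which.max(abs(w0))
  resid <- function(z) {
    y <- z[1:6]; pp <- exp(z[7]); w <- z[8:13]
    e <- set_free(env0, free, pp)
    J <- circuit_jacobian(y, e, params)
    c(derivatives(pmax(y, 0), e, params), as.numeric(J %*% w), w[anchor] - 1)
  }
  z <- c(y0, log(p0), w0)
  for (it in 1:30) {
    r <- resid(z)
    if (sqrt(sum(r^2)) < 1e-9 * max(1, params$a_F)) break
    J <- fd_jacobian(resid, z)
    dz <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dz)) return(NULL)
    z <- z + dz
    if (!all(is.finite(z))) return(NULL)
  }
  list(state = pmax(z[1:6], 0), p = exp(z[7]))
}

#' Continue an equilibrium branch in one signal and locate folds
#'
#' Pseudo-arclength continuation (secant predictor, bordered-Newton
#' corrector, adaptive step) of an equilibrium branch as `c6` or `c12`
#' varies, in log10 of the free parameter. Saddle-node (fold) points are
#' detected by a sign change of the tangent's parameter component, bracketed
#' by step bisection to a relative tolerance of 1e-4, and polished by Newton
#' on the extended fold system.
#'
#' @param env0 Base environment; its `free` component is the starting value
#'   of the continuation parameter (must be inside `range`).
#' @param free `"c6"` or `"c12"`.
#' @param range Length-2 positive numeric: parameter range to cover.
#' @param params A `morpho_params` object.
#' @param ds0 Initial arclength step (log10-parameter units).
#' @param start_state Optional starting equilibrium; located automatically
#'   when `NULL`.
#' @param max_steps Step budget before the branch is declared partial.
#' @return A `morpho_branch`: list with `param` (values along the branch),
#'   `states` (matrix), `stability`, `fold_points` (parameter values),
#'   `fold_states`, `free`, and `complete` (FALSE when the branch terminated
#'   early, with a `diagnostic`).
#' @export
continue_branch <- function(env0, free = c("c6", "c12"), range, params,
                            ds0 = 0.05, start_state = NULL, max_steps = 2000) {
  free <- match.arg(free)
  validate_params(params)
  if (length(range) != 2 || any(range <= 0) || diff(range) <= 0)
    stop("range must be positive and increasing")
  p_start <- env0[[free]]
  if (p_start < range[1] || p_start > range[2])
    stop("env0[[free]] must lie inside range")
  if (is.null(start_state)) {
    eq <- find_equilibria(env0, params)
    if (length(eq) == 0) stop("no equilibrium at env0 to start from")
    start_state <- eq[[1]]$state
  }
  th_lo <- log10(range[1]); th_hi <- log10(range[2])
  ds_min <- 1e-8; ds_max <- 0.08
  # scale each species by its saturation level so state directions are O(1)
  # and commensurate with the log10-parameter direction
  yscale <- with(params, c((a_R + b_R) / g_luxR, (a_R + b_R) / g_lasR,
                           (a_F + b_F) / g_lacI, (a_F + b_F) / g_tetR,
                           (a_F + b_F) / g_cfp, (a_F + b_F) / g_yfp))
  to_z <- function(y, th) c(y / yscale, th)
  from_z <- function(z) pmax(z[1:6] * yscale, 0)

  newton_corr <- function(z_pred, tang) {
    z <- z_pred
    for (it in 1:25) {
      e <- set_free(env0, free, 10^z[7])
      y <- from_z(z)
      fy <- derivatives(y, e, params) / yscale
      g <- sum(tang * (z - z_pred))
      r <- c(fy, g)
      if (sqrt(sum(r^2)) < 1e-10 * max(1, params$a_F))
        return(list(z = z, iters = it, ok = TRUE))
      J <- circuit_jacobian(y, e, params) * outer(1 / yscale, yscale)
      ftheta <- env_theta_deriv(y, e, params, free) / yscale
      A <- rbind(cbind(J, ftheta), matrix(tang, 1))
      dz <- tryCatch(solve(A, -r), error = function(e2) NULL)
      if (is.null(dz)) return(list(ok = FALSE))
      z <- z + dz
      if (!all(is.finite(z))) return(list(ok = FALSE))
    }
    list(ok = FALSE)
  }

  tangent_at <- function(z, t_prev) {
    e <- set_free(env0, free, 10^z[7])
    y <- from_z(z)
    J <- circuit_jacobian(y, e, params) * outer(1 / yscale, yscale)
    ftheta <- env_theta_deriv(y, e, params, free) / yscale
    A <- rbind(cbind(J, ftheta), matrix(t_prev, 1))
    t_new <- tryCatch(solve(A, c(rep(0, 6), 1)), error = function(e2) NULL)
    if (is.null(t_new)) return(NULL)
    t_new / sqrt(sum(t_new^2))
  }

  run_direction <- function(dir) {
    z <- to_z(start_state, log10(p_start))
    tang <- tangent_at(z, c(rep(0, 6), dir))
    if (is.null(tang)) return(NULL)
    if (sign(tang[7]) != dir && tang[7] != 0) tang <- -tang
    ds <- ds0
    pts <- list(z); tangs <- list(tang)
    folds <- list()
    diagnostic <- NULL
    for (step in seq_len(max_steps)) {
      z_pred <- z + ds * tang
      sol <- newton_corr(z_pred, tang)
      # reject steps that land far from the predictor (branch-jump guard)
      if (!isTRUE(sol$ok) ||
          sqrt(sum((sol$z - z)^2)) > 1.5 * ds) {
        ds <- ds / 2
        if (ds < ds_min) { diagnostic <- "step collapse"; break }
        next
      }
      z_new <- sol$z
      t_new <- tangent_at(z_new, tang)
      if (is.null(t_new)) { diagnostic <- "singular tangent"; break }
      if (sum(t_new * tang) < 0) t_new <- -t_new
      if (sign(tangs[[length(tangs)]][7]) != 0 &&
          sign(t_new[7]) != sign(tangs[[length(tangs)]][7]) &&
          sign(t_new[7]) != 0) {
        # fold between z and z_new: bisect the step until the bracket in
        # theta is tight, then polish
        z_a <- z; t_a <- tang; ds_b <- ds
        z_b <- z_new
        while (abs(z_b[7] - z_a[7]) > 1e-4 * max(abs(z_a[7]), 0.1) &&
               ds_b > ds_min) {
          ds_b <- ds_b / 2
          sol_m <- newton_corr(z_a + ds_b * t_a, t_a)
          if (!isTRUE(sol_m$ok)) break
          z_m <- sol_m$z
          t_m <- tangent_at(z_m, t_a)
          if (is.null(t_m)) break
          if (sum(t_m * t_a) < 0) t_m <- -t_m
          if (sign(t_m[7]) == sign(t_a[7])) { z_a <- z_m; t_a <- t_m }
          else z_b <- z_m
        }
        guess <- (z_a + z_b) / 2
        pol <- polish_fold(from_z(guess), 10^guess[7], env0, free, params)
        folds[[length(folds) + 1]] <-
          if (!is.null(pol)) pol else list(state = from_z(guess),
                                           p = 10^guess[7])
      }
      z <- z_new; tang <- t_new
      pts[[length(pts) + 1]] <- z
      tangs[[length(tangs) + 1]] <- tang
      ds <- min(ds_max, if (sol$iters <= 3) ds * 1.3 else ds)
      if (z[7] > th_hi + 1e-9 || z[7] < th_lo - 1e-9) break
    }
    list(pts = pts, folds = folds, diagnostic = diagnostic)
  }

  up <- run_direction(+1)
  down <- run_direction(-1)
  pts <- c(rev(if (is.null(down)) list() else down$pts),
           if (is.null(up)) list() else up$pts[-1])
  if (length(pts) == 0) stop("continuation failed at the starting point")
  zmat <- do.call(rbind, pts)
  folds <- c(if (!is.null(down)) down$folds, if (!is.null(up)) up$folds)
  fold_p <- vapply(folds, function(f) f$p, numeric(1))
  keep <- fold_p >= range[1] * (1 - 1e-6) & fold_p <= range[2] * (1 + 1e-6)
  # deduplicate folds found from both directions
  fold_p <- fold_p[keep]; folds <- folds[keep]
  if (length(fold_p) > 1) {
    ord <- order(fold_p)
    fold_p <- fold_p[ord]; folds <- folds[ord]
    uniq <- c(TRUE, diff(log10(fold_p)) > 1e-3)
    fold_p <- fold_p[uniq]; folds <- folds[uniq]
  }
  states_nat <- sweep(zmat[, 1:6, drop = FALSE], 2, yscale, `*`)
  states_nat[states_nat < 0] <- 0
  stab <- vapply(seq_len(nrow(zmat)), function(k) {
    classify_equilibrium(states_nat[k, ],
                         set_free(env0, free, 10^zmat[k, 7]),
                         params)$stability
  }, character(1))
  diag_msg <- c(if (!is.null(up)) up$diagnostic,
                if (!is.null(down)) down$diagnostic)
  structure(list(free = free,
                 param = 10^zmat[, 7],
                 states = states_nat,
                 stability = stab,
                 fold_points = fold_p,
                 fold_states = lapply(folds, function(f) f$state),
                 complete = length(diag_msg) == 0,
                 diagnostic = if (length(diag_msg)) diag_msg else NULL,
                 env0 = env0, range = range),
            class = "morpho_branch")
}

#' @export
print.morpho_branch <- function(x, ...) {
  cat(sprintf("<morpho_branch> %s in [%g, %g]: %d points, %d fold(s)%s\n",
              x$free, x$range[1], x$range[2], length(x$param),
              length(x$fold_points),
              if (x$complete) "" else " [partial]"))
  if (length(x$fold_points))
    cat("  folds at:", paste(signif(x$fold_points, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Build a log-spaced signal grid specification
#'
#' @param c6_range,c12_range Length-2 positive ranges (nM).
#' @param n Points per axis (>= 8).
#' @return List with log-spaced `c6` and `c12` vectors.
#' @export
log_grid <- function(c6_range = c(1, 1000), c12_range = c(1, 10000), n = 12) {
  if (n < 8) stop("need >= 8 points per axis")
  list(c6 = 10^seq(log10(c6_range[1]), log10(c6_range[2]), length.out = n),
       c12 = 10^seq(log10(c12_range[1]), log10(c12_range[2]), length.out = n))
}

# Bistable c6-window on one c12 row from saddle-node continuation: the
# window's lower edge is the fold where the CFP-high branch is born
# (continued down from the high-c6 end) and its upper edge the fold where
# the YFP-high branch dies (continued up from the low-c6 end); a missing
# fold clips the window at the grid range.
row_window_continuation <- function(c12, params, range_c6, iptg, atc, seed) {
  env_hi <- signal_env(c6 = range_c6[2], c12 = c12, iptg = iptg, atc = atc)
  env_lo <- signal_env(c6 = range_c6[1], c12 = c12, iptg = iptg, atc = atc)
  eq_hi <- find_equilibria(env_hi, params, seed = seed)
  eq_lo <- find_equilibria(env_lo, params, seed = seed)
  stable_of <- function(eqs, which_max) {
    st <- Filter(function(e) e$stability == "stable", eqs)
    if (length(st) == 0) return(NULL)
    sc <- vapply(st, function(e) e$state[[which_max]], numeric(1))
    st[[which.max(sc)]]$state
  }
  cfp_state <- stable_of(eq_hi, "cfp")   # CFP-high branch anchor at c6 max
  yfp_state <- stable_of(eq_lo, "yfp")   # branch anchor at c6 min
  folds_from <- function(env, state) {
    if (is.null(state)) return(numeric(0))
    br <- continue_branch(env, free = "c6", range = range_c6,
                          params = params, start_state = state)
    br$fold_points
  }
  f_lo <- folds_from(env_hi, cfp_state)
  f_hi <- folds_from(env_lo, yfp_state)
  lo <- if (length(f_lo)) min(f_lo) else NA_real_
  hi <- if (length(f_hi)) max(f_hi) else NA_real_
  n_lo <- sum(vapply(eq_lo, function(e) e$stability == "stable", logical(1)))
  n_hi <- sum(vapply(eq_hi, function(e) e$stability == "stable", logical(1)))
  if (is.na(lo) && is.na(hi)) {
    # no fold on either branch: the row is uniformly mono- or bistable
    if (n_lo >= 2 && n_hi >= 2) return(range_c6)
    return(c(NA_real_, NA_real_))
  }
  if (is.na(lo)) lo <- if (n_lo >= 2) range_c6[1] else NA_real_
  if (is.na(hi)) hi <- if (n_hi >= 2) range_c6[2] else NA_real_
  if (is.na(lo) || is.na(hi) || hi <= lo) return(c(NA_real_, NA_real_))
  c(lo, hi)
}

#' Map the bistable region in (C6, C12) space
#'
#' With `method = "counting"` (the brute-force oracle), counts stable
#' equilibria on a log-spaced signal grid by multi-start equilibrium
#' location. With `method = "continuation"`, locates the saddle-node folds
#' bracketing the bistable c6-window on each c12 row by pseudo-arclength
#' continuation and marks the cells between them. Both extract the
#' polyline boundary of the two-or-more-stable-states region by contouring
#' in log-concentration space.
#'
#' @param grid_spec Output of [log_grid()] (or any list with `c6`, `c12`
#'   vectors).
#' @param params A `morpho_params` object.
#' @param method `"counting"` or `"continuation"`.
#' @param iptg,atc Inducer context applied at every grid point.
#' @param seed Seed forwarded to [find_equilibria()].
#' @return A `morpho_bistability_map`: list with `c6`, `c12`, integer matrix
#'   `counts` (rows = c6, cols = c12), `bistable` logical matrix, and
#'   `boundary` (list of data.frames with `c6`, `c12` polyline vertices).
#' @examples
#' \donttest{
#' bm <- map_bistable_region(log_grid(n = 8), default_params())
#' sum(bm$bistable)
#' }
#' @export
map_bistable_region <- function(grid_spec, params,
                                method = c("counting", "continuation"),
                                iptg = 0, atc = 0, seed = 1L) {
  method <- match.arg(method)
  c6g <- grid_spec$c6; c12g <- grid_spec$c12
  if (length(c6g) < 8 || length(c12g) < 8)
    stop("grids must have >= 8 points per axis")
  counts <- matrix(0L, length(c6g), length(c12g))
  if (method == "counting") {
    for (i in seq_along(c6g)) for (j in seq_along(c12g)) {
      counts[i, j] <- count_stable(
        signal_env(c6 = c6g[i], c12 = c12g[j], iptg = iptg, atc = atc),
        params, seed = seed)
    }
  } else {
    rng <- range(c6g)
    for (j in seq_along(c12g)) {
      w <- row_window_continuation(c12g[j], params, rng, iptg, atc, seed)
      inside <- !is.na(w[1]) & c6g > w[1] & c6g < w[2]
      counts[, j] <- ifelse(inside, 2L, 1L)
    }
  }
  bist <- counts >= 2L
  boundary <- list()
  if (any(bist) && !all(bist)) {
    cl <- contourLines(log10(c6g), log10(c12g), ifelse(bist, 1, 0),
                       levels = 0.5)
    boundary <- lapply(cl, function(s)
      data.frame(c6 = 10^s$x, c12 = 10^s$y))
  }
  structure(list(c6 = c6g, c12 = c12g, counts = counts, bistable = bist,
                 boundary = boundary, iptg = iptg, atc = atc),
            class = "morpho_bistability_map")
}

#' @export
print.morpho_bistability_map <- function(x, ...) {
  cat(sprintf("<morpho_bistability_map> %dx%d grid, %d bistable cell(s), IPTG %g uM\n",
              length(x$c6), length(x$c12), sum(x$bistable), x$iptg))
  invisible(x)
}

#' Export a bistability map or hysteresis grid as CSV
#'
#' Long format `(c6, c12, value)`; a JSON sidecar with the grid metadata is
#' written next to it.
#'
#' @param x A `morpho_bistability_map` or `morpho_hysteresis_grid`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(x, path) {
  value <- if (inherits(x, "morpho_bistability_map")) x$counts else x$readout
  df <- expand.grid(c6 = x$c6, c12 = x$c12)
  df$value <- as.vector(value)
  write.csv(df, path, row.names = FALSE)
  meta <- list(class = class(x), n_c6 = length(x$c6), n_c12 = length(x$c12),
               iptg = x$iptg, atc = x$atc,
               conditioning = x$conditioning)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Simulate the conditioning / exposure hysteresis protocol
#'
#' Emulates the flow-cytometry hysteresis experiment: cells start from the
#' naive (zero) state, are conditioned in 500 nM of one signal for 2 h,
#' washed, then exposed to each (C6, C12) grid combination for 5 h; the
#' readout per grid point is the normalised fluorescence difference
#' `(cfp - yfp) / (cfp + yfp + eps)` at protocol end.
#'
#' @param conditioning `"C6"` or `"C12"`.
#' @param grid_spec Output of [log_grid()].
#' @param params A `morpho_params` object.
#' @param t_condition Conditioning duration (h).
#' @param conditioning_conc Conditioning concentration (nM).
#' @param t_exposure Exposure duration (h); the experimental protocol uses
#'   5 h, larger values probe the asymptotic (equilibrium) readout.
#' @param iptg,atc Inducer context during both phases.
#' @param eps Normalisation floor (a.u.).
#' @return A `morpho_hysteresis_grid`: list with `c6`, `c12`, `readout`
#'   matrix in `[-1, 1]`, and the protocol settings.
#' @export
hysteresis_protocol <- function(conditioning = c("C6", "C12"), grid_spec,
                                params, t_condition = 2,
                                conditioning_conc = 500, t_exposure = 5,
                                iptg = 0, atc = 0, eps = 1e-9) {
  conditioning <- match.arg(conditioning)
  validate_params(params)
  c6g <- grid_spec$c6; c12g <- grid_spec$c12
  cond_env <- if (conditioning == "C6")
    signal_env(c6 = conditioning_conc, iptg = iptg, atc = atc)
  else signal_env(c12 = conditioning_conc, iptg = iptg, atc = atc)
  tr <- integrate_circuit(rep(0, 6), cond_env, params, t_end = t_condition,
                          dt_out = t_condition)
  y_cond <- tr$states[nrow(tr$states), ]
  grid <- expand.grid(c6 = c6g, c12 = c12g)
  envs <- cbind(grid$c6, grid$c12, iptg, atc)
  y0 <- matrix(rep(y_cond, each = nrow(grid)), nrow = nrow(grid))
  pm <- matrix(pack_params(params), nrow = 1)
  term <- .integrate_batch_cpp(y0, envs, pm, variant_code(params), t_exposure)
  readout <- (term[, 5] - term[, 6]) / (term[, 5] + term[, 6] + eps)
  structure(list(c6 = c6g, c12 = c12g,
                 readout = matrix(readout, length(c6g), length(c12g)),
                 conditioning = conditioning, t_condition = t_condition,
                 conditioning_conc = conditioning_conc,
                 t_exposure = t_exposure, iptg = iptg, atc = atc),
            class = "morpho_hysteresis_grid")
}

#' @export
print.morpho_hysteresis_grid <- function(x, ...) {
  cat(sprintf("<morpho_hysteresis_grid> conditioned in %s, %dx%d grid, exposure %g h\n",
              x$conditioning, length(x$c6), length(x$c12), x$t_exposure))
  invisible(x)
}
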