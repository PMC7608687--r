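#' Hill activation and repression functions
#'
#' The elementary regulatory response forms used throughout the model.
#' `hill_act(s, K, n) = s^n / (K^n + s^n)` rises from 0 to 1;
#' `hill_rep(r, K, n) = K^n / (K^n + r^n)` falls from 1 to 0.
#'
#' @param s,r Ligand / repressor concentration (>= 0); vectorised.
#' @param K Half-saturation constant (> 0).
#' @param n Hill coefficient (>= 1).
#' @return Fraction in `[0, 1]`.
#' @examples
#' hill_act(c(0, 10, 1e6), K = 10, n = 2)
#' hill_rep(10, K = 10, n = 2)
#' @export
hill_act <- function(s, K, n) {
  if (any(!is.finite(s)) || any(s < 0)) stop("hill_act: s must be finite and >= 0")
  if (K <= 0 || n < 1) stop("hill_act: require K > 0, n >= 1")
  r <- (s / K)^n
  r / (1 + r)
}

#' @rdname hill_act
#' @export
hill_rep <- function(r, K, n) {
  if (any(!(r >= 0))) stop("hill_rep: r must be finite and >= 0")
  if (K <= 0 || n < 1) stop("hill_rep: require K > 0, n >= 1")
  q <- (r / K)^n
  out <- 1 / (1 + q)
  out[is.infinite(r)] <- 0
  out
}

#' Active repressor remaining in the presence of its inducer
#'
#' IPTG binds LacI and aTc binds TetR, inactivating them. The active pool is
#' `total * K_ind^n / (K_ind^n + inducer^n)`: the full total with no inducer,
#' zero at saturating inducer.
#'
#' @param total Total repressor (a.u., >= 0).
#' @param inducer Inducer concentration (>= 0, may be `Inf`).
#' @param K_ind Half-inactivation constant (> 0).
#' @param n_ind Hill coefficient (>= 1).
#' @return Active repressor concentration (a.u.).
#' @examples
#' effective_repressor(5, 100, K_ind = 100, n_ind = 2) # half derepressed
#' @export
effective_repressor <- function(total, inducer, K_ind, n_ind) {
  if (any(total < 0)) stop("effective_repressor: total must be >= 0")
  total * hill_rep(inducer, K_ind, n_ind)
}

.state_names <- c("luxR", "lasR", "lacI", "tetR", "cfp", "yfp")

as_state <- function(x) {
  if (is.list(x)) x <- unlist(x[.state_names])
  x <- as.numeric(x)
  if (length(x) != 6 || any(!is.finite(x)) || any(x < 0))
    stop("circuit state must be 6 finite non-negative values (",
         paste(.state_names, collapse = ", "), ")")
  names(x) <- .state_names
  x
}

#' Time derivatives of the intracellular circuit state
#'
#' Evaluates the right-hand side of the ODE model at one state. The state
#' vector is `(luxR, lasR, lacI, tetR, cfp, yfp)` in a.u. For the exclusive
#' receiver, TetR (net of aTc) represses LuxR synthesis and LacI (net of
#' IPTG) represses LasR synthesis; the receiver variant expresses both
#' receptors constitutively. Promoter activities are the receptor-scaled
#' Hill responses `A6 = (luxR/luxR_ref) * hill_act(c6, K6, n6)` (plus
#' optional crosstalk from C12) and symmetrically `A12`; each drives its
#' bicistronic pair (CFP with LacI; YFP with TetR) with shared production
#' but species-specific removal.
#'
#' @param state Numeric state vector of length 6 (or named list).
#' @param env A [signal_env()].
#' @param params A `morpho_params` object.
#' @return Named numeric vector of rates (a.u./h).
#' @examples
#' derivatives(rep(0, 6), signal_env(c6 = 500), default_params())
#' @export
derivatives <- function(state, env, params) {
  y <- as_state(state)
  validate_params(params)
  dy <- .circuit_rhs_cpp(y, pack_params(params), variant_code(params),
                         env$c6, env$c12, env$iptg, env$atc)
  names(dy) <- .state_names
  dy
}

# Analytic Jacobian of derivatives() wrt the state; used by the Newton
# equilibrium solver and for stability classification.
circuit_jacobian <- function(state, env, params) {
  y <- as_state(state)
  p <- params
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  g <- c(p$g_luxR, p$g_lasR, p$g_lacI, p$g_tetR, p$g_cfp, p$g_yfp)
  diag(J) <- -g
  h6 <- hill_act(env$c6, p$K6, p$n6)
  h12 <- hill_act(env$c12, p$K12, p$n12)
  dA6_dluxR <- (h6 + p$cross_c12 * h12) / p$luxR_ref
  dA12_dlasR <- (h12 + p$cross_c6 * h6) / p$lasR_ref
  if (p$variant != "receiver") {
    phi_iptg <- hill_rep(env$iptg, p$K_iptg, p$n_iptg)
    phi_atc <- hill_rep(env$atc, p$K_atc, p$n_atc)
    dhr <- function(r, K, n) {
      if (r <= 0) return(if (n == 1) -1 / K else 0)
      q <- (r / K)^n
      -(n / r) * q / (1 + q)^2
    }
    J["luxR", "tetR"] <- p$a_R * dhr(y["tetR"] * phi_atc, p$K_tet, p$n_tet) * phi_atc
    J["lasR", "lacI"] <- p$a_R * dhr(y["lacI"] * phi_iptg, p$K_lac, p$n_lac) * phi_iptg
  }
  J["lacI", "luxR"] <- p$a_F * dA6_dluxR
  J["cfp", "luxR"] <- p$a_F * dA6_dluxR
  J["tetR", "lasR"] <- p$a_F * dA12_dlasR
  J["yfp", "lasR"] <- p$a_F * dA12_dlasR
  J
}

#' Integrate the circuit ODEs
#'
#' Adaptive Runge-Kutta (Dormand-Prince 5(4)) integration under a constant
#' environment, or a piecewise-constant schedule of environments (a list of
#' `list(t_end =, env =)` segments, e.g. a conditioning-then-exposure
#' protocol).
#'
#' @param state0 Initial state (length-6 numeric, default all zero).
#' @param env A [signal_env()], or a list of segments
#'   `list(list(t_end = 2, env = ...), list(t_end = 7, env = ...))` with
#'   strictly increasing `t_end` (hours, absolute).
#' @param params A `morpho_params` object.
#' @param t_end Final time (h); ignored when `env` is a schedule.
#' @param dt_out Output spacing (h).
#' @param rtol,atol Solver tolerances.
#' @return A `morpho_trajectory`: list with `times`, `states` (matrix with
#'   named columns), and `env`.
#' @examples
#' tr <- integrate_circuit(env = signal_env(c6 = 500), params = default_params(),
#'                         t_end = 20)
#' tail(tr$states[, "cfp"], 1)
#' @export
integrate_circuit <- function(state0 = rep(0, 6), env, params, t_end = 24,
                              dt_out = 0.1, rtol = 1e-8, atol = 1e-10) {
  y0 <- as_state(state0)
  validate_params(params)
  pv <- pack_params(params)
  vc <- variant_code(params)
  if (inherits(env, "signal_env")) {
    segments <- list(list(t_end = t_end, env = env))
  } else {
    segments <- env
    ends <- vapply(segments, function(s) s$t_end, numeric(1))
    if (any(diff(c(0, ends)) <= 0))
      stop("schedule t_end values must be strictly increasing from 0")
    t_end <- ends[length(ends)]
  }
  if (t_end <= 0) stop("t_end must be > 0")
  times <- numeric(0); states <- NULL
  t0 <- 0; y <- y0
  for (seg in segments) {
    tt <- unique(c(seq(t0, seg$t_end, by = dt_out), seg$t_end))
    e <- seg$env
    m <- .integrate_cpp(y, tt, pv, vc, e$c6, e$c12, e$iptg, e$atc, rtol, atol)
    keep <- if (length(times) > 0) -1L else seq_along(tt)
    times <- c(times, tt[keep])
    states <- rbind(states, m[keep, , drop = FALSE])
    y <- m[nrow(m), ]
    t0 <- seg$t_end
  }
  colnames(states) <- .state_names
  structure(list(times = times, states = states,
                 env = if (length(segments) == 1) segments[[1]]$env else segments),
            class = "morpho_trajectory")
}

#' @export
print.morpho_trajectory <- function(x, ...) {
  cat(sprintf("<morpho_trajectory> %d time points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  print(round(x$states[nrow(x$states), ], 3))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes columns `t, luxR, lasR, lacI, tetR, cfp, yfp`.
#'
#' @param traj A `morpho_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$times, traj$states, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
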