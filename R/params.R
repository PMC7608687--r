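#' Signal environment seen by one cell or one grid point
#'
#' Bundles the extracellular inputs of the circuit: the two acyl-homoserine
#' lactone signals (C6 = 3O-C6-HSL sensed by LuxR, C12 = 3O-C12-HSL sensed by
#' LasR) and the two chemical inducers that titrate the repressors (IPTG
#' derepresses LacI, aTc derepresses TetR).
#'
#' @param c6 3O-C6-HSL concentration (nM).
#' @param c12 3O-C12-HSL concentration (nM).
#' @param iptg IPTG concentration (uM).
#' @param atc anhydrotetracycline concentration (ng/mL).
#' @return An object of class `signal_env`.
#' @examples
#' signal_env(c6 = 37, c12 = 100)
#' @export
signal_env <- function(c6 = 0, c12 = 0, iptg = 0, atc = 0) {
  vals <- c(c6 = c6, c12 = c12, iptg = iptg, atc = atc)
  if (!all(is.finite(vals))) stop("signal_env: all inputs must be finite")
  if (any(vals < 0)) stop("signal_env: concentrations must be >= 0")
  structure(as.list(vals), class = "signal_env")
}

#' @export
print.signal_env <- function(x, ...) {
  cat(sprintf("<signal_env> C6 = %g nM, C12 = %g nM, IPTG = %g uM, aTc = %g ng/mL\n",
              x$c6, x$c12, x$iptg, x$atc))
  invisible(x)
}

.param_names <- c(
  "a_R", "b_R", "a_F", "b_F",
  "K6", "n6", "K12", "n12",
  "K_lac", "n_lac", "K_tet", "n_tet",
  "K_iptg", "n_iptg", "K_atc", "n_atc",
  "g_luxR", "g_lasR", "g_lacI", "g_tetR", "g_cfp", "g_yfp",
  "luxR_ref", "lasR_ref", "cross_c12", "cross_c6"
)

.variants <- c("receiver", "exclusive_receiver",
               "relay_c6_to_c12", "relay_c12_to_c6")

#' Construct a full circuit parameter set
#'
#' All kinetic, regulatory and calibration parameters of the intracellular
#' model. Synthesis rates are in a.u./h, removal rates in 1/h (degradation
#' plus dilution), half-activation constants for the HSLs in nM, repression
#' constants in a.u. of repressor protein, inducer constants in the inducer's
#' native units (uM IPTG, ng/mL aTc). `luxR_ref`/`lasR_ref` set the receptor
#' level at which the scaled promoter activity reaches the Hill value;
#' defaults are the unrepressed receptor steady states.
#'
#' @param variant One of `"receiver"`, `"exclusive_receiver"`,
#'   `"relay_c6_to_c12"`, `"relay_c12_to_c6"`. Relay variants share the
#'   exclusive-receiver intracellular model; the synthase source term is
#'   applied by the spatial simulator.
#' @param a_R,b_R Maximal and basal synthesis rate of the receptors
#'   LuxR/LasR from their repressible promoters (a.u./h).
#' @param a_F,b_F Maximal and basal synthesis rate of the bicistronic
#'   P_lux (CFP + LacI) and P_las (YFP + TetR) outputs (a.u./h).
#' @param K6,n6 Half-activation constant (nM) and Hill coefficient of the
#'   LuxR-C6 response; `K12`,`n12` likewise for LasR-C12.
#' @param K_lac,n_lac Half-repression constant (a.u.) and Hill coefficient
#'   of LacI acting on the LasR promoter; `K_tet`,`n_tet` for TetR on the
#'   LuxR promoter.
#' @param K_iptg,n_iptg,K_atc,n_atc Inducer binding constants: IPTG
#'   inactivates LacI, aTc inactivates TetR.
#' @param g_luxR,g_lasR,g_lacI,g_tetR,g_cfp,g_yfp First-order removal rates
#'   (1/h). Fluorescent proteins are stable, so their rates are dilution
#'   only; repressors and receptors turn over faster.
#' @param luxR_ref,lasR_ref Receptor reference levels (a.u.); `NULL` means
#'   the unrepressed steady state `(a_R + b_R)/g`.
#' @param cross_c12,cross_c6 Crosstalk gains in `[0, 1]`: weight of C12
#'   activating LuxR and of C6 activating LasR. Default 0 (no crosstalk).
#' @return An object of class `morpho_params` (a named list).
#' @seealso [default_params()] for the calibrated defaults.
#' @export
morpho_params <- function(variant = "exclusive_receiver",
                          a_R = 1, b_R = 0.01,
                          a_F = 100, b_F = 0.1,
                          K6 = 60, n6 = 2, K12 = 100, n12 = 2,
                          K_lac = 2, n_lac = 2, K_tet = 5, n_tet = 2,
                          K_iptg = 10, n_iptg = 2, K_atc = 10, n_atc = 2,
                          g_luxR = 1, g_lasR = 1, g_lacI = 1, g_tetR = 1,
                          g_cfp = 0.1, g_yfp = 0.1,
                          luxR_ref = NULL, lasR_ref = NULL,
                          cross_c12 = 0, cross_c6 = 0) {
  variant <- match.arg(variant, .variants)
  if (is.null(luxR_ref)) luxR_ref <- (a_R + b_R) / g_luxR
  if (is.null(lasR_ref)) lasR_ref <- (a_R + b_R) / g_lasR
  p <- list(variant = variant,
            a_R = a_R, b_R = b_R, a_F = a_F, b_F = b_F,
            K6 = K6, n6 = n6, K12 = K12, n12 = n12,
            K_lac = K_lac, n_lac = n_lac, K_tet = K_tet, n_tet = n_tet,
            K_iptg = K_iptg, n_iptg = n_iptg, K_atc = K_atc, n_atc = n_atc,
            g_luxR = g_luxR, g_lasR = g_lasR, g_lacI = g_lacI,
            g_tetR = g_tetR, g_cfp = g_cfp, g_yfp = g_yfp,
            luxR_ref = luxR_ref, lasR_ref = lasR_ref,
            cross_c12 = cross_c12, cross_c6 = cross_c6)
  class(p) <- "morpho_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of rates and constants, Hill coefficients >= 1, and
#' crosstalk gains in `[0, 1]`. Called by the constructor; exported so
#' deserialised or hand-edited parameter lists can be re-checked.
#'
#' @param p A `morpho_params` object.
#' @return `p`, invisibly, or an error.
#' @export
validate_params <- function(p) {
  if (!inherits(p, "morpho_params")) stop("not a morpho_params object")
  num <- unlist(p[.param_names])
  if (length(num) != length(.param_names) || !all(is.finite(num)))
    stop("parameter set incomplete or non-finite")
  pos <- c("a_R", "b_R", "a_F", "b_F", "K6", "K12", "K_lac", "K_tet",
           "K_iptg", "K_atc", "g_luxR", "g_lasR", "g_lacI", "g_tetR",
           "g_cfp", "g_yfp", "luxR_ref", "lasR_ref")
  if (any(num[pos] <= 0)) stop("rates and constants must be > 0: ",
                               paste(pos[num[pos] <= 0], collapse = ", "))
  hills <- c("n6", "n12", "n_lac", "n_tet", "n_iptg", "n_atc")
  if (any(num[hills] < 1)) stop("Hill coefficients must be >= 1")
  xt <- num[c("cross_c12", "cross_c6")]
  if (any(xt < 0 | xt > 1)) stop("crosstalk gains must lie in [0, 1]")
  if (!p$variant %in% .variants) stop("unknown circuit variant: ", p$variant)
  invisible(p)
}

#' Default calibrated parameter set
#'
#' The package-default Exclusive Receiver parameters. Because the fitted
#' values behind the original circuit are not published in machine-readable
#' form, these defaults come from a documented calibration (see
#' `scripts/calibrate.R` in the source tree and the methods vignette) chosen
#' so that: the circuit is bistable at (37 nM C6, 100 nM C12) without
#' inducer; at 10 uM IPTG the bistable region contains (200 nM C6, 2000 nM
#' C12) and excludes (20 nM C6, 2000 nM C12), where the YFP state is
#' monostable; and (500, 0) / (0, 500) nM are monostable CFP / YFP.
#'
#' All parameters are shared between the two culture phases except the
#' fluorescent-protein removal rates, which are pure dilution (the proteins
#' are stable): in exponentially growing liquid culture dilution equals the
#' growth rate (0.7/h, matching [growth_model()]), while on a slowly
#' growing solid lawn it is 0.1/h, which is what makes perdurance of
#' switched-off CFP visible in kymographs.
#'
#' @param variant Circuit variant for the returned set (parameters are
#'   shared across variants).
#' @param phase `"solid"` (lawn on agar; default) or `"liquid"`
#'   (exponential-phase culture, as in plate and flow assays).
#' @return A `morpho_params` object.
#' @examples
#' p <- default_params()
#' p$K6
#' @export
default_params <- function(variant = "exclusive_receiver",
                           phase = c("solid", "liquid")) {
  phase <- match.arg(phase)
  g_fp <- if (phase == "solid") 0.1 else 0.7
  morpho_params(variant = variant, g_cfp = g_fp, g_yfp = g_fp)
}

#' @export
print.morpho_params <- function(x, ...) {
  cat(sprintf("<morpho_params> variant = %s\n", x$variant))
  num <- unlist(x[.param_names])
  print(round(num, 4))
  invisible(x)
}

# Pack parameters into the fixed-order numeric vector used by the C++ core.
pack_params <- function(p) {
  validate_params(p)
  as.numeric(unlist(p[.param_names]))
}

variant_code <- function(p) {
  # receiver -> 0; all mutually-inhibiting variants -> 1
  if (p$variant == "receiver") 0L else 1L
}

#' Write / read a parameter set as JSON
#'
#' Round-trippable JSON serialisation with validation on read.
#'
#' @param p A `morpho_params` object.
#' @param path File path.
#' @return `read_params()` returns a validated `morpho_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(c("variant", .param_names), names(raw))
  if (length(miss) > 0)
    stop("parameter file missing fields: ", paste(miss, collapse = ", "))
  p <- structure(raw[c("variant", .param_names)], class = "morpho_params")
  validate_params(p)
  p
}
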