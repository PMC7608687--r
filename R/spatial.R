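# 1D reaction-diffusion simulation of a lawn of receiver cells under
# transient HSL gradients, including relay (cell-produced) gradients.

#' Configure the 1D reaction-diffusion simulation
#'
#' Cell-centred grid on a domain of length `L` with no-flux boundaries.
#' Signals diffuse; immobile cells at every grid point run the intracellular
#' circuit model with the local signal concentrations. The splitting
#' interval between diffusion and reaction updates is capped at 0.05 h (and
#' never exceeds a tenth of the grid diffusion time), following the
#' separation between the fast solver scales and the ~1/h circuit
#' timescale.
#'
#' @param L Domain length (mm).
#' @param n_x Number of grid cells.
#' @param D_c6,D_c12 Diffusivities (mm^2/h). Default 0.36 mm^2/h
#'   (~1e-6 cm^2/s, typical for small molecules in agar).
#' @param t_end Simulated time (h).
#' @param dt_out Output cadence (h).
#' @param dt_split Splitting interval (h); `NULL` picks the default cap.
#' @param hsl_decay First-order HSL degradation rate (1/h); default 0 so
#'   signal mass is conserved and gradients homogenise to their spatial
#'   averages.
#' @param k_relay Relay synthase production gain (nM per a.u. promoter
#'   activity per h); only used by [simulate_relay()].
#' @param iptg,atc Inducer context of the agar (uM / ng/mL). Solid-culture
#'   assays use 10 uM IPTG by default.
#' @return A `spatial_config` list, including the cell-centre coordinates
#'   `x`.
#' @export
spatial_config <- function(L = 6, n_x = 120, D_c6 = 0.36, D_c12 = 0.36,
                           t_end = 24, dt_out = 0.25, dt_split = NULL,
                           hsl_decay = 0, k_relay = 60, iptg = 10, atc = 0) {
  if (L <= 0 || n_x < 8 || D_c6 <= 0 || D_c12 <= 0 || t_end <= 0)
    stop("invalid spatial configuration")
  dx <- L / n_x
  if (is.null(dt_split))
    dt_split <- min(0.05, 0.1 * dx^2 / max(D_c6, D_c12))
  structure(list(L = L, n_x = as.integer(n_x), dx = dx,
                 x = (seq_len(n_x) - 0.5) * dx,
                 D_c6 = D_c6, D_c12 = D_c12, t_end = t_end,
                 dt_out = dt_out, dt_split = dt_split,
                 hsl_decay = hsl_decay, k_relay = k_relay,
                 iptg = iptg, atc = atc),
            class = "spatial_config")
}

# Fractional coverage of each grid cell by the interval [a, b] (mm).
cell_coverage <- function(a, b, config) {
  lo <- (seq_len(config$n_x) - 1) * config$dx
  hi <- lo + config$dx
  pmax(0, pmin(hi, b) - pmax(lo, a)) / config$dx
}

#' Initial condition: antiparallel sources at the two domain ends
#'
#' Mirrors the solid-culture assay: wells cut at both ends of the domain,
#' each a fraction (default 25%) of the domain, loaded with HSL at 4x the
#' target spatial-average concentration (so that diffusion to homogeneity
#' yields exactly the requested averages). C12 occupies the left end, C6
#' the right end. Partial boundary cells are weighted so the domain mean of
#' each field equals its requested average exactly.
#'
#' @param avg_c6,avg_c12 Target spatial averages (nM).
#' @param source_fraction Fraction of the domain occupied by each source,
#'   in `(0, 0.5]`.
#' @param config A [spatial_config()].
#' @return List with numeric fields `c6`, `c12` of length `n_x`.
#' @examples
#' cfg <- spatial_config(n_x = 50)
#' ic <- make_antiparallel_ic(200, 2000, config = cfg)
#' mean(ic$c6) # exactly 200
#' @export
make_antiparallel_ic <- function(avg_c6, avg_c12, source_fraction = 0.25,
                                 config) {
  if (avg_c6 < 0 || avg_c12 < 0) stop("averages must be >= 0")
  if (source_fraction <= 0 || source_fraction > 0.5)
    stop("source_fraction must lie in (0, 0.5]; larger sources overlap")
  L <- config$L
  w_left <- cell_coverage(0, source_fraction * L, config)
  w_right <- cell_coverage((1 - source_fraction) * L, L, config)
  list(c6 = avg_c6 / source_fraction * w_right,
       c12 = avg_c12 / source_fraction * w_left)
}

#' Initial condition: a single central source
#'
#' Emulates the relay assay: a central well holding the primary HSL at
#' concentration `conc` over a fraction of the domain; the spatial average
#' is `conc * source_fraction`.
#'
#' @param conc Source concentration (nM), e.g. 40000 nM (40 uM).
#' @param source_fraction Fraction of the domain covered by the source.
#' @param config A [spatial_config()].
#' @return Numeric field of length `n_x`.
#' @export
make_central_source_ic <- function(conc, source_fraction = 0.1, config) {
  if (conc < 0) stop("conc must be >= 0")
  if (source_fraction <= 0 || source_fraction > 0.5)
    stop("source_fraction must lie in (0, 0.5]")
  L <- config$L
  a <- (0.5 - source_fraction / 2) * L
  conc * cell_coverage(a, a + source_fraction * L, config)
}

run_rd <- function(config, params, c6_0, c12_0, relay_code) {
  validate_params(params)
  if (length(c6_0) != config$n_x || length(c12_0) != config$n_x)
    stop("initial fields must have length n_x")
  if (any(c6_0 < 0) || any(c12_0 < 0)) stop("initial fields must be >= 0")
  t_store <- unique(c(seq(0, config$t_end, by = config$dt_out), config$t_end))
  raw <- .simulate_rd_cpp(c6_0, c12_0, config$dx, config$D_c6, config$D_c12,
                          if (relay_code == 0L) 0 else config$k_relay,
                          relay_code, config$hsl_decay, config$iptg,
                          config$atc, pack_params(params),
                          variant_code(params), config$dt_split, t_store)
  structure(c(list(x = config$x, times = t_store, config = config,
                   relay = relay_code), raw),
            class = "spatial_fields")
}

#' Simulate diffusion of transient gradients over a lawn of receiver cells
#'
#' Operator-split update: Crank-Nicolson diffusion of C6 and C12 with
#' no-flux boundaries, then an intracellular reaction step at every grid
#' point with the local signal concentrations held fixed. Cells neither
#' move nor secrete. With zero degradation the total mass of each signal is
#' conserved and the fields homogenise to their spatial averages.
#'
#' @param config A [spatial_config()].
#' @param params A `morpho_params` object.
#' @param ic List with initial `c6` and `c12` fields (e.g. from
#'   [make_antiparallel_ic()]).
#' @return A `spatial_fields` object: `x`, `times`, and matrices
#'   (`times x x`) `c6`, `c12`, `luxR`, `lasR`, `lacI`, `tetR`, `cfp`,
#'   `yfp`.
#' @export
simulate_rd <- function(config, params, ic) {
  run_rd(config, params, ic$c6, ic$c12, 0L)
}

#' Simulate an exclusive relay lawn responding to a single central gradient
#'
#' As [simulate_rd()], but cells carry a relay synthase co-expressed with
#' one signalling pathway: with primary `"C6"` the C6 pathway co-expresses
#' LasI, sourcing C12 into the field at rate `k_relay` times the local
#' P_lux promoter activity; primary `"C12"` reverses the roles (LuxI with
#' the C12 pathway produces C6). The primary signal's total mass stays
#' constant (zero degradation default); the secondary's is non-decreasing.
#'
#' @param config A [spatial_config()]; `k_relay` sets the production gain.
#' @param params A `morpho_params` object.
#' @param primary `"C6"` or `"C12"`: which signal forms the primary central
#'   gradient.
#' @param source_conc Central source concentration (nM); default 40000
#'   (40 uM).
#' @param source_fraction Fraction of the domain covered by the central
#'   well.
#' @return A `spatial_fields` object.
#' @export
simulate_relay <- function(config, params, primary = c("C6", "C12"),
                           source_conc = 40000, source_fraction = 0.1) {
  primary <- match.arg(primary)
  src <- make_central_source_ic(source_conc, source_fraction, config)
  zero <- numeric(config$n_x)
  if (primary == "C6") run_rd(config, params, src, zero, 1L)
  else run_rd(config, params, zero, src, 2L)
}

#' @export
print.spatial_fields <- function(x, ...) {
  cat(sprintf("<spatial_fields> %d x-points, %d times over [0, %g] h%s\n",
              length(x$x), length(x$times), max(x$times),
              if (x$relay == 0) "" else sprintf(", relay mode %d", x$relay)))
  invisible(x)
}

#' Per-position signal-space trajectories and the spatial-average path
#'
#' Extracts, for selected positions, the time-indexed (C6, C12) path a cell
#' at that position experiences, plus the domain-mean path. Without a relay
#' the mean path is a single point (mass conservation); with a relay its
#' secondary component grows over time.
#'
#' @param fields A `spatial_fields` object.
#' @param positions Positions (mm) to extract; default 5 equally spaced.
#' @return List with `mean` (data.frame `t`, `c6`, `c12`) and `paths` (list
#'   of data.frames per position, named by position).
#' @export
phase_trajectories <- function(fields, positions = NULL) {
  if (is.null(positions))
    positions <- seq(min(fields$x), max(fields$x), length.out = 5)
  idx <- vapply(positions, function(p) which.min(abs(fields$x - p)),
                integer(1))
  paths <- lapply(idx, function(i)
    data.frame(t = fields$times, c6 = fields$c6[, i], c12 = fields$c12[, i]))
  names(paths) <- signif(fields$x[idx], 4)
  list(mean = data.frame(t = fields$times,
                         c6 = rowMeans(fields$c6),
                         c12 = rowMeans(fields$c12)),
       paths = paths)
}

#' Export spatial fields as long-format CSV
#'
#' Columns `t, x, c6, c12, luxR, lasR, lacI, tetR, cfp, yfp`; a JSON
#' sidecar with the configuration is written next to it.
#'
#' @param fields A `spatial_fields` object.
#' @param path CSV output path.
#' @param thin Keep every `thin`-th stored time (to bound file size).
#' @return `path`, invisibly.
#' @export
write_spatial_csv <- function(fields, path, thin = 1L) {
  tsel <- seq(1, length(fields$times), by = thin)
  comps <- c("c6", "c12", "luxR", "lasR", "lacI", "tetR", "cfp", "yfp")
  df <- expand.grid(x = fields$x, t = fields$times[tsel])[, c("t", "x")]
  for (cc in comps) df[[cc]] <- as.vector(t(fields[[cc]][tsel, , drop = FALSE]))
  write.csv(df, path, row.names = FALSE)
  cfg <- fields$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "x")], paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
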