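# Kymograph normalisation, equal-fluorescence boundary detection, and
# static / moving / absent classification.

#' Build a normalized kymograph from spatial fields or raw intensity arrays
#'
#' Each fluorescence channel is divided by its own global (space x time)
#' maximum, so values lie in `[0, 1]` and a perduring stable protein remains
#' comparable across the whole timelapse. An all-zero channel stays zero.
#' Normalisation is idempotent.
#'
#' @param x A `spatial_fields` object, or a list with `x`, `times`, and
#'   `cfp` / `yfp` intensity matrices (`times` in rows).
#' @return A `morpho_kymograph`: list with `x`, `times`, `cfp`, `yfp` (both
#'   normalized to `[0, 1]`).
#' @export
normalize_channels <- function(x) {
  cfp <- as.matrix(x$cfp); yfp <- as.matrix(x$yfp)
  if (any(cfp < 0) || any(yfp < 0))
    stop("negative intensities in input channels")
  norm1 <- function(m) { mx <- max(m); if (mx > 0) m / mx else m }
  structure(list(x = x$x, times = x$times,
                 cfp = norm1(cfp), yfp = norm1(yfp)),
            class = "morpho_kymograph")
}

#' Read a kymograph from a long-format CSV table
#'
#' Accepts any table with columns `t`, `x`, `cfp`, `yfp` (such as the
#' output of [write_spatial_csv()]) and reshapes it to matrices.
#'
#' @param path CSV file path.
#' @return A list with `x`, `times`, `cfp`, `yfp` suitable for
#'   [normalize_channels()].
#' @export
read_kymograph_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t", "x", "cfp", "yfp")
  if (!all(need %in% names(df)))
    stop("kymograph CSV must have columns t, x, cfp, yfp")
  xs <- sort(unique(df$x)); ts <- sort(unique(df$t))
  shape <- function(v) {
    m <- matrix(NA_real_, length(ts), length(xs))
    m[cbind(match(df$t, ts), match(df$x, xs))] <- v
    if (any(is.na(m))) stop("kymograph table is not a complete t-x grid")
    m
  }
  list(x = xs, times = ts, cfp = shape(df$cfp), yfp = shape(df$yfp))
}

# Crossing of (cfp - yfp) at one time; returns all valid interpolated
# crossings with the detectability requirement that both channels reach the
# threshold within one grid cell of the crossing.
crossings_at <- function(cfp, yfp, xs, thr) {
  d <- cfp - yfp
  n <- length(xs)
  idx <- which(d[-n] * d[-1] < 0 | (d[-n] == 0 & d[-1] != 0))
  if (any(d == 0)) idx <- sort(unique(c(idx, which(d == 0 & seq_len(n) < n))))
  out <- numeric(0)
  for (i in idx) {
    det_c <- max(cfp[i], cfp[i + 1]) >= thr
    det_y <- max(yfp[i], yfp[i + 1]) >= thr
    if (!(det_c && det_y)) next
    if (d[i] == d[i + 1]) frac <- 0.5
    else frac <- d[i] / (d[i] - d[i + 1])
    out <- c(out, xs[i] + frac * (xs[i + 1] - xs[i]))
  }
  out
}

#' Trace the equal-normalized-fluorescence boundary over time
#'
#' At each stored time, the boundary `beta(t)` is the position where the
#' normalized CFP and YFP profiles cross, linearly interpolated between
#' grid points, and counted only where both channels are detectable
#' (>= `detection_threshold` within one grid cell of the crossing). With
#' multiple crossings the one nearest the previous boundary is kept
#' (nearest the domain centre at the first valid time). `t_det` is the
#' first time a valid crossing exists; the displacement is
#' `delta_beta = |beta(t_last) - beta(t_det)|` where `t_last` is the last
#' time with a valid boundary.
#'
#' @param kymo A `morpho_kymograph` (see [normalize_channels()]); raw
#'   fields are normalized automatically.
#' @param detection_threshold Detectability threshold in `(0, 1)`.
#' @return A `morpho_boundary_trace`: list with `times`, `beta` (NA where
#'   undefined), `t_det`, `t_last`, `delta_beta`, `L`, and the final
#'   normalized profiles.
#' @export
locate_boundary <- function(kymo, detection_threshold = 0.1) {
  if (!inherits(kymo, "morpho_kymograph")) kymo <- normalize_channels(kymo)
  thr <- detection_threshold
  if (thr <= 0 || thr >= 1) stop("detection_threshold must be in (0, 1)")
  xs <- kymo$x
  nt <- length(kymo$times)
  L <- max(xs) + xs[1]  # cell-centred grid: domain spans [0, max(x) + dx/2]
  beta <- rep(NA_real_, nt)
  prev <- NA_real_
  for (k in seq_len(nt)) {
    cr <- crossings_at(kymo$cfp[k, ], kymo$yfp[k, ], xs, thr)
    if (length(cr) == 0) next
    ref <- if (is.na(prev)) L / 2 else prev
    beta[k] <- cr[which.min(abs(cr - ref))]
    prev <- beta[k]
  }
  valid <- which(!is.na(beta))
  t_det <- if (length(valid)) kymo$times[valid[1]] else NA_real_
  t_last <- if (length(valid)) kymo$times[valid[length(valid)]] else NA_real_
  delta <- if (length(valid)) abs(beta[valid[length(valid)]] - beta[valid[1]])
           else NA_real_
  structure(list(times = kymo$times, beta = beta, t_det = t_det,
                 t_last = t_last, delta_beta = delta, L = L,
                 final_cfp = kymo$cfp[nt, ], final_yfp = kymo$yfp[nt, ],
                 detection_threshold = thr),
            class = "morpho_boundary_trace")
}

#' @export
print.morpho_boundary_trace <- function(x, ...) {
  if (is.na(x$t_det)) cat("<morpho_boundary_trace> no valid boundary\n")
  else cat(sprintf(
    "<morpho_boundary_trace> detected at t = %g h, last valid t = %g h, delta_beta = %.3g mm (%.1f%% of L)\n",
    x$t_det, x$t_last, x$delta_beta, 100 * x$delta_beta / x$L))
  invisible(x)
}

#' Classify a boundary trace as static, moving, or absent
#'
#' Labels: `"N"` when no valid boundary exists at the final time (dominant
#' channel decided by the larger final spatial-mean normalized intensity,
#' `"neither"` when their difference is < 0.05); `"S"` (static) when the
#' displacement between first detectability and the end is less than
#' `stable_fraction` of the domain size; `"M"` (moving) otherwise. For S/M
#' the dominant channel is the one occupying the larger terminal domain.
#'
#' @param trace A `morpho_boundary_trace` from [locate_boundary()].
#' @param L Domain size (mm); defaults to the trace's own.
#' @param stable_fraction Displacement threshold as a fraction of `L`
#'   (default 0.10).
#' @return A `morpho_boundary_class`: list with `label` in
#'   `{"S", "M", "N"}`, `dominant` in `{"CFP", "YFP", "neither"}`, and
#'   `delta_beta_frac`.
#' @export
classify_boundary <- function(trace, L = trace$L, stable_fraction = 0.10) {
  nt <- length(trace$times)
  mean_c <- mean(trace$final_cfp)
  mean_y <- mean(trace$final_yfp)
  at_end <- !is.na(trace$beta[nt])
  if (!at_end) {
    dominant <- if (abs(mean_c - mean_y) < 0.05) "neither"
                else if (mean_c > mean_y) "CFP" else "YFP"
    label <- "N"
    dfrac <- if (is.na(trace$delta_beta)) NA_real_ else trace$delta_beta / L
  } else {
    dfrac <- trace$delta_beta / L
    label <- if (dfrac < stable_fraction) "S" else "M"
    n_cfp <- sum(trace$final_cfp > trace$final_yfp)
    dominant <- if (n_cfp > length(trace$final_cfp) / 2) "CFP" else "YFP"
  }
  structure(list(label = label, dominant = dominant,
                 delta_beta_frac = dfrac, stable_fraction = stable_fraction),
            class = "morpho_boundary_class")
}

#' @export
print.morpho_boundary_class <- function(x, ...) {
  cat(sprintf("<boundary> label = %s, dominant = %s, delta_beta = %s of domain\n",
              x$label, x$dominant,
              if (is.na(x$delta_beta_frac)) "NA"
              else sprintf("%.1f%%", 100 * x$delta_beta_frac)))
  invisible(x)
}

#' Write a boundary trace and verdict
#'
#' Writes the per-time boundary positions as CSV and a one-line JSON
#' verdict `{label, dominant, delta_beta_frac}`.
#'
#' @param trace A `morpho_boundary_trace`.
#' @param verdict A `morpho_boundary_class`.
#' @param path CSV output path (the JSON verdict gets `.json` appended).
#' @return `path`, invisibly.
#' @export
write_boundary <- function(trace, verdict, path) {
  write.csv(data.frame(t = trace$times, beta = trace$beta), path,
            row.names = FALSE)
  jsonlite::write_json(list(label = verdict$label,
                            dominant = verdict$dominant,
                            delta_beta_frac = verdict$delta_beta_frac),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
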