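#' Experiment parameters
#'
#' Physical parameters of a voltammetric experiment, required for the
#' uncompensated-resistance / double-layer corrections and for conversion to
#' dimensionless form.
#'
#' @param area Electrode area A (cm^2).
#' @param conc Bulk concentration C (mol cm^-3).
#' @param diff_coef Diffusion coefficient D (cm^2 s^-1).
#' @param scan_rate Scan rate v (V s^-1).
#' @param temperature Thermodynamic temperature T (K).
#' @param n_electrons Number of transferred electrons n (used by the
#'   synthetic generator and validation, not by the conversion itself).
#' @param ru Uncompensated resistance Ru (Ohm); 0 switches the IR correction
#'   off.
#' @param cdl Double-layer capacitance C_DL (F); 0 switches the capacitive
#'   correction off.
#' @return A list of class `experiment_params`.
#' @export
#' @examples
#' experiment_params(area = 0.1, conc = 1e-6, diff_coef = 1e-5, scan_rate = 0.1)
experiment_params <- function(area, conc, diff_coef, scan_rate,
                              temperature = 298.15, n_electrons = 1L,
                              ru = 0, cdl = 0) {
  vals <- c(area = area, conc = conc, diff_coef = diff_coef,
            scan_rate = scan_rate, temperature = temperature,
            n_electrons = n_electrons)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    vk_abort("invalid_params",
             "area, conc, diff_coef, scan_rate, temperature and n_electrons must all be > 0.")
  }
  if (ru < 0 || cdl < 0) {
    vk_abort("invalid_params", "`ru` and `cdl` must be >= 0 (0 = correction off).")
  }
  structure(list(area = area, conc = conc, diff_coef = diff_coef,
                 scan_rate = scan_rate, temperature = temperature,
                 n_electrons = as.integer(n_electrons), ru = ru, cdl = cdl),
            class = "experiment_params")
}

#' @export
print.experiment_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_params> A = %g cm^2, C = %g mol/cm^3, D = %g cm^2/s,\n",
    "  v = %g V/s, T = %g K, n = %d, Ru = %g Ohm, C_DL = %g F\n"),
    x$area, x$conc, x$diff_coef, x$scan_rate, x$temperature,
    x$n_electrons, x$ru, x$cdl))
  invisible(x)
}

#' Persist and restore experiment parameters
#'
#' Parameters are stored as YAML so the last-used values are available in
#' later sessions. The default location is the user configuration directory;
#' supply `path` to store elsewhere.
#'
#' @param params An [experiment_params()] object.
#' @param path YAML file path; defaults to [default_params_path()].
#' @return `save_params()` returns the path invisibly; `load_params()`
#'   returns an `experiment_params`.
#' @export
save_params <- function(params, path = default_params_path()) {
  stopifnot(inherits(params, "experiment_params"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path = default_params_path()) {
  if (!file.exists(path)) {
    vk_abort("no_saved_params", sprintf("No saved parameters at '%s'.", path))
  }
  p <- yaml::read_yaml(path)
  experiment_params(area = p$area, conc = p$conc, diff_coef = p$diff_coef,
                    scan_rate = p$scan_rate, temperature = p$temperature,
                    n_electrons = p$n_electrons, ru = p$ru, cdl = p$cdl)
}

#' @rdname save_params
#' @export
default_params_path <- function() {
  cfg <- Sys.getenv("VOLTKIT_CONFIG", "")
  if (nzchar(cfg)) return(cfg)
  file.path(tools::R_user_dir("voltkit", "config"), "params.yaml")
}

# --- smoothing ---------------------------------------------------------------

# center-point Savitzky-Golay weights for a symmetric window of half-width m
# and polynomial order k: first row of (X'X)^{-1} X' with X the Vandermonde
# matrix of offsets -m..m
sg_center_weights <- function(m, k) {
  off <- seq(-m, m)
  X <- outer(off, 0:k, `^`)
  drop(solve(crossprod(X), t(X))[1L, ])
}

#' Savitzky-Golay smoothing of the current axis
#'
#' Local least-squares polynomial smoothing of the current; the potential
#' axis is untouched. Near the record ends the window shrinks symmetrically
#' (with the polynomial order capped at the number of available offsets)
#' instead of padding, so no data is fabricated at sweep turns.
#'
#' @param vg A `voltammogram`.
#' @param poly_order Polynomial order (>= 0).
#' @param side_points Points on each side of the smoothed point; the window
#'   is `2 * side_points + 1` wide.
#' @return The smoothed `voltammogram`.
#' @export
#' @examples
#' vg <- synth_gaussian_peak(n = 256, noise_sigma = 0.05, seed = 1)
#' smooth_current(vg, poly_order = 2, side_points = 7)
smooth_current <- function(vg, poly_order = 2L, side_points = 7L) {
  y <- vg$current
  n <- length(y)
  m <- as.integer(side_points)
  k <- as.integer(poly_order)
  if (k < 0L || m < 1L) vk_abort("invalid_params", "Need poly_order >= 0, side_points >= 1.")
  if (2L * m + 1L > n) {
    vk_abort("window_too_large", sprintf(
      "Window of %d points exceeds the %d-point record.", 2L * m + 1L, n))
  }
  if (k >= 2L * m + 1L) {
    vk_abort("window_too_large", "poly_order must be < window width.")
  }
  sm <- y
  # interior: full window as a running weighted sum
  w <- sg_center_weights(m, k)
  core <- stats::filter(y, w, method = "convolution", sides = 2)
  idx <- (m + 1L):(n - m)
  sm[idx] <- core[idx]
  # edges: shrink the window symmetrically, cap the order
  for (j in seq_len(m)) {
    mj <- j - 1L
    if (mj == 0L) next  # 1-point window: value unchanged
    kj <- min(k, 2L * mj)
    wj <- sg_center_weights(mj, kj)
    sm[j] <- sum(wj * y[(j - mj):(j + mj)])
    sm[n - j + 1L] <- sum(wj * y[(n - j + 1L - mj):(n - j + 1L + mj)])
  }
  vg_update(vg, current = sm)
}

# --- background subtraction --------------------------------------------------

#' Subtract a blank voltammogram
#'
#' Point-for-point subtraction of a blank (supporting-electrolyte) record; an
#' alternative to the double-layer capacitance correction. The potential axes
#' must match point-for-point.
#'
#' @param vg A `voltammogram`.
#' @param blank The blank `voltammogram`, same potential axis.
#' @param tol Maximum tolerated potential-axis mismatch (V).
#' @return `vg` with the blank's current subtracted.
#' @export
subtract_background <- function(vg, blank, tol = 1e-9) {
  if (nrow(vg) != nrow(blank) || max(abs(vg$potential - blank$potential)) > tol) {
    vk_abort("x_axis_mismatch",
             "The potential axes of the voltammogram and the blank must match point-for-point.")
  }
  vg_update(vg, current = vg$current - blank$current)
}

# --- Ru / C_DL correction ----------------------------------------------------

# central differences interior, one-sided at the ends
central_diff <- function(y, t) {
  n <- length(y)
  d <- numeric(n)
  if (any(diff(t) <= 0)) {
    vk_abort("non_finite_derivative", "Duplicate time points: derivative undefined.")
  }
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d
}

#' Correct a voltammogram for IR drop and double-layer charging
#'
#' The potential axis is corrected for the ohmic drop across the
#' uncompensated resistance, `E' = E + I * Ru`, and the current axis for the
#' double-layer charging contribution,
#' `I_F = I + C_DL * dE'/dt + Ru * C_DL * dI/dt`, using central-difference
#' time derivatives. The corrected record is then re-interpolated onto a
#' uniform potential grid (per sweep direction, same point count) unless
#' `regrid = FALSE`. `ru = 0, cdl = 0` is the identity apart from that
#' re-grid; `cdl = 0` with `ru > 0` performs the separate IR correction only.
#'
#' The printed sign of the ohmic term matches one current-sign convention
#' only; `ir_sign = -1` flips it for records with the opposite convention.
#'
#' @param vg A `voltammogram` with a time axis (attached, or reconstructable
#'   from the scan rate).
#' @param ru Uncompensated resistance (Ohm).
#' @param cdl Double-layer capacitance (F).
#' @param ir_sign `+1` (default) or `-1`; sign of the `I * Ru` potential shift.
#' @param regrid Re-interpolate onto a uniform potential grid afterwards.
#' @return The corrected `voltammogram`.
#' @export
correct_ru_cdl <- function(vg, ru = 0, cdl = 0, ir_sign = 1, regrid = TRUE) {
  if (ru < 0 || cdl < 0) vk_abort("invalid_params", "`ru` and `cdl` must be >= 0.")
  if (!ir_sign %in% c(-1, 1)) vk_abort("invalid_params", "`ir_sign` must be +1 or -1.")
  if (ru == 0 && cdl == 0) {
    return(if (regrid) regrid_uniform(vg) else vg)
  }
  t <- vg_time(vg)
  e_prime <- vg$potential + ir_sign * vg$current * ru
  i_f <- vg$current
  if (cdl > 0) {
    i_f <- i_f + cdl * central_diff(e_prime, t) + ru * cdl * central_diff(vg$current, t)
  }
  out <- vg_update(vg, potential = e_prime, current = i_f, time = t)
  if (regrid) regrid_uniform(out) else out
}

#' Estimate the double-layer capacitance from a non-Faradaic window
#'
#' In the first approximation the double-layer capacitance is potential
#' independent and the purely capacitive current is `I = C_DL * dE/dt`, so a
#' least-squares fit of current on the local sweep rate over a user-selected
#' window of the record where no Faradaic reaction occurs yields C_DL.
#'
#' @param vg A `voltammogram`.
#' @param left,right Potential window (V) free of Faradaic current.
#' @return Estimated C_DL (F).
#' @export
estimate_cdl <- function(vg, left, right) {
  sel <- vg$potential >= min(left, right) & vg$potential <= max(left, right)
  if (sum(sel) < 2L) vk_abort("cursor_outside_range", "Window holds fewer than 2 points.")
  t <- vg_time(vg)
  dedt <- central_diff(vg$potential, t)
  fit <- lm(y ~ 0 + x, data = data.frame(y = vg$current[sel], x = dedt[sel]))
  # magnitude only: the sign of the capacitive term depends on the record's
  # current-sign convention (see the ir_sign discussion in correct_ru_cdl)
  abs(unname(coef(fit)[1]))
}

# --- dimensionless form ------------------------------------------------------

#' Convert a voltammogram to dimensionless form
#'
#' The current axis is divided by `F * A * C * sqrt(D * F * v / (R * T))`,
#' giving the dimensionless current psi; the potential axis is unchanged. The
#' time axis is simultaneously rescaled to the dimensionless time
#' `tau = (F * v / (R * T)) * t`, so that semiintegration of the result
#' plateaus at the apparent number of transferred electrons.
#'
#' @param vg A `voltammogram` (current in A).
#' @param params An [experiment_params()] object.
#' @return A dimensionless `voltammogram` (attribute `dimensionless` set).
#' @export
#' @examples
#' vg <- synth_cv(n_points = 512)
#' psi <- to_dimensionless(vg, attr(vg, "params"))
to_dimensionless <- function(vg, params) {
  stopifnot(inherits(params, "experiment_params"))
  if (isTRUE(attr(vg, "dimensionless"))) {
    warn("Voltammogram is already dimensionless; converting again.")
  }
  FF <- volt_constants[["F"]]
  RR <- volt_constants[["R"]]
  den <- FF * params$area * params$conc *
    sqrt(params$diff_coef * FF * params$scan_rate / (RR * params$temperature))
  sigma <- FF * params$scan_rate / (RR * params$temperature)  # 1/s
  t <- vg_time(vg)
  out <- vg_update(vg, current = vg$current / den, time = t * sigma)
  attr(out, "dimensionless") <- TRUE
  # in tau units the sweep advances at R*T/F volts per unit time
  attr(out, "scan_rate") <- RR * params$temperature / FF
  out
}
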