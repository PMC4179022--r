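#' Evaluate a peak against a cursor-defined baseline
#'
#' Implements the cursor workflow of differential-pulse / square-wave peak
#' evaluation (`baseline = "chord"`: the baseline is the chord through the
#' curve points nearest the two cursors) and cyclic-voltammetry evaluation
#' (`baseline = "tangent"`: the baseline is the least-squares tangent to the
#' curve over a window centred at the left cursor, i.e. the pre-peak foot).
#' The peak is the global extremum of the baseline-subtracted signed curve
#' between the cursors, optionally restricted to within `max_peak_distance`
#' of a cursor to pick out shoulders. The discrete extremum is refined by a
#' three-point parabolic fit unless `refine = FALSE`.
#'
#' With `iupac = FALSE` (classical polarographic orientation) the curve is
#' negated before evaluation, so reported heights are always >= 0.
#'
#' @param vg A `voltammogram`.
#' @param left,right Cursor abscissae (V), `left < right`, inside the record.
#' @param baseline `"chord"` or `"tangent"`.
#' @param tangent_window Potential span (V) of the regression window for the
#'   tangent baseline; must cover at least 2 samples.
#' @param iupac Logical; `FALSE` evaluates non-IUPAC-oriented records.
#' @param max_peak_distance Optional span (V) restricting the search to
#'   within this distance of either cursor.
#' @param refine Logical; parabolic sub-sample refinement of the extremum.
#' @return A one-row tibble of class `peak_result`: `peak_E`, `peak_I`
#'   (baseline-subtracted height, >= 0), `baseline_slope`,
#'   `baseline_intercept`, `baseline_kind`, `iupac`.
#' @export
#' @examples
#' vg <- synth_gaussian_peak(n = 1024)
#' find_peak(vg, left = 0.1, right = 0.9)
find_peak <- function(vg, left, right, baseline = c("chord", "tangent"),
                      tangent_window = NULL, iupac = NULL,
                      max_peak_distance = NULL, refine = TRUE) {
  baseline <- match.arg(baseline)
  if (is.null(iupac)) iupac <- isTRUE(attr(vg, "iupac"))
  e <- vg$potential
  if (left >= right) vk_abort("invalid_params", "`left` must be < `right`.")
  if (left < min(e) || right > max(e)) {
    vk_abort("cursor_outside_range", "Cursors must lie inside the potential range.")
  }
  sgn <- if (iupac) 1 else -1
  y <- sgn * vg$current
  il <- nearest_index(e, left)
  ir <- nearest_index(e, right)
  if (baseline == "chord") {
    slope <- (y[ir] - y[il]) / (e[ir] - e[il])
    intercept <- y[il] - slope * e[il]
  } else {
    if (is.null(tangent_window) || tangent_window <= 0) {
      vk_abort("invalid_params", "`tangent_window` (V) is required for the tangent baseline.")
    }
    fit <- local_tangent(e, y, left, tangent_window)
    slope <- fit[2]
    intercept <- fit[1]
  }
  win <- e >= min(left, right) & e <= max(left, right)
  if (!is.null(max_peak_distance)) {
    win <- win & (abs(e - left) <= max_peak_distance | abs(e - right) <= max_peak_distance)
  }
  if (sum(win) < 3L) vk_abort("cursor_outside_range", "Fewer than 3 points between the cursors.")
  idx <- which(win)
  resid <- y[idx] - (slope * e[idx] + intercept)
  k <- which.max(resid)
  scale <- max(abs(y[idx])) + max(abs(resid))
  if (resid[k] <= 1e-12 * max(scale, 1e-300) || k == 1L || k == length(idx)) {
    vk_abort("no_peak",
             "No interior maximum above the baseline between the cursors.")
  }
  j <- idx[k]
  peak_e <- e[j]
  peak_h <- resid[k]
  if (isTRUE(refine) && j > idx[1] && j < idx[length(idx)]) {
    ref <- parabolic_vertex(e[(j - 1):(j + 1)],
                            y[(j - 1):(j + 1)] - (slope * e[(j - 1):(j + 1)] + intercept))
    if (!is.null(ref) && ref[1] >= e[j - 1] && ref[1] <= e[j + 1]) {
      peak_e <- ref[1]
      peak_h <- ref[2]
    }
  }
  out <- tibble(peak_E = peak_e, peak_I = peak_h,
                baseline_slope = slope * sgn, baseline_intercept = intercept * sgn,
                baseline_kind = baseline, iupac = iupac)
  class(out) <- c("peak_result", class(out))
  attr(out, "vg") <- vg
  attr(out, "cursors") <- c(left, right)
  out
}

# sample nearest an abscissa; ties broken toward the lower index
nearest_index <- function(x, at) {
  d <- abs(x - at)
  which(d == min(d))[1L]
}

# least-squares line over the window [at - w/2, at + w/2]; c(intercept, slope)
local_tangent <- function(x, y, at, width) {
  sel <- x >= at - width / 2 & x <= at + width / 2
  if (sum(sel) < 2L) {
    vk_abort("invalid_params", "Tangent window covers fewer than 2 points.")
  }
  unname(coef(lm(yy ~ xx, data = data.frame(xx = x[sel], yy = y[sel]))))
}

# vertex of the parabola through 3 points; NULL if degenerate/concave-up
parabolic_vertex <- function(x, y) {
  X <- cbind(1, x, x^2)
  ab <- tryCatch(solve(X, y), error = function(e) NULL)
  if (is.null(ab) || ab[3] >= 0) return(NULL)
  xv <- unname(-ab[2] / (2 * ab[3]))
  c(xv, unname(ab[1] + ab[2] * xv + ab[3] * xv^2))
}

#' Split a cyclic voltammogram into half-cycles
#'
#' Splits the record at strict sign changes of the potential step. A monotone
#' linear-sweep record returns a single segment. Consecutive segments share
#' their vertex sample.
#'
#' @param vg A `voltammogram`.
#' @return A list of `voltammogram` half-cycles with attributes `n_half`
#'   and `n_cycles` (`floor(n_half / 2)`).
#' @export
#' @examples
#' cv <- synth_cv(n_points = 256)
#' length(split_cycles(cv))
split_cycles <- function(vg) {
  segs <- sweep_segments(vg$potential)
  out <- lapply(seq_along(segs), function(i) {
    idx <- segs[[i]]
    voltammogram(vg$potential[idx], vg$current[idx],
                 time = if ("time" %in% names(vg)) vg$time[idx] else NULL,
                 scan_rate = scan_rate(vg), iupac = attr(vg, "iupac"),
                 label = paste0(attr(vg, "label") %||% "cv", " half-cycle ", i))
  })
  attr(out, "n_half") <- length(out)
  attr(out, "n_cycles") <- length(out) %/% 2L
  out
}

#' Evaluate a wave-shaped response
#'
#' For sigmoidal responses (polarograms, rotating-disk voltammograms,
#' neopolarograms, amperometric steps) the signal is measured between a
#' lower (pre-wave) and an upper (post-wave) baseline anchored at the two
#' cursors. Three modes are available:
#' \describe{
#'   \item{flat}{both baselines horizontal at the curve values nearest the
#'     cursors — convenient for amperograms;}
#'   \item{skewed}{the lower baseline is the least-squares tangent at its
#'     cursor and the upper baseline adopts the same slope — appropriate for
#'     normal-pulse voltammetry;}
#'   \item{separate}{each baseline takes the slope of its own local tangent.}
#' }
#' The half-wave abscissa is where the curve crosses the line midway between
#' the baselines (linear interpolation between the bracketing samples;
#' multiple crossings resolve to the one nearest the steepest part of the
#' curve), and the wave height is the baseline gap at that abscissa.
#'
#' @param vg A `voltammogram` (use `x = "time"` for amperograms whose
#'   abscissa is time).
#' @param left,right Cursor abscissae: one on the pre-wave plateau, one on
#'   the post-wave plateau.
#' @param mode `"flat"`, `"skewed"` or `"separate"`.
#' @param tangent_window Abscissa span of the tangent regression windows
#'   (required for the skewed and separate modes).
#' @param x Column to use as the abscissa, `"potential"` or `"time"`.
#' @return A one-row tibble of class `wave_result`: `wave_height`,
#'   `half_wave_E`, `mode`, and the two baselines' slopes and intercepts.
#' @export
#' @examples
#' vg <- synth_sigmoid_wave(n = 1024)
#' evaluate_wave(vg, left = 0.05, right = 0.45, mode = "flat")
evaluate_wave <- function(vg, left, right, mode = c("flat", "skewed", "separate"),
                          tangent_window = NULL, x = c("potential", "time")) {
  mode <- match.arg(mode)
  x <- match.arg(x)
  e <- vg[[x]]
  y <- vg$current
  if (left >= right) vk_abort("invalid_params", "`left` must be < `right`.")
  if (left < min(e) || right > max(e)) {
    vk_abort("cursor_outside_range", "Cursors must lie inside the abscissa range.")
  }
  il <- nearest_index(e, left)
  ir <- nearest_index(e, right)
  if (mode == "flat") {
    lower <- c(y[il], 0)
    upper <- c(y[ir], 0)
  } else {
    if (is.null(tangent_window) || tangent_window <= 0) {
      vk_abort("invalid_params", "`tangent_window` is required for the skewed modes.")
    }
    tl <- local_tangent(e, y, left, tangent_window)
    if (mode == "skewed") {
      lower <- c(tl[1], tl[2])
      # same slope, anchored at the far cursor's curve point
      upper <- c(y[ir] - tl[2] * e[ir], tl[2])
    } else {
      tr <- local_tangent(e, y, right, tangent_window)
      lower <- c(tl[1], tl[2])
      upper <- c(tr[1], tr[2])
    }
  }
  sel <- which(e >= left & e <= right)
  b_lo <- lower[1] + lower[2] * e[sel]
  b_up <- upper[1] + upper[2] * e[sel]
  gap <- b_up - b_lo
  if (any(gap == 0) || !all(sign(gap) == sign(gap[1]))) {
    vk_abort("no_wave", "The baselines cross between the cursors.")
  }
  mid <- (b_lo + b_up) / 2
  d <- y[sel] - mid
  cross <- which(d[-1] * d[-length(d)] < 0 | d[-length(d)] == 0)
  if (length(cross) == 0L) {
    vk_abort("no_wave", "The curve never crosses the mid-gap line between the cursors.")
  }
  if (length(cross) > 1L) {
    slope_at <- abs(central_diff(y[sel], seq_along(sel)))
    cross <- cross[which.max(pmax(slope_at[cross], slope_at[cross + 1L]))]
  }
  k <- cross[1L]
  # linear interpolation between the bracketing samples
  frac <- if (d[k] == 0) 0 else d[k] / (d[k] - d[k + 1L])
  e_half <- e[sel][k] + frac * (e[sel][k + 1L] - e[sel][k])
  h <- abs((upper[1] + upper[2] * e_half) - (lower[1] + lower[2] * e_half))
  out <- tibble(wave_height = h, half_wave_E = e_half, mode = mode,
                lower_slope = lower[2], lower_intercept = lower[1],
                upper_slope = upper[2], upper_intercept = upper[1])
  class(out) <- c("wave_result", class(out))
  attr(out, "vg") <- vg
  attr(out, "cursors") <- c(left, right)
  attr(out, "x") <- x
  out
}

#' Export peak/wave results as CSV
#'
#' Writes one row per result with the potential first and the current second
#' (the spreadsheet row layout of classical peak-evaluation workflows):
#' `peak_E, peak_I` for peaks and `half_wave_E, wave_height` for waves.
#'
#' @param results A `peak_result`/`wave_result`, a list of them, or a data
#'   frame with columns `potential_V` and `current_A`.
#' @param path Output CSV path.
#' @param append Append to an existing file (header written only when the
#'   file does not yet exist).
#' @return `path`, invisibly.
#' @export
export_results <- function(results, path, append = FALSE) {
  if (inherits(results, "peak_result") || inherits(results, "wave_result")) {
    results <- list(results)
  }
  rows <- if (is.data.frame(results)) {
    results
  } else {
    dplyr::bind_rows(lapply(results, function(r) {
      if (inherits(r, "peak_result")) {
        tibble(potential_V = r$peak_E, current_A = r$peak_I)
      } else if (inherits(r, "wave_result")) {
        tibble(potential_V = r$half_wave_E, current_A = r$wave_height)
      } else {
        vk_abort("invalid_params", "Results must be peak_result or wave_result objects.")
      }
    }))
  }
  new_file <- !(append && file.exists(path))
  lines <- if (nrow(rows) == 0L) character() else
    sprintf("%.17g,%.17g", rows$potential_V, rows$current_A)
  if (new_file) lines <- c("potential_V,current_A", lines)
  con <- file(path, open = if (new_file) "w" else "a")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @method autoplot peak_result
#' @export
autoplot.peak_result <- function(object, ...) {
  vg <- attr(object, "vg")
  cur <- attr(object, "cursors")
  sgn <- if (object$iupac) 1 else -1
  p <- autoplot(vg) +
    ggplot2::geom_abline(slope = object$baseline_slope,
                         intercept = object$baseline_intercept,
                         linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cur, linetype = "dotted") +
    ggplot2::annotate("point", x = object$peak_E,
                      y = sgn * object$peak_I +
                        object$baseline_slope * object$peak_E +
                        object$baseline_intercept,
                      shape = 4, size = 3)
  p
}

#' @method autoplot wave_result
#' @export
autoplot.wave_result <- function(object, ...) {
  vg <- attr(object, "vg")
  cur <- attr(object, "cursors")
  autoplot(vg) +
    ggplot2::geom_abline(slope = object$lower_slope,
                         intercept = object$lower_intercept, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$upper_slope,
                         intercept = object$upper_intercept, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$half_wave_E, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = cur, linetype = "dotted", alpha = 0.4)
}
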