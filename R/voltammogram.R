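#' Construct a voltammogram
#'
#' A voltammogram is the package's universal currency: a tibble with columns
#' `potential` (V; or elapsed time in s for amperograms), `current` (A, or
#' dimensionless after [to_dimensionless()]) and `time` (s), plus metadata
#' carried in attributes (scan rate, plotting orientation, label).
#'
#' When `time` is not supplied it is reconstructed from the potential program
#' as `t_j = cumsum(|dE|) / v`, which supports direction reversals in cyclic
#' experiments. A scan rate is therefore required unless `time` is given
#' explicitly.
#'
#' @param potential Numeric vector of applied potentials (V).
#' @param current Numeric vector of measured currents (A), same length.
#' @param time Optional numeric vector of sample times (s), strictly
#'   increasing. Reconstructed from `potential` and `scan_rate` when `NULL`.
#' @param scan_rate Scan rate v (V s^-1). May be `NULL` for signals that do
#'   not need a time axis (e.g. peak evaluation of a pulse voltammogram).
#' @param iupac Logical; `TRUE` when the record follows the IUPAC orientation
#'   (anodic currents positive).
#' @param label Optional character label (e.g. the source file).
#' @param dimensionless Logical; `TRUE` once the current axis holds the
#'   dimensionless current psi.
#'
#' @return A tibble of class `voltammogram`.
#' @export
#' @examples
#' vg <- voltammogram(seq(0, 0.5, by = 0.01), rnorm(51, 1e-6, 1e-8),
#'                    scan_rate = 0.1)
#' vg
voltammogram <- function(potential, current, time = NULL, scan_rate = NULL,
                         iupac = TRUE, label = NULL, dimensionless = FALSE) {
  potential <- as.numeric(potential)
  current <- as.numeric(current)
  if (length(potential) != length(current)) {
    vk_abort("length_mismatch", "`potential` and `current` must have the same length.")
  }
  if (length(potential) < 2L) {
    vk_abort("too_few_points", "A voltammogram needs at least 2 points.")
  }
  if (anyNA(potential) || anyNA(current)) {
    vk_abort("non_finite", "`potential` and `current` must not contain NA.")
  }
  if (!is.null(time)) {
    time <- as.numeric(time)
    if (length(time) != length(potential)) {
      vk_abort("length_mismatch", "`time` must match `potential` in length.")
    }
    if (any(diff(time) <= 0)) {
      vk_abort("time_not_increasing", "`time` must be strictly increasing.")
    }
  } else if (!is.null(scan_rate)) {
    time <- reconstruct_time(potential, scan_rate)
  }
  out <- tibble(potential = potential, current = current)
  if (!is.null(time)) out$time <- time
  new_voltammogram(out, scan_rate = scan_rate, iupac = iupac, label = label,
                   dimensionless = dimensionless)
}

# low-level: stamp class + attributes onto a data frame
new_voltammogram <- function(df, scan_rate = NULL, iupac = TRUE, label = NULL,
                             dimensionless = FALSE, ...) {
  out <- as_tibble(df)
  class(out) <- c("voltammogram", class(out))
  attr(out, "scan_rate") <- scan_rate
  attr(out, "iupac") <- isTRUE(iupac)
  attr(out, "label") <- label
  attr(out, "dimensionless") <- isTRUE(dimensionless)
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Coerce a data frame to a voltammogram
#'
#' The first two numeric columns are taken as potential and current unless
#' columns named `potential` and `current` are present.
#'
#' @param x A data frame.
#' @inheritParams voltammogram
#' @param ... Unused.
#' @return A `voltammogram`.
#' @export
as_voltammogram <- function(x, scan_rate = NULL, iupac = TRUE, label = NULL, ...) {
  stopifnot(is.data.frame(x))
  if (all(c("potential", "current") %in% names(x))) {
    voltammogram(x$potential, x$current, time = x[["time"]],
                 scan_rate = scan_rate, iupac = iupac, label = label)
  } else {
    num <- which(vapply(x, is.numeric, logical(1)))
    if (length(num) < 2L) {
      vk_abort("not_voltammetric", "Need two numeric columns (potential, current).")
    }
    voltammogram(x[[num[1]]], x[[num[2]]], scan_rate = scan_rate,
                 iupac = iupac, label = label)
  }
}

#' Test for the voltammogram class
#' @param x An object.
#' @return Logical scalar.
#' @export
is_voltammogram <- function(x) inherits(x, "voltammogram")

#' Scan rate of a voltammogram
#' @param vg A `voltammogram`.
#' @return Scan rate in V s^-1, or `NULL`.
#' @export
scan_rate <- function(vg) attr(vg, "scan_rate")

#' @rdname scan_rate
#' @param value New scan rate (V s^-1).
#' @export
`scan_rate<-` <- function(vg, value) {
  attr(vg, "scan_rate") <- value
  if (!is.null(value) && !"time" %in% names(vg)) {
    vg$time <- reconstruct_time(vg$potential, value)
  }
  vg
}

# t_j = cumsum(|dE|)/v along the recorded order; supports CV reversals.
reconstruct_time <- function(potential, scan_rate) {
  if (is.null(scan_rate) || scan_rate <= 0) {
    vk_abort("invalid_params", "`scan_rate` must be a positive number.")
  }
  t <- cumsum(c(0, abs(diff(potential)))) / scan_rate
  if (any(diff(t) <= 0)) {
    vk_abort("non_finite_derivative",
             "Duplicate potential points: cannot reconstruct a strictly increasing time axis.")
  }
  t
}

# time column, reconstructing from the potential program when absent
vg_time <- function(vg) {
  if ("time" %in% names(vg)) return(vg$time)
  reconstruct_time(vg$potential, scan_rate(vg))
}

# replace columns while preserving voltammogram attributes
vg_update <- function(vg, potential = NULL, current = NULL, time = NULL, ...) {
  out <- vg
  if (!is.null(potential)) out$potential <- potential
  if (!is.null(current)) out$current <- current
  if (!is.null(time)) out$time <- time
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.voltammogram <- function(x, ...) {
  hdr <- sprintf(
    "# A voltammogram: %d points%s%s%s",
    nrow(x),
    if (!is.null(scan_rate(x))) sprintf(", v = %g V/s", scan_rate(x)) else "",
    if (isTRUE(attr(x, "dimensionless"))) ", dimensionless" else "",
    if (!is.null(attr(x, "label"))) sprintf(" [%s]", attr(x, "label")) else ""
  )
  cat(hdr, "\n")
  print(as_tibble(unclass_vg(x)), ...)
  invisible(x)
}

unclass_vg <- function(x) {
  class(x) <- setdiff(class(x), "voltammogram")
  x
}

#' Re-grid a voltammogram onto uniformly spaced potentials
#'
#' Each monotone sweep segment is linearly interpolated onto a uniform
#' potential grid spanning its own range, keeping the segment's point count.
#' The time axis is rebuilt from the scan rate when available.
#'
#' @param vg A `voltammogram`.
#' @param n Optional number of points per segment (default: keep counts).
#' @return A `voltammogram` with uniform potential spacing per sweep.
#' @export
regrid_uniform <- function(vg, n = NULL) {
  segs <- sweep_segments(vg$potential)
  pieces <- lapply(seq_along(segs), function(i) {
    idx <- segs[[i]]
    np <- if (is.null(n)) length(idx) else n
    e <- vg$potential[idx]
    grid <- seq(e[1], e[length(e)], length.out = np)
    y <- interp_lin(e, vg$current[idx], grid)
    # drop the duplicated junction point for segments after the first
    if (i > 1L) list(potential = grid[-1], current = y[-1])
    else list(potential = grid, current = y)
  })
  pot <- unlist(lapply(pieces, `[[`, "potential"))
  cur <- unlist(lapply(pieces, `[[`, "current"))
  tm <- if (!is.null(scan_rate(vg))) reconstruct_time(pot, scan_rate(vg)) else NULL
  out <- voltammogram(pot, cur, time = tm, scan_rate = scan_rate(vg),
                      iupac = attr(vg, "iupac"), label = attr(vg, "label"),
                      dimensionless = attr(vg, "dimensionless"))
  attr(out, "uniform_dx") <- TRUE
  out
}

# linear interpolation tolerating a decreasing abscissa; NA outside the range
interp_lin <- function(x, y, xout) {
  if (length(x) > 1L && x[1] > x[length(x)]) {
    x <- rev(x)
    y <- rev(y)
  }
  approx(x, y, xout = xout, ties = "ordered")$y
}

# indices of maximal monotone sweep segments (split at sign changes of dE);
# each segment includes its starting vertex so segments overlap by one point
sweep_segments <- function(potential) {
  d <- diff(potential)
  s <- sign(d)
  s[s == 0] <- NA
  # carry forward the last nonzero direction over flat steps
  for (i in seq_along(s)) if (is.na(s[i])) s[i] <- if (i > 1) s[i - 1] else 1
  breaks <- which(diff(s) != 0) + 1L  # first index of each new sweep (in d-space)
  starts <- c(1L, breaks)
  ends <- c(breaks, length(potential))
  Map(function(a, b) a:b, starts, ends)
}

#' Plot a voltammogram
#'
#' @param object A `voltammogram`.
#' @param ... Unused.
#' @return A ggplot object (current vs potential).
#' @method autoplot voltammogram
#' @export
autoplot.voltammogram <- function(object, ...) {
  ylab <- if (isTRUE(attr(object, "dimensionless"))) "dimensionless current psi"
          else "current / A"
  ggplot2::ggplot(as_tibble(unclass_vg(object)),
                  ggplot2::aes(x = .data$potential, y = .data$current)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "potential / V", y = ylab,
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' @export
plot.voltammogram <- function(x, ...) print(autoplot(x, ...))
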