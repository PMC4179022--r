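#' Voltammogram transforms
#'
#' Derivative, integral, semiderivative and semiintegral transforms. All four
#' operate on the time axis (reconstructed from the scan rate when not
#' attached) and return a `voltammogram` whose current column holds the
#' transformed signal plotted against the original potential, so transforms
#' compose without index bookkeeping.
#'
#' @param vg A `voltammogram`.
#' @param kind One of `"derivative"`, `"integral"`, `"semiderivative"`,
#'   `"semiintegral"`.
#' @return A transformed `voltammogram` (attribute `transform` records the
#'   kind).
#' @export
#' @examples
#' vg <- synth_cv(n_points = 512, dimensionless = TRUE)
#' neo <- transform_voltammogram(vg, "semiintegral")
transform_voltammogram <- function(vg, kind = c("semiintegral", "semiderivative",
                                                "derivative", "integral")) {
  kind <- match.arg(kind)
  switch(kind,
         derivative = vg_derivative(vg),
         integral = vg_integral(vg),
         semiintegral = semiintegrate(vg),
         semiderivative = semidifferentiate(vg))
}

#' @rdname transform_voltammogram
#' @export
vg_derivative <- function(vg) {
  if (nrow(vg) < 3L) vk_abort("too_few_points", "Derivative needs at least 3 points.")
  t <- vg_time(vg)
  vg_update(vg, current = central_diff(vg$current, t), transform = "derivative")
}

#' @rdname transform_voltammogram
#' @export
vg_integral <- function(vg) {
  if (nrow(vg) < 3L) vk_abort("too_few_points", "Integral needs at least 3 points.")
  t <- vg_time(vg)
  q <- drop(pracma::cumtrapz(t, vg$current))
  vg_update(vg, current = q, transform = "integral")
}

# uniform time step or error; returns dt
uniform_dt <- function(t, rtol = 1e-6) {
  d <- diff(t)
  dt <- mean(d)
  if (dt <= 0 || max(abs(d - dt)) > rtol * dt) {
    vk_abort("non_uniform_time_step",
             "Semiintegration needs a uniform time step; re-grid first (see regrid_uniform()).")
  }
  dt
}

# G1 (Grünwald-Letnikov) half-order integral of y sampled at step dt:
# m_j = sqrt(dt) * sum_{k=0..j-1} w_k y_{j-k}, w_0 = 1, w_k = w_{k-1} (k - 1/2)/k.
# The convolution is evaluated by FFT; the weights are the G1 recursion exactly.
g1_semiintegrate <- function(y, dt) {
  n <- length(y)
  k <- seq_len(n - 1L)
  w <- c(1, cumprod((k - 0.5) / k))
  m <- convolve(y, rev(w), type = "open")[seq_len(n)]
  sqrt(dt) * m
}

#' @rdname transform_voltammogram
#' @export
semiintegrate <- function(vg) {
  t <- vg_time(vg)
  dt <- uniform_dt(t)
  vg_update(vg, current = g1_semiintegrate(vg$current, dt), transform = "semiintegral")
}

#' @rdname transform_voltammogram
#' @details Semidifferentiation is performed as semiintegration followed by
#'   ordinary differentiation.
#' @export
semidifferentiate <- function(vg) {
  out <- vg_derivative(semiintegrate(vg))
  vg_update(out, transform = "semiderivative")
}
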