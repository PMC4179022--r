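# run expr with a local, restored RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

add_noise <- function(y, sigma, seed) {
  if (sigma <= 0) return(y)
  if (is.null(seed)) {
    vk_abort("invalid_spec", "A seed is required whenever noise_sigma > 0.")
  }
  with_seed(seed, y + stats::rnorm(length(y), 0, sigma))
}

default_synth_params <- function(scan_rate = 0.1) {
  experiment_params(area = 0.1, conc = 1e-6, diff_coef = 1e-5,
                    scan_rate = scan_rate, temperature = 298.15)
}

#' Generate a reversible cyclic voltammogram
#'
#' Constructs a Nernstian (reversible, planar semi-infinite diffusion) CV
#' through its semiintegral: the neopolarogram
#' `M(E) = n / (1 + exp(-n F (E - E0) / (R T)))` is laid down on the
#' triangular potential program and the dimensionless current is obtained as
#' its half-order derivative over dimensionless time. This construction is
#' exact for reversible planar diffusion and makes the semiintegral plateau
#' of the dimensionless record equal the electron count by construction. The
#' record describes an oxidation (anodic peak positive, IUPAC orientation).
#'
#' @param n_points Total number of samples over both sweeps (>= 64).
#' @param e_start,e_vertex Start and vertex potentials (V); the sweep runs
#'   `e_start -> e_vertex -> e_start`.
#' @param e0 Formal potential (V).
#' @param n_electrons Number of transferred electrons.
#' @param params [experiment_params()] used to scale the record into amperes
#'   and seconds (its `scan_rate` is the experiment's v).
#' @param noise_sigma Additive Gaussian current noise (A, or dimensionless
#'   units when `dimensionless = TRUE`); requires `seed` when > 0.
#' @param seed Integer seed for the noise.
#' @param dimensionless Return psi vs E on the dimensionless time axis
#'   instead of amperes vs seconds.
#' @return A `voltammogram`. Ground truth for testing is attached as
#'   attribute `truth` (list with `n_electrons`, `e0`, `plateau`, the
#'   noise-free semiintegral `M` and dimensionless current `psi`), and the
#'   generating `params` as attribute `params`.
#' @export
#' @examples
#' cv <- synth_cv(n_points = 512, n_electrons = 1)
#' attr(cv, "truth")$plateau
synth_cv <- function(n_points = 1024L, e_start = -0.25, e_vertex = 0.25,
                     e0 = 0, n_electrons = 1L,
                     params = default_synth_params(),
                     noise_sigma = 0, seed = NULL, dimensionless = FALSE) {
  n_points <- as.integer(n_points)
  if (n_points < 64L) vk_abort("invalid_spec", "`n_points` must be >= 64.")
  stopifnot(inherits(params, "experiment_params"))
  n <- n_electrons
  FF <- volt_constants[["F"]]
  RR <- volt_constants[["R"]]
  f_over_rt <- FF / (RR * params$temperature)
  # uniform triangular program: both sweeps share the step, so the sample
  # count is rounded to the nearest odd value
  m <- (n_points + 1L) %/% 2L
  fwd <- seq(e_start, e_vertex, length.out = m)
  e_prog <- c(fwd, rev(fwd)[-1L])
  eps <- f_over_rt * (e_prog - e0)
  # dimensionless time advances so that |d eps / d tau| = 1
  tau <- cumsum(c(0, abs(diff(eps))))
  dtau <- tau[2] - tau[1]
  m_true <- n / (1 + exp(-n * eps))
  psi <- central_diff(g1_semiintegrate(m_true, dtau), tau)
  truth <- list(n_electrons = n, e0 = e0, plateau = n, M = m_true, psi = psi)
  if (dimensionless) {
    cur <- add_noise(psi, noise_sigma, seed)
    out <- voltammogram(e_prog, cur, time = tau,
                        scan_rate = RR * params$temperature / FF,
                        label = "synthetic reversible CV (dimensionless)",
                        dimensionless = TRUE)
  } else {
    den <- FF * params$area * params$conc *
      sqrt(params$diff_coef * FF * params$scan_rate / (RR * params$temperature))
    cur <- add_noise(psi * den, noise_sigma, seed)
    out <- voltammogram(e_prog, cur, time = tau / (f_over_rt * params$scan_rate),
                        scan_rate = params$scan_rate,
                        label = "synthetic reversible CV")
  }
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  out
}

#' Generate a three-component scan-rate mixture
#'
#' Forward model of the elimination decomposition: on a common potential
#' grid, `I(E) = I_k(E) * rho^0 + I_d(E) * rho^(1/2) + I_c(E) * rho^1`, where
#' the kinetic, diffusion and capacitive shapes are supplied and `rho` is the
#' scan rate relative to the reference. The true components are stored for
#' oracle use in attribute `truth`.
#'
#' @param potential Common potential grid (V).
#' @param i_kinetic,i_diffusion,i_capacitive Component current shapes (A) on
#'   that grid (at the reference scan rate).
#' @param rel_rate Relative scan rate rho = v / v_ref.
#' @param scan_rate_ref Reference scan rate (V s^-1); the record's scan rate
#'   is `rel_rate * scan_rate_ref`.
#' @return A `voltammogram` with attribute `truth` holding the components.
#' @export
synth_mixture <- function(potential, i_kinetic, i_diffusion, i_capacitive,
                          rel_rate = 1, scan_rate_ref = 0.1) {
  lens <- lengths(list(potential, i_kinetic, i_diffusion, i_capacitive))
  if (length(unique(lens)) != 1L) {
    vk_abort("grid_mismatch", "All component shapes must share the potential grid.")
  }
  if (rel_rate <= 0) vk_abort("invalid_spec", "`rel_rate` must be > 0.")
  cur <- i_kinetic + i_diffusion * sqrt(rel_rate) + i_capacitive * rel_rate
  out <- voltammogram(potential, cur, scan_rate = rel_rate * scan_rate_ref,
                      label = sprintf("synthetic mixture rho=%g", rel_rate))
  attr(out, "truth") <- list(kinetic = i_kinetic, diffusion = i_diffusion,
                             capacitive = i_capacitive, rel_rate = rel_rate)
  out
}

#' Gaussian peak on a linear ramp
#'
#' `I(E) = intercept + slope * E + amp * exp(-(E - center)^2 / (2 sigma^2))`,
#' the standard fixture for peak-evaluation checks.
#'
#' @param n Number of points.
#' @param amp,center,sigma Gaussian amplitude, position (V) and width (V).
#' @param base_slope,base_intercept Linear baseline.
#' @param e_range Potential range, length 2.
#' @param noise_sigma,seed Additive Gaussian noise and its mandatory seed.
#' @return A `voltammogram` with attribute `truth`.
#' @export
synth_gaussian_peak <- function(n = 1024L, amp = 2, center = 0.5, sigma = 0.05,
                                base_slope = 0.5, base_intercept = 1,
                                e_range = c(0, 1), noise_sigma = 0, seed = NULL) {
  e <- seq(e_range[1], e_range[2], length.out = n)
  y <- base_intercept + base_slope * e + amp * exp(-(e - center)^2 / (2 * sigma^2))
  out <- voltammogram(e, add_noise(y, noise_sigma, seed),
                      label = "synthetic Gaussian peak")
  attr(out, "truth") <- list(amp = amp, center = center, sigma = sigma,
                             base_slope = base_slope, base_intercept = base_intercept)
  out
}

#' Sigmoid wave fixture
#'
#' `I(E) = intercept + slope * E + height / (1 + exp(-(E - half_wave)/width))`.
#'
#' @param n Number of points.
#' @param height Wave height (A).
#' @param half_wave Half-wave potential (V).
#' @param width Logistic width (V).
#' @param base_slope,base_intercept Linear baseline under the lower plateau.
#' @param e_range Potential range, length 2.
#' @param noise_sigma,seed Additive Gaussian noise and its mandatory seed.
#' @return A `voltammogram` with attribute `truth`.
#' @export
synth_sigmoid_wave <- function(n = 1024L, height = 1e-6, half_wave = 0.25,
                               width = 0.02, base_slope = 0, base_intercept = 0,
                               e_range = c(0, 0.5), noise_sigma = 0, seed = NULL) {
  e <- seq(e_range[1], e_range[2], length.out = n)
  y <- base_intercept + base_slope * e + height / (1 + exp(-(e - half_wave) / width))
  out <- voltammogram(e, add_noise(y, noise_sigma, seed),
                      label = "synthetic sigmoid wave")
  attr(out, "truth") <- list(height = height, half_wave = half_wave, width = width,
                             base_slope = base_slope, base_intercept = base_intercept)
  out
}

#' Staircase amperogram fixture
#'
#' Constant-potential amperometry with standard additions: the current steps
#' up by `step_height` at each addition. The abscissa is time; evaluate the
#' steps with [evaluate_wave()] in flat mode (`x = "time"`).
#'
#' @param n_steps Number of additions.
#' @param step_height Current increment per addition (A).
#' @param step_length Duration of each plateau (s).
#' @param dt Sampling interval (s).
#' @param i0 Baseline current (A).
#' @param tau Exponential approach time constant (s) after each addition.
#' @param noise_sigma,seed Additive Gaussian noise and its mandatory seed.
#' @return A `voltammogram` whose `time` column is the abscissa; `potential`
#'   is held at 0. Attribute `truth` stores the step times and heights.
#' @export
synth_staircase <- function(n_steps = 4L, step_height = 1e-7, step_length = 60,
                            dt = 0.5, i0 = 1e-8, tau = 2,
                            noise_sigma = 0, seed = NULL) {
  t_end <- (n_steps + 1) * step_length
  t <- seq(0, t_end, by = dt)
  step_times <- step_length * seq_len(n_steps)
  y <- rep(i0, length(t))
  for (ts in step_times) {
    after <- t >= ts
    y[after] <- y[after] + step_height * (1 - exp(-(t[after] - ts) / tau))
  }
  out <- voltammogram(rep(0, length(t)), add_noise(y, noise_sigma, seed),
                      time = t, label = "synthetic staircase amperogram")
  attr(out, "truth") <- list(step_times = step_times, step_height = step_height,
                             i0 = i0, tau = tau)
  out
}

#' Distort a voltammogram with IR drop and double-layer charging
#'
#' Forward model inverted by [correct_ru_cdl()]: the input's potential is the
#' true electrode potential E' and its current the Faradaic current I_F. The
#' measured current solves `I = I_F - C_DL dE'/dt - Ru C_DL dI/dt` (fixed
#' point iteration over the same central-difference operator the corrector
#' uses) and the recorded potential is `E = E' - I * Ru`. The true time axis
#' is kept on the output (physically, the applied ramp is uniform in time).
#'
#' @param vg The clean `voltammogram` (E', I_F).
#' @param ru Uncompensated resistance (Ohm).
#' @param cdl Double-layer capacitance (F).
#' @param max_iter,tol Fixed-point iteration controls.
#' @return The distorted `voltammogram`.
#' @export
#' @examples
#' cv <- synth_cv(n_points = 512)
#' raw <- distort_ru_cdl(cv, ru = 100, cdl = 1e-6)
distort_ru_cdl <- function(vg, ru = 0, cdl = 0, max_iter = 200L, tol = 1e-14) {
  if (ru < 0 || cdl < 0) vk_abort("invalid_params", "`ru` and `cdl` must be >= 0.")
  if (ru == 0 && cdl == 0) return(vg)
  t <- vg_time(vg)
  e_prime <- vg$potential
  i_f <- vg$current
  rhs <- i_f - cdl * central_diff(e_prime, t)
  i_meas <- rhs
  if (ru * cdl > 0) {
    for (it in seq_len(max_iter)) {
      i_new <- rhs - ru * cdl * central_diff(i_meas, t)
      delta <- max(abs(i_new - i_meas))
      i_meas <- i_new
      if (delta <= tol * max(abs(i_meas), 1e-300)) break
    }
  }
  e_meas <- e_prime - i_meas * ru
  vg_update(vg, potential = e_meas, current = i_meas, time = t)
}

#' Write a trace in a potentiostat ASCII dialect
#'
#' Test-fixture writer: emits one or more traces in the given [dialect()]
#' with arbitrary header lines, covering paired `X1 Y1 X2 Y2` layouts,
#' shared-X multi-column layouts and decimal-comma files, so the parser can
#' be exercised round-trip without instrument data.
#'
#' @param vgrams A `voltammogram` or a list of them (all the same length; in
#'   the shared-X layout they must share the first trace's potential axis).
#' @param path Output file path.
#' @param dialect A [dialect()]; its first item delimiter separates items.
#' @param header_lines Character vector of junk header lines to prepend.
#' @param eol Line delimiter (`"\n"`, `"\r\n"` or `"\r"`).
#' @return `path`, invisibly.
#' @export
write_dialect <- function(vgrams, path, dialect = dialect(),
                          header_lines = character(), eol = "\n") {
  if (is_voltammogram(vgrams)) vgrams <- list(vgrams)
  n <- nrow(vgrams[[1L]])
  if (!all(vapply(vgrams, nrow, integer(1)) == n)) {
    vk_abort("grid_mismatch", "All traces must have the same length.")
  }
  sep <- dialect$item_delims[[1L]]
  fmt_num <- function(v) {
    s <- sprintf("%.15g", v)
    if (dialect$decimal_mark == ",") s <- gsub(".", ",", s, fixed = TRUE)
    s
  }
  cols <- if (dialect$layout == "paired_xy") {
    unlist(lapply(vgrams, function(v) list(fmt_num(v$potential), fmt_num(v$current))),
           recursive = FALSE)
  } else {
    c(list(fmt_num(vgrams[[1L]]$potential)),
      lapply(vgrams, function(v) fmt_num(v$current)))
  }
  rows <- do.call(paste, c(cols, sep = sep))
  txt <- paste0(paste(c(header_lines, rows), collapse = eol), eol)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  invisible(path)
}
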