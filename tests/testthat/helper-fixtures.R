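# shared fixtures and small oracles, built in code at test time

# uniform linear-sweep voltammogram with an arbitrary current shape
lsv <- function(n, f, e_range = c(0, 1), scan_rate = 0.1) {
  e <- seq(e_range[1], e_range[2], length.out = n)
  voltammogram(e, f(e), scan_rate = scan_rate)
}

# voltammogram over an explicit time axis (potential = ramp at 1 V/s)
timed <- function(t, y) voltammogram(t, y, time = t, scan_rate = 1)

# closed-form semiintegral of t^p
semi_power <- function(p, t) gamma(p + 1) / gamma(p + 1.5) * t^(p + 0.5)

# signal-scale sup-norm relative error
rel_sup <- function(x, ref) max(abs(x - ref)) / max(abs(ref))

# three-component mixture trio on a shared grid at relative rates rho
mixture_trio <- function(rho = c(0.5, 1, 2), n = 257) {
  e <- seq(-0.2, 0.2, length.out = n)
  ik <- 2e-7 * exp(-((e + 0.05) / 0.07)^2)
  id <- 1e-6 * exp(-(e / 0.05)^2)
  ic <- 5e-8 + 1e-7 * e
  list(vgrams = lapply(rho, function(r)
         synth_mixture(e, ik, id, ic, rel_rate = r, scan_rate_ref = 0.2)),
       e = e, kinetic = ik, diffusion = id, capacitive = ic, rho = rho)
}

expect_vk_error <- function(expr, class) {
  expect_error(expr, class = paste0("voltkit_error_", class))
}
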