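test_that("the conserve-diffusion double elimination at (0.5,1,2) gives the classical coefficients", {
  fit <- solve_elimination(
    elimination_spec("diffusion", c("kinetic", "capacitive"), c(0.5, 1, 2)))
  a <- unname(coef(fit))
  expect_equal(signif(a[1], 5), -11.657)
  expect_equal(signif(a[2], 5), 17.485)
  expect_equal(signif(a[3], 5), -5.8284)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("two-rate and identity systems solve to the hand-derived values", {
  # a1 + sqrt(2) a2 = 1, a1 + 2 a2 = 0  =>  a = (2 + sqrt(2), -(2 + sqrt(2))/2)
  fit <- solve_elimination(elimination_spec("diffusion", "capacitive", c(1, 2)))
  expect_equal(unname(coef(fit)), c(2 + sqrt(2), -(2 + sqrt(2)) / 2),
               tolerance = 1e-12)
  expect_equal(signif(unname(coef(fit)), 5), c(3.4142, -1.7071))
  ident <- solve_elimination(elimination_spec("kinetic", character(), 1))
  expect_equal(unname(coef(ident)), 1)
})

test_that("spec validation rejects inconsistent selections", {
  expect_vk_error(elimination_spec("diffusion", "diffusion", c(0.5, 1)),
                  "invalid_spec")
  expect_vk_error(elimination_spec("diffusion", "kinetic", c(0.5, 1, 2)),
                  "invalid_spec")
  expect_vk_error(elimination_spec("diffusion", "kinetic", c(1, 1)),
                  "singular_system")
  expect_vk_error(elimination_spec("diffusion", "kinetic", c(0.5, 2)),
                  "invalid_spec")  # no reference rate
})

test_that("every standard function satisfies its constraints at random rate sets", {
  set.seed(14)
  for (rep in 1:3) {
    rho <- sort(c(1, runif(2, 0.2, 3)))
    while (anyDuplicated(signif(rho, 12))) rho <- sort(c(1, runif(2, 0.2, 3)))
    fits <- standard_eliminations(rho)
    expect_named(fits, paste0("E", 1:6))
    for (fit in fits) {
      expect_lt(max(abs(fit$residuals)), 1e-9)
      powers <- voltkit:::vk_powers
      rr <- fit$spec$rel_rates
      a <- unname(coef(fit))
      expect_equal(sum(a * rr^powers[fit$spec$conserve]), 1, tolerance = 1e-9)
      for (el in fit$spec$eliminate) {
        expect_equal(sum(a * rr^powers[el]), 0, tolerance = 1e-9)
      }
    }
  }
})

test_that("permuting the input rate order permutes the coefficients consistently", {
  rho <- c(0.5, 1, 2)
  fit <- solve_elimination(elimination_spec("diffusion", c("kinetic", "capacitive"), rho))
  perm <- c(3, 1, 2)
  fit2 <- solve_elimination(
    elimination_spec("diffusion", c("kinetic", "capacitive"), rho[perm]))
  expect_equal(unname(coef(fit2)), unname(coef(fit))[perm], tolerance = 1e-12)
})

test_that("double eliminations recover their conserved component exactly", {
  trio <- mixture_trio()
  targets <- list(diffusion = trio$diffusion, kinetic = trio$kinetic,
                  capacitive = trio$capacitive)
  for (keep in names(targets)) {
    spec <- elimination_spec(keep, setdiff(names(targets), keep), trio$rho)
    out <- apply_elimination(trio$vgrams, spec)
    expect_equal(out$current, targets[[keep]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("single eliminations conserve one component and pass the third through scaled", {
  trio <- mixture_trio()
  fits <- standard_eliminations(trio$rho)
  comp <- list(kinetic = trio$kinetic, diffusion = trio$diffusion,
               capacitive = trio$capacitive)
  powers <- voltkit:::vk_powers
  for (lab in c("E1", "E2", "E3")) {
    fit <- fits[[lab]]
    sub <- trio$vgrams[match(fit$spec$rel_rates, trio$rho)]
    out <- apply_elimination(sub, fit)
    third <- setdiff(names(comp), c(fit$spec$conserve, fit$spec$eliminate))
    passthrough <- sum(unname(coef(fit)) * fit$spec$rel_rates^powers[third])
    expected <- comp[[fit$spec$conserve]] + passthrough * comp[[third]]
    expect_equal(out$current, expected, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a rate-independent signal is annihilated when v^0 is eliminated", {
  e <- seq(0, 1, length.out = 65)
  shape <- sin(2 * e) * 1e-6
  vgs <- lapply(c(0.05, 0.1, 0.2), function(v)
    voltammogram(e, shape, scan_rate = v))
  out <- apply_elimination(
    vgs, elimination_spec("diffusion", c("kinetic", "capacitive"), c(0.5, 1, 2)))
  expect_lt(max(abs(out$current)), 1e-6 * 1e-9)
})

test_that("elimination is scale invariant and checks rates and grids", {
  trio <- mixture_trio()
  spec <- elimination_spec("diffusion", c("kinetic", "capacitive"), trio$rho)
  out1 <- apply_elimination(trio$vgrams, spec)
  scaled <- lapply(trio$vgrams, function(v) vg_update(v, current = 3.7 * v$current))
  out2 <- apply_elimination(scaled, spec)
  expect_equal(out2$current, 3.7 * out1$current, tolerance = 1e-12)
  expect_vk_error(
    apply_elimination(trio$vgrams, spec, rates = c(0.1, 0.2, 0.3)),
    "rate_mismatch")
  expect_vk_error(apply_elimination(trio$vgrams[1:2], spec), "rate_mismatch")
})

test_that("inputs on shifted grids are interpolated onto the reference grid", {
  e_ref <- seq(-0.2, 0.2, length.out = 201)
  shape_k <- 1e-7 * exp(-((e_ref + 0.05) / 0.07)^2)
  shape_d <- 1e-6 * exp(-(e_ref / 0.05)^2)
  make <- function(e, rho) {
    k <- 1e-7 * exp(-((e + 0.05) / 0.07)^2)
    d <- 1e-6 * exp(-(e / 0.05)^2)
    voltammogram(e, k + d * sqrt(rho), scan_rate = 0.1 * rho)
  }
  vgs <- list(make(e_ref, 1),
              make(seq(-0.25, 0.25, length.out = 301), 0.5),
              make(seq(-0.21, 0.19, length.out = 157), 2))
  out <- apply_elimination(
    vgs, elimination_spec("diffusion", c("kinetic", "capacitive"), c(0.5, 1, 2)))
  keep <- out$potential >= -0.21 & out$potential <= 0.19
  ref_d <- 1e-6 * exp(-(out$potential / 0.05)^2)
  # limited only by linear-interpolation error on the coarsest input grid
  expect_lt(max(abs(out$current - ref_d)) / max(ref_d), 0.01)
})

test_that("an adsorption-controlled trio yields the peak-counter-peak signature", {
  # surface-confined Faradaic current scales as v^1 and its peak shifts
  # slightly with log(v); the conserve-diffusion function then leaves a
  # bipolar residue crossing zero near the peak
  e <- seq(-0.2, 0.2, length.out = 401)
  rho <- c(0.5, 1, 2)
  vgs <- lapply(rho, function(r) {
    peak <- 1e-6 * r * exp(-((e - 0.01 * log(r)) / 0.04)^2)
    voltammogram(e, peak, scan_rate = 0.1 * r)
  })
  out <- apply_elimination(
    vgs, elimination_spec("diffusion", c("kinetic", "capacitive"), rho))
  win <- abs(out$potential) < 0.1
  expect_gt(max(out$current[win]), 0)
  expect_lt(min(out$current[win]), 0)
  s <- sign(out$current[win][abs(out$current[win]) > 1e-9])
  expect_true(any(diff(s) != 0))  # zero crossing between the lobes
})

test_that("tidy and glance summarise an elimination fit", {
  fit <- standard_eliminations(c(0.5, 1, 2))$E4
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$rel_rate, c(0.5, 1, 2))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$conserve, "diffusion")
  expect_equal(gl$label, "E4")
  expect_lt(gl$max_residual, 1e-9)
})
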