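test_that("a Gaussian on a linear ramp is recovered by the chord baseline", {
  for (n in c(256, 1024)) {
    vg <- synth_gaussian_peak(n = n, amp = 2, center = 0.5, sigma = 0.05,
                              base_slope = 0.5, base_intercept = 1)
    res <- find_peak(vg, left = 0.1, right = 0.9)
    step <- diff(vg$potential[1:2])
    expect_lt(abs(res$peak_E - 0.5), step)
    expect_lt(abs(res$peak_I - 2) / 2, 0.01)
  }
})

test_that("peak recovery error shrinks with grid density", {
  errs <- sapply(c(256, 1024, 4096), function(n) {
    vg <- synth_gaussian_peak(n = n, amp = 2, center = 0.503, sigma = 0.05)
    res <- find_peak(vg, 0.1, 0.9)
    abs(res$peak_I - 2)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate inputs raise NoPeak and cursor errors", {
  line <- lsv(101, function(e) 1 + 2 * e)
  expect_vk_error(find_peak(line, 0.1, 0.9), "no_peak")
  expect_vk_error(find_peak(line, 0.9, 0.1), "invalid_params")
  expect_vk_error(find_peak(line, -0.5, 0.9), "cursor_outside_range")
  expect_vk_error(find_peak(line, 0.1, 0.9, baseline = "tangent",
                            tangent_window = 0.05), "no_peak")
})

test_that("orientation symmetry: negated current with iupac=FALSE is identical", {
  vg <- synth_gaussian_peak(n = 512)
  res <- find_peak(vg, 0.1, 0.9)
  neg <- vg_update(vg, current = -vg$current)
  res_neg <- find_peak(neg, 0.1, 0.9, iupac = FALSE)
  expect_equal(res_neg$peak_E, res$peak_E)
  expect_equal(res_neg$peak_I, res$peak_I)
  expect_gte(res$peak_I, 0)
  expect_gte(res_neg$peak_I, 0)
})

test_that("translation and current-scale equivariance hold exactly", {
  vg <- synth_gaussian_peak(n = 512)
  res <- find_peak(vg, 0.1, 0.9, refine = FALSE)
  shifted <- voltammogram(vg$potential + 0.35, vg$current)
  res_s <- find_peak(shifted, 0.45, 1.25, refine = FALSE)
  expect_equal(res_s$peak_E, res$peak_E + 0.35, tolerance = 1e-12)
  scaled <- vg_update(vg, current = 2.5 * vg$current)
  res_c <- find_peak(scaled, 0.1, 0.9, refine = FALSE)
  expect_equal(res_c$peak_I, 2.5 * res$peak_I, tolerance = 1e-12)
})

test_that("max_peak_distance restricts the search to a shoulder", {
  e <- seq(0, 1, length.out = 1001)
  y <- 2 * exp(-((e - 0.5) / 0.05)^2) + 0.8 * exp(-((e - 0.26) / 0.03)^2)
  vg <- voltammogram(e, y)
  main <- find_peak(vg, 0.1, 0.9)
  expect_lt(abs(main$peak_E - 0.5), 0.01)
  shoulder <- find_peak(vg, 0.2, 0.9, max_peak_distance = 0.1)
  expect_lt(abs(shoulder$peak_E - 0.26), 0.01)
})

test_that("the tangent baseline evaluates a CV forward sweep within 3%", {
  cv <- synth_cv(n_points = 4097, dimensionless = TRUE)
  half <- (nrow(cv) + 1) %/% 2
  fwd <- split_cycles(cv)[[1]]
  res <- find_peak(fwd, left = -0.15, right = 0.15,
                   baseline = "tangent", tangent_window = 0.02)
  # oracle: construction peak minus the extrapolated foot tangent
  y <- fwd$current
  e <- fwd$potential
  sel <- abs(e + 0.15) <= 0.01
  foot <- lm(y ~ e, data = data.frame(e = e[sel], y = y[sel]))
  truth <- max(y - predict(foot, newdata = data.frame(e = e)))
  expect_lt(abs(res$peak_I - truth) / truth, 0.03)
  # invariance to an added linear ramp (the tangent absorbs it)
  ramp <- vg_update(fwd, current = fwd$current + 0.3 * fwd$potential + 0.1)
  res_r <- find_peak(ramp, -0.15, 0.15, baseline = "tangent", tangent_window = 0.02)
  expect_lt(abs(res_r$peak_I - res$peak_I) / res$peak_I, 0.01)
})

test_that("cycle splitting counts half cycles and finds the vertices", {
  # triangular 3-cycle program: 6 half cycles
  up <- seq(0, 1, length.out = 51)
  tri <- c(up, rev(up)[-1])
  e3 <- c(tri, tri[-1], tri[-1])
  vg <- voltammogram(e3, sin(seq_along(e3) / 10), scan_rate = 1)
  segs <- split_cycles(vg)
  expect_length(segs, 6)
  expect_equal(attr(segs, "n_cycles"), 3)
  # monotone sweep: one segment
  expect_length(split_cycles(lsv(64, function(e) e)), 1)
  # 2.5-cycle record: 5 half cycles, boundaries at the programmed vertices
  e25 <- c(tri, tri[-1], up[-1])
  vg25 <- voltammogram(e25, rep(1, length(e25)), scan_rate = 1)
  segs25 <- split_cycles(vg25)
  expect_length(segs25, 5)
  vertices <- vapply(segs25, function(s) s$potential[nrow(s)], numeric(1))
  expect_equal(vertices, c(1, 0, 1, 0, 1))
})

test_that("sigmoid waves are recovered in all three baseline modes", {
  step <- 0.5 / 1023
  flat_vg <- synth_sigmoid_wave(n = 1024, height = 1e-6, half_wave = 0.25)
  res <- evaluate_wave(flat_vg, 0.05, 0.45, mode = "flat")
  expect_lt(abs(res$wave_height - 1e-6) / 1e-6, 0.01)
  expect_lt(abs(res$half_wave_E - 0.25), step)

  ramp_vg <- synth_sigmoid_wave(n = 1024, height = 1e-6, half_wave = 0.25,
                                base_slope = 2e-7)
  res_sk <- evaluate_wave(ramp_vg, 0.05, 0.45, mode = "skewed",
                          tangent_window = 0.04)
  expect_lt(abs(res_sk$wave_height - 1e-6) / 1e-6, 0.02)
  expect_lt(abs(res_sk$half_wave_E - 0.25), 2 * step)

  res_sep <- evaluate_wave(ramp_vg, 0.05, 0.45, mode = "separate",
                           tangent_window = 0.04)
  expect_lt(abs(res_sep$wave_height - 1e-6) / 1e-6, 0.02)
  expect_lt(abs(res_sep$half_wave_E - 0.25), 2 * step)
})

test_that("waves degenerate cleanly", {
  flatline <- lsv(101, function(e) rep(1e-6, 101))
  expect_vk_error(evaluate_wave(flatline, 0.1, 0.9, mode = "flat"), "no_wave")
})

test_that("staircase amperograms evaluate step by step in flat mode", {
  amp <- synth_staircase(n_steps = 3, step_height = 1e-7, step_length = 60,
                         dt = 0.5, i0 = 1e-8)
  truth <- attr(amp, "truth")
  for (k in 1:3) {
    ts <- truth$step_times[k]
    res <- evaluate_wave(amp, left = ts - 15, right = ts + 50,
                         mode = "flat", x = "time")
    expect_lt(abs(res$wave_height - 1e-7) / 1e-7, 0.02)
    expect_gt(res$half_wave_E, ts)
  }
})

test_that("results export potential-first and round-trip", {
  vg <- synth_gaussian_peak(n = 256)
  p1 <- find_peak(vg, 0.1, 0.9)
  w1 <- evaluate_wave(synth_sigmoid_wave(n = 256), 0.05, 0.45, mode = "flat")
  f <- withr::local_tempfile(fileext = ".csv")
  export_results(list(p1, w1), f)
  back <- read.csv(f)
  expect_equal(names(back), c("potential_V", "current_A"))
  expect_equal(back$potential_V, c(p1$peak_E, w1$half_wave_E))
  expect_equal(back$current_A, c(p1$peak_I, w1$wave_height))
  # appending adds rows without duplicating the header
  export_results(p1, f, append = TRUE)
  expect_equal(nrow(read.csv(f)), 3)
  # empty result list gives a header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_results(list(), f2)
  expect_equal(nrow(read.csv(f2)), 0)
})

test_that("result autoplots build", {
  vg <- synth_gaussian_peak(n = 256)
  p <- autoplot(find_peak(vg, 0.1, 0.9))
  expect_s3_class(p, "ggplot")
  w <- autoplot(evaluate_wave(synth_sigmoid_wave(n = 256), 0.05, 0.45, "flat"))
  expect_s3_class(w, "ggplot")
  expect_no_error(ggplot2::ggplot_build(w))
})
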