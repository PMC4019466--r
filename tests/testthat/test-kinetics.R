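test_that("rates extract from linear and burst-contaminated traces", {
  # perfectly linear: slope -0.001/s with eps 6220 -> 0.1608 uM/s
  t <- seq(0, 600, by = 5)
  a <- 0.9 - 0.001 * t
  r <- rate_from_trace(t, a, epsilon = 6220, path = 1)
  expect_equal(r$rate, 0.001 / 6220 * 1e6, tolerance = 1e-9)
  expect_equal(r$rate, 0.1608, tolerance = 1e-3)
  expect_false(r$low_confidence)
  # zero slope
  r0 <- rate_from_trace(t, rep(0.5, length(t)))
  expect_equal(r0$rate, 0)
  # burst then linear: window finds the linear phase within 2%
  tr <- make_absorbance_trace(0.16, burst_amplitude = 0.08, burst_tau = 40)
  rb <- rate_from_trace(tr$data$time, tr$data$a340)
  expect_equal(rb$rate, 0.16, tolerance = 0.02)
  # blank subtraction removes a shared drift
  drift <- 0.0004 * t
  rr <- rate_from_trace(t, a + drift, reference = drift)
  expect_equal(rr$rate, 0.001 / 6220 * 1e6, tolerance = 1e-9)
  expect_error(rate_from_trace(t, c(a[-1], NA)), "non-finite")
})

test_that("michaelis-menten fit recovers noise-free parameters essentially exactly", {
  kd <- make_kinetics_data(Km = 52, kcat = 6.12e-3, enzyme_conc = 5)
  fit <- mm_fit(kd$data$substrate, kd$data$rate, kd$enzyme_conc)
  expect_equal(fit$Km, 52, tolerance = 1e-6)
  expect_equal(fit$kcat, 6.12e-3, tolerance = 1e-6)
  # fitted curve passes through Vmax/2 at S = Km
  v_at_km <- fit$Vmax * fit$Km / (fit$Km + fit$Km)
  expect_equal(v_at_km, fit$Vmax / 2)
})

test_that("mm fit matches a brute-force grid search on noisy data", {
  kd <- make_kinetics_data(noise_cv = 0.05, seed = 17)
  fit <- mm_fit(kd$data$substrate, kd$data$rate, kd$enzyme_conc)
  grid <- mm_grid_sse(kd$data$substrate, kd$data$rate,
                      km_range = c(10, 200), vmax_range = c(0.01, 0.08))
  sse_fit <- sum(residuals(fit$fit)^2)
  expect_lte(sse_fit, grid$sse * 1.01)
  expect_equal(fit$Km, grid$Km, tolerance = 0.01)
  expect_equal(fit$Vmax, grid$Vmax, tolerance = 0.01)
})

test_that("mm fit is scale equivariant", {
  kd <- make_kinetics_data()
  f1 <- mm_fit(kd$data$substrate, kd$data$rate, kd$enzyme_conc)
  alpha <- 13.7
  f2 <- mm_fit(kd$data$substrate, alpha * kd$data$rate, kd$enzyme_conc)
  expect_equal(f2$Km, f1$Km, tolerance = 1e-9)
  expect_equal(f2$Vmax, alpha * f1$Vmax, tolerance = 1e-9)
})

test_that("parameter recovery stays accurate across noisy replicates", {
  errs_km <- errs_kcat <- numeric(200)
  for (k in 1:200) {
    kd <- make_kinetics_data(noise_cv = 0.05, seed = k)
    fit <- mm_fit(kd$data$substrate, kd$data$rate, kd$enzyme_conc)
    errs_km[k] <- abs(fit$Km - 52) / 52
    errs_kcat[k] <- abs(fit$kcat - 6.12e-3) / 6.12e-3
  }
  expect_lt(median(errs_km), 0.10)
  expect_lt(median(errs_kcat), 0.05)
})

test_that("efficiency reduction behaves as a ratio statistic", {
  kd <- make_kinetics_data()
  fit <- mm_fit(kd$data$substrate, kd$data$rate, kd$enzyme_conc)
  expect_equal(efficiency_reduction(fit, fit), 0)
  expect_equal(efficiency_reduction(fit, 0), 100)
  expect_equal(efficiency_reduction(fit$efficiency, 0.06 * fit$efficiency), 94)
  # invariant to common rescaling of both efficiencies
  expect_equal(efficiency_reduction(3 * fit$efficiency, 3 * 0.06 * fit$efficiency), 94)
  expect_error(efficiency_reduction(0, 1), "zero")
})

test_that("binding fit recovers Kd and honours a frozen scale", {
  bd <- make_binding_data(Kd = 1.5, s = 0.85)
  fit <- binding_fit(bd$data$protein_conc, bd$data$signal)
  expect_equal(fit$Kd, 1.5, tolerance = 1e-6)
  expect_equal(fit$s, 0.85, tolerance = 1e-6)
  # signal at [P] = Kd is s/2 on the fitted curve
  expect_equal(fit$s * fit$Kd / (fit$Kd + fit$Kd), fit$s / 2)
  # frozen scale propagates across a series
  f2 <- binding_fit(bd$data$protein_conc, bd$data$signal, s_fixed = 0.85)
  expect_equal(f2$Kd, 1.5, tolerance = 1e-6)
  expect_equal(f2$s, 0.85)
})

test_that("binding fit matches a grid search on noisy data", {
  bd <- make_binding_data(Kd = 1.5, s = 1, noise_cv = 0.05, seed = 9)
  fit <- binding_fit(bd$data$protein_conc, bd$data$signal)
  kds <- seq(0.5, 4, length.out = 400); ss <- seq(0.5, 1.5, length.out = 400)
  best <- c(Inf, NA, NA)
  for (kd_ in kds) for (s_ in ss) {
    sse <- sum((bd$data$signal -
                  s_ * bd$data$protein_conc / (kd_ + bd$data$protein_conc))^2)
    if (sse < best[1]) best <- c(sse, kd_, s_)
  }
  expect_lte(sum(residuals(fit$fit)^2), best[1] * 1.01)
  expect_equal(fit$Kd, best[2], tolerance = 0.01)
})
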