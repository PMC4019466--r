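# one deterministic quasi-uniform ball shared by the scattering tests
ball <- make_sphere_cloud(R = 20, n = 4000, method = "grid")
ball_xyz <- coords(ball$model)
ball_n <- nrow(ball_xyz)

test_that("profile container and text round trip", {
  p <- scattering_profile(c(0.01, 0.02), c(10, 5), c(1, 0.5))
  f <- withr::local_tempfile(fileext = ".dat")
  write_saxs_profile(p, f)
  p2 <- read_saxs_profile(f)
  expect_equal(p2$q, p$q)
  expect_equal(p2$intensity, p$intensity)
  expect_equal(p2$sigma, p$sigma)
  expect_error(scattering_profile(c(0.02, 0.01), c(1, 1)), "increasing")
  expect_error(scattering_profile(c(0.01, 0.02), c(1, 1), c(1, -1)), "sigma")
})

test_that("guinier recovers the generating Rg and applies the window rule", {
  gp <- make_guinier_profile(Rg = 23.40, q = seq(0.005, 0.1, length.out = 60))
  g <- guinier_fit(gp$profile)
  expect_equal(g$Rg, 23.40, tolerance = 1e-4)
  expect_equal(g$I0, 1, tolerance = 1e-6)
  expect_lt(g$qmax_rg, 1.3)
  # flat profile: Rg 0
  flat <- scattering_profile(seq(0.01, 0.1, 0.01), rep(2.5, 10))
  gf <- guinier_fit(flat)
  expect_equal(gf$Rg, 0)
  expect_equal(gf$I0, 2.5, tolerance = 1e-9)
  # rising profile: no Guinier region
  up <- scattering_profile(seq(0.01, 0.1, 0.01), seq(1, 2, length.out = 10))
  expect_error(guinier_fit(up), "no Guinier region")
})

test_that("debye closed forms: single point, two points, q->0 limit", {
  one <- matrix(0, 1, 3)
  p1 <- debye_profile(one, c(0, 0.1, 0.5))
  expect_equal(p1$intensity, rep(1, 3))
  d <- 7.3
  two <- rbind(c(0, 0, 0), c(d, 0, 0))
  q <- c(0, 0.05, 0.2, 0.5)
  p2 <- debye_profile(two, q, bin_width = 1e-4)
  want <- ifelse(q == 0, 4, 2 * (1 + sin(q * d) / (q * d)))
  expect_equal(p2$intensity, want, tolerance = 1e-4)
})

test_that("debye profile of a uniform ball matches the analytic form factor", {
  q <- seq(0.005, 4 / 20, length.out = 40)
  dp <- debye_profile(ball_xyz, q)
  rel <- abs(dp$intensity / ball_n^2 - sphere_form_factor(q * 20)) /
    sphere_form_factor(q * 20)
  expect_lt(max(rel), 0.03)
})

test_that("guinier Rg of a model's debye profile matches the coordinate Rg", {
  q <- seq(0.004, 0.08, length.out = 50)
  dp <- debye_profile(ball_xyz, q)
  g <- guinier_fit(dp)
  expect_equal(g$Rg, rg_from_coords(ball_xyz), tolerance = 0.02)
  expect_equal(g$Rg, sqrt(3 / 5) * 20, tolerance = 0.02)
})

test_that("P(r) reproduces Dmax and the second-moment Rg of the ball", {
  pr <- pr_from_structure(ball_xyz, r_bin = 0.5)
  expect_lte(pr$Dmax, 40)
  expect_equal(pr$Dmax, 40, tolerance = 0.05)
  expect_equal(pr$Rg_pr, sqrt(3 / 5) * 20, tolerance = 0.02)
  expect_true(all(pr$pr >= 0))
  expect_equal(pr$pr[1], 0)
  expect_equal(pr$pr[length(pr$pr)], 0)
  expect_equal(pr$I0_pr, ball_n^2)
  # two points at distance d
  d <- 5.5
  pr2 <- pr_from_structure(rbind(c(0, 0, 0), c(d, 0, 0)), r_bin = 0.25)
  expect_equal(pr2$Dmax, d)
  expect_error(pr_from_structure(matrix(0, 1, 3)), "degenerate")
})

test_that("P(r) and Guinier Rg of one synthetic model agree closely", {
  q <- seq(0.004, 0.04, length.out = 40)
  g <- guinier_fit(debye_profile(ball_xyz, q))
  pr <- pr_from_structure(ball_xyz, r_bin = 0.25)
  expect_equal(g$Rg, pr$Rg_pr, tolerance = 0.005)
})

test_that("porod volume recovers the ball volume and flags truncation", {
  q <- seq(0.004, 0.8, length.out = 400)
  dp <- debye_profile(ball_xyz, q)
  suppressWarnings(pv <- porod_volume(dp))
  expect_equal(pv$volume, 4 / 3 * pi * 20^3, tolerance = 0.15)
  expect_true(pv$reliable)
  # scale invariance: doubling I leaves the volume unchanged
  dp2 <- scattering_profile(dp$q, 2 * dp$intensity)
  suppressWarnings(pv2 <- porod_volume(dp2))
  expect_equal(pv2$volume, pv$volume, tolerance = 1e-9)
  # truncated profile (qmax*Rg < 2) is flagged unreliable
  short <- seq(0.004, 0.1, length.out = 40)
  expect_warning(pvs <- porod_volume(debye_profile(ball_xyz, short)),
                 "unreliable")
  expect_false(pvs$reliable)
})

test_that("chi2 scale factor matches a grid search and is scale invariant", {
  Ie <- c(10, 5, 2); Im <- c(9, 6, 2); s <- c(1, 1, 1)
  ep <- scattering_profile(c(0.01, 0.02, 0.03), Ie, s)
  mp <- scattering_profile(c(0.01, 0.02, 0.03), Im)
  fit <- chi2_fit(mp, ep)
  grid <- chi2_grid_c(Ie, Im, s, seq(0.5, 2, by = 1e-6))
  expect_equal(fit$c, grid$c, tolerance = 1e-5)
  expect_equal(fit$chi2, grid$chi2, tolerance = 1e-6)
  # identical curves: chi2 0, c 1
  f0 <- chi2_fit(scattering_profile(ep$q, Ie), ep)
  expect_equal(f0$chi2, 0, tolerance = 1e-12)
  expect_equal(f0$c, 1)
  # model twice the data: chi2 0 at c = 0.5
  f2 <- chi2_fit(scattering_profile(ep$q, 2 * Ie), ep)
  expect_equal(f2$chi2, 0, tolerance = 1e-12)
  expect_equal(f2$c, 0.5)
  # uniform model rescaling never changes chi2
  f3 <- chi2_fit(scattering_profile(ep$q, 7.3 * Im), ep)
  expect_equal(f3$chi2, fit$chi2, tolerance = 1e-9)
  expect_error(chi2_fit(mp, scattering_profile(ep$q, Ie)), "sigma")
  expect_error(chi2_fit(scattering_profile(c(1, 2), c(1, 1)), ep), "overlap")
})
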