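test_that("scattering_profile validates its fields", {
  expect_error(scattering_profile(c(0.1, 0.1), c(1, 1)), "ascending")
  expect_error(scattering_profile(c(0.1, 0.2), c(1, Inf)), "finite")
  expect_error(scattering_profile(c(0.1, 0.2), c(1, 1), sigma = c(1, 0)),
               "sigma")
})

test_that("Debye profile limits: single point and forward scattering", {
  q <- default_q_grid()
  p1 <- debye_profile(matrix(c(1, 2, 3), 1, 3), q, f = 2)
  expect_true(all(p1$intensity == 4))
  set.seed(6)
  xyz <- matrix(rnorm(60, sd = 10), 20, 3)
  p <- debye_profile(xyz, c(0, q), f = 1.5)
  expect_equal(p$intensity[1], (20 * 1.5)^2)  # I(0) = (N f)^2
})

test_that("Debye profile is invariant to rigid motion", {
  set.seed(7)
  xyz <- matrix(rnorm(90, sd = 8), 30, 3)
  p <- debye_profile(xyz, default_q_grid())
  moved <- sweep(xyz %*% t(random_rotation()), 2, c(30, -4, 12), "+")
  p2 <- debye_profile(moved, default_q_grid())
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-9)
})

test_that("Debye sphere profile matches the analytic form factor", {
  set.seed(101)
  R <- 30
  xyz <- sample_sphere_points(5000L, R)
  q <- seq(0.005, 4 / R, length.out = 40L)
  p <- debye_profile(xyz, q)
  ff <- p$intensity / nrow(xyz)^2
  oracle <- sphere_form_factor(q, R)
  # 1% agreement: in normalised units over the whole qR <= 4 range, and
  # point-by-point relative up to qR = 3 (beyond which the form factor
  # approaches its first zero and a finite point cloud cannot pin down
  # relative values)
  expect_lt(max(abs(ff - oracle)), 0.01)
  expect_lt(max((abs(ff - oracle) / oracle)[q * R <= 3]), 0.01)

  # Guinier radius of the same cloud: Rg = sqrt(3/5) R within 2%
  gu <- guinier_fit(p)
  expect_equal(gu$rg, sqrt(3 / 5) * R, tolerance = 0.02)
})

test_that("Guinier fit is exact on a Gaussian profile and scale-invariant", {
  q <- default_q_grid()
  rg <- 25; i0 <- 7.5
  prof <- scattering_profile(q, i0 * exp(-q^2 * rg^2 / 3))
  fit <- guinier_fit(prof)
  expect_equal(fit$rg, rg, tolerance = 1e-6)
  expect_equal(fit$i0, i0, tolerance = 1e-6)
  expect_lte(fit$q_range_used[2] * fit$rg, 1.3 + 1e-9)

  k <- 1e4
  fit_k <- guinier_fit(scattering_profile(q, k * prof$intensity))
  expect_equal(fit_k$rg, fit$rg, tolerance = 1e-9)
  expect_equal(fit_k$i0, k * fit$i0, tolerance = 1e-6)
})

test_that("Guinier fit rejects non-positive low-angle intensities", {
  q <- default_q_grid()
  I <- 5 * exp(-q^2 * 20^2 / 3)
  I[3] <- -0.1
  expect_error(guinier_fit(scattering_profile(q, I)), "non-positive")
  expect_error(guinier_fit(scattering_profile(q[1:4], I[1:4])), "points")
})

test_that("two-state fit recovers pure and mixed fractions exactly", {
  sim <- make_hinge_ensemble(n_residues_fixed = 60L,
                             n_residues_mobile = 60L,
                             angles_deg = c(0, 23.8), seed = 17)
  open_ch <- sim$chains[[1]]; closed_ch <- sim$chains[[2]]
  mx1 <- make_saxs_mixture(open_ch, closed_ch, w_open = 1, noise_cv = 0)
  expect_equal(mx1$profile$intensity, mx1$open_profile$intensity)
  fit1 <- two_state_fit(mx1$profile, mx1$open_profile, mx1$closed_profile)
  expect_equal(fit1$w_open, 1, tolerance = 1e-9)

  mx <- make_saxs_mixture(open_ch, closed_ch, w_open = 0.3, noise_cv = 0)
  fit <- two_state_fit(mx$profile, mx$open_profile, mx$closed_profile)
  expect_equal(fit$w_open, 0.3, tolerance = 1e-6)
  expect_equal(fit$w_open + fit$w_closed, 1, tolerance = 1e-9)
  expect_equal(fit$background, 0, tolerance = 1e-6)

  # mixture residual never exceeds either pure-state residual
  res_mix <- fit$chi2_reduced
  pure_open <- sum((mx$profile$intensity - mx$open_profile$intensity)^2)
  pure_closed <- sum((mx$profile$intensity -
                        mx$closed_profile$intensity)^2)
  expect_lte(res_mix * fit$n_points, min(pure_open, pure_closed))
})

test_that("identical basis profiles are rejected as degenerate", {
  q <- default_q_grid()
  p <- scattering_profile(q, exp(-q^2 * 100))
  expect_error(two_state_fit(p, p, p), "unidentifiable")
})

test_that("mixture fractions are recovered within 0.02 at 1% noise", {
  sim <- make_hinge_ensemble(angles_deg = c(0, 23.8), seed = 23)
  open_p <- debye_profile(sim$chains[[1]])
  closed_p <- debye_profile(sim$chains[[2]])
  w <- vapply(1:100, function(k) {
    mx <- make_saxs_mixture(sim$chains[[1]], sim$chains[[2]],
                            w_open = 0.5, noise_cv = 0.01, seed = k)
    two_state_fit(mx$profile, open_p, closed_p)$w_open
  }, numeric(1))
  # Monte-Carlo recovery: unbiased within the band, and the typical
  # single-curve error inside it too
  expect_lt(abs(mean(w) - 0.5), 0.02)
  expect_lt(stats::median(abs(w - 0.5)), 0.02)
  expect_lt(stats::sd(w), 0.02)
})

test_that("scattering text files round-trip through the SAS dialect", {
  q <- default_q_grid(n = 30L)
  prof <- scattering_profile(q, 100 * exp(-q^2 * 50), sigma = rep(0.5, 30),
                             label = "round trip")
  f <- withr::local_tempfile(fileext = ".dat")
  write_dat_profile(prof, f)
  back <- read_dat_profile(f)
  expect_equal(back$q, prof$q, tolerance = 1e-7)
  expect_equal(back$intensity, prof$intensity, tolerance = 1e-7)
  expect_equal(back$sigma, prof$sigma, tolerance = 1e-7)
})
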