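bpa_coeffs <- c(3.09e-2, 3.39e-4, -3.10e-8, 8.81e-13)

test_that("polynomial fit recovers exact cubic data to high precision", {
  t <- seq(0, 18000, by = 3600)
  y <- bpa_coeffs[1] + bpa_coeffs[2] * t + bpa_coeffs[3] * t^2 +
    bpa_coeffs[4] * t^3
  fit <- fit_h2o2_polynomial(t, y, order = 3)
  expect_equal(fit$coefficients, bpa_coeffs, tolerance = 1e-7)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  expect_equal(fit$t_max_s, 18000)
})

test_that("polynomial fit handles degenerate and invalid series", {
  t <- seq(0, 18000, by = 3600)
  fit <- fit_h2o2_polynomial(t, rep(0.7, length(t)), order = 3)
  expect_equal(fit$coefficients[1], 0.7, tolerance = 1e-12)
  expect_equal(fit$coefficients[-1], rep(0, 3), tolerance = 1e-12)
  expect_error(fit_h2o2_polynomial(c(0, 3600, 3600, 7200, 10800, 14400),
                                   runif(6), order = 3),
               "strictly increasing")
  expect_error(fit_h2o2_polynomial(t[1:4], runif(4), order = 3),
               "at least")
})

test_that("polynomial fit on noisy data stays within its standard errors", {
  t <- seq(0, 18000, by = 1800)
  truth <- bpa_coeffs[1] + bpa_coeffs[2] * t + bpa_coeffs[3] * t^2 +
    bpa_coeffs[4] * t^3
  set.seed(7)
  y <- truth * (1 + rnorm(length(t), sd = 0.05))
  fit <- fit_h2o2_polynomial(t, y, order = 3)
  expect_lt(fit$fit_r2, 1)
  expect_gt(fit$fit_r2, 0.9)
  # standard errors from the OLS design, computed independently in the
  # scaled-time frame (raw powers of t are too ill-conditioned to invert)
  tau <- t / max(t)
  X <- outer(tau, 0:3, `^`)
  b_tau <- fit$coefficients * max(t)^(0:3)
  res <- y - X %*% b_tau
  s2 <- sum(res^2) / (length(t) - 4)
  se_tau <- sqrt(diag(s2 * solve(crossprod(X))))
  expect_true(all(abs(b_tau - bpa_coeffs * max(t)^(0:3)) <= 3 * se_tau))
})

test_that("oh_star applies the proportionality with clamping and domain checks", {
  poly <- h2o2_poly(bpa_coeffs, t_max_s = 18000)
  prof <- oh_profile(poly, 1e-10, 1.31e-4)
  expect_equal(oh_star(prof, 0), 1e-10 * 3.09e-2)
  expect_error(oh_star(prof, 18001), "domain")
  expect_error(oh_star(prof, -1), "domain")
  # a polynomial that dips negative inside the domain is clamped to zero
  dip <- oh_profile(h2o2_poly(c(-0.5, 1e-4), t_max_s = 10000), 2, 1e-4)
  expect_equal(oh_star(dip, 0), 0)
  expect_gt(oh_star(dip, 10000), 0)
  zero <- oh_profile(h2o2_poly(0, t_max_s = 100), 5, 1e-4)
  expect_equal(oh_star(zero, 50), 0)
})

test_that("oh_exposure computes the closed-form clamped integral", {
  poly <- h2o2_poly(bpa_coeffs, t_max_s = 18000)
  prof <- oh_profile(poly, 1e-10, 1.31e-4)
  expect_equal(oh_exposure(prof, 0, 18000), 2.40e-10, tolerance = 1e-3)
  expect_identical(oh_exposure(prof, 5000, 5000), 0)
  # additivity over subintervals
  expect_equal(oh_exposure(prof, 0, 7000) + oh_exposure(prof, 7000, 18000),
               oh_exposure(prof, 0, 18000), tolerance = 1e-12)
  expect_error(oh_exposure(prof, 0, 19000), "domain")
})

test_that("oh_exposure equals numerical quadrature on random polynomials", {
  set.seed(23)
  for (i in 1:10) {
    poly <- random_poly()
    if (i %% 3 == 0)   # force a sign change inside the domain
      poly <- h2o2_poly(c(-0.2, poly$coefficients[-1]), t_max_s = 18000)
    prof <- oh_profile(poly, 10^runif(1, -11, -9), 1.31e-4)
    # independent quadrature: locate the clamp kinks by sign-change scan +
    # bisection, then integrate each smooth piece (integrate() straddling a
    # kink is inaccurate, so the pieces are the oracle)
    f <- function(t) oh_star(prof, t) * prof$reference_conc
    raw <- function(t) {
      cf <- poly$coefficients
      cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3
    }
    grid <- seq(0, 18000, length.out = 2001)
    sgn <- sign(raw(grid))
    idx <- which(diff(sgn) != 0)
    kinks <- vapply(idx, function(k)
      stats::uniroot(raw, c(grid[k], grid[k + 1]), tol = 1e-10)$root,
      numeric(1))
    pts <- c(0, kinks, 18000)
    quad <- sum(vapply(seq_len(length(pts) - 1), function(k)
      stats::integrate(f, pts[k], pts[k + 1], rel.tol = 1e-12)$value,
      numeric(1)))
    u <- oh_exposure(prof, 0, 18000)
    expect_equal(u, quad, tolerance = 1e-9)
  }
})

test_that("the current-density law reproduces calibrated factors", {
  law <- current_density_law(slope = 6.48e-12, intercept = 8.55e-12)
  expect_equal(signif(k_of_j(law, 20), 3), 1.38e-10)
  expect_equal(signif(k_of_j(law, 15), 3), 1.06e-10)
  expect_equal(k_of_j(law, 0), 8.55e-12)
  # strictly increasing in j for a positive slope
  j <- seq(1, 25, by = 0.5)
  expect_true(all(diff(k_of_j(law, j)) > 0))
})

test_that("fit_current_law recovers lines and reports R^2", {
  truth <- current_density_law(6.48e-12, 8.55e-12)
  j2 <- c(5, 20)
  fit2 <- fit_current_law(j2, k_of_j(truth, j2))
  expect_equal(fit2$slope, 6.48e-12, tolerance = 1e-10)
  expect_equal(fit2$intercept, 8.55e-12, tolerance = 1e-10)
  j <- c(2.5, 5, 10, 15, 20)
  fitp <- fit_current_law(j, k_of_j(truth, j))
  expect_equal(fitp$fit_r2, 1, tolerance = 1e-10)
  set.seed(5)
  kn <- k_of_j(truth, j) * (1 + rnorm(5, sd = 0.03))
  fitn <- fit_current_law(j, kn)
  se_slope <- summary(stats::lm(kn ~ j))$coefficients[2, 2]
  expect_lt(abs(fitn$slope - 6.48e-12), 3 * se_slope)
  expect_error(fit_current_law(c(5, 5, 5), c(1, 2, 3) * 1e-11),
               "identical")
})
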