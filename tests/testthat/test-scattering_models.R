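# Closed-form scattering laws against independently computed oracles.

test_that("Lorentzian density has the textbook peak, half-width and norm", {
  expect_equal(lorentzian_density(0, 0.1), 1 / (0.1 * pi), tolerance = 1e-12)
  # half maximum at omega = Gamma, by definition of the HWHM
  for (g in c(0.01, 0.3, 2)) {
    expect_equal(lorentzian_density(g, g), lorentzian_density(0, g) / 2)
    expect_equal(lorentzian_density(-g, g), lorentzian_density(g, g))
  }
  # numeric integral over +/-50 Gamma against the closed arctan form
  g <- 0.2
  om <- seq(-50 * g, 50 * g, length.out = 200001)
  num <- sum(lorentzian_density(om, g)) * (om[2] - om[1])
  expect_equal(num, 2 / pi * atan(50), tolerance = 1e-6)
  expect_equal(num, 0.9872693, tolerance = 1e-5)
  # quadrature matches the analytic tail fraction out to +/-500 Gamma
  om <- seq(-500 * g, 500 * g, length.out = 400001)
  num <- sum(lorentzian_density(om, g)) * (om[2] - om[1])
  expect_equal(num, 2 / pi * atan(500), tolerance = 1e-6)
  expect_error(lorentzian_density(0, 0), "positive")
  expect_error(lorentzian_density(0, -1), "positive")
})

test_that("jump-diffusion width rises as D_T Q^2 and saturates at hbar/tau0", {
  jd <- jump_diffusion_params(0.117, 3.3)
  expect_equal(jump_diffusion_hwhm(jd, 0), 0)
  expect_equal(jump_diffusion_hwhm(jd, 1), 0.0555593, tolerance = 1e-5)
  q <- seq(0, 12, by = 0.1)
  g <- jump_diffusion_hwhm(jd, q)
  expect_true(all(diff(g) > 0))                      # strictly increasing
  expect_true(all(g <= hbar_mev_ps / 3.3 + 1e-12))   # bounded by asymptote
  expect_equal(jump_diffusion_hwhm(jd, 1e4), hbar_mev_ps / 3.3,
               tolerance = 1e-4)
  expect_error(jump_diffusion_params(-1, 3), "d_t")
  expect_error(jump_diffusion_params(0.1, -1), "tau0")
})

test_that("Brownian width is the tau0 = 0 jump-diffusion limit", {
  expect_equal(brownian_hwhm(0.117, 0), 0)
  expect_equal(brownian_hwhm(0.117, 1), 0.0770108, tolerance = 1e-5)
  jd0 <- jump_diffusion_params(0.2, 0)
  q <- seq(0, 3, by = 0.25)
  expect_equal(brownian_hwhm(0.2, q), jump_diffusion_hwhm(jd0, q))
})

test_that("sphere EISF matches the Bessel oracle, bounds and first zero", {
  expect_equal(sphere_eisf(2, 0), 1)
  expect_equal(sphere_eisf(1, 1), 0.8163232, tolerance = 1e-6)
  expect_equal(sphere_eisf(2.11, 1 / 2.11), 0.8163232, tolerance = 1e-6)
  # first zero of j1 at x = 4.493409 (root-finding oracle)
  expect_lt(sphere_eisf(1, 4.493409), 1e-10)
  x <- seq(0, 8, by = 0.01)
  y <- sphere_eisf(1, x)
  expect_true(all(y >= 0 & y <= 1))
  # monotone decreasing up to the first zero
  ix <- x <= 4.4934
  expect_true(all(diff(y[ix]) <= 0))
})

test_that("immobile fraction shifts the EISF floor from 0 to p", {
  q <- seq(0, 6, by = 0.05)
  expect_equal(eisf_with_immobile(confined_rotation_params(1, 2, 0.1), q),
               rep(1, length(q)))
  p0 <- confined_rotation_params(0, 2, 0.1)
  expect_equal(eisf_with_immobile(p0, q), sphere_eisf(2, q))
  ph <- confined_rotation_params(0.5, 1, 0.1)
  expect_equal(eisf_with_immobile(ph, 1), 0.9081616, tolerance = 1e-6)
  a <- eisf_with_immobile(ph, q)
  expect_true(all(a >= 0.5 & a <= 1))
  expect_equal(eisf_with_immobile(ph, 500), 0.5, tolerance = 1e-4)
  expect_error(confined_rotation_params(1.2, 2, 0.1), "p must")
})

test_that("rotational multipole widths follow D_R l(l+1)", {
  expect_equal(rotational_hwhm(confined_rotation_params(0.3, 2, 0.24), 1L),
               0.48)
  expect_equal(rotational_hwhm(confined_rotation_params(0.3, 2, 0.1), 2L),
               0.6)
  expect_equal(rotational_hwhm(confined_rotation_params(0.3, 2, 0), 5L), 0)
  expect_error(rotational_hwhm(confined_rotation_params(0.3, 2, 0.1), 0L),
               "integer")
})

test_that("composite model evaluates to DW-damped elastic + Lorentzians + line", {
  om <- seq(-4, 4, by = 0.004)
  step <- om[2] - om[1]
  shape <- exp(-om^2 / (2 * 0.03^2))
  shape <- shape / (sum(shape) * step)
  # pure elastic: scaled resolution shape
  m0 <- composite_spectrum_model(q = 1, u2 = 0, elastic_amplitude = 2)
  expect_equal(evaluate_composite(m0, om, shape), 2 * shape)
  # u2 = 0 leaves no damping; u2 > 0 damps by exp(-u2 q^2 / 3)
  m1 <- composite_spectrum_model(q = 1.5, u2 = 0.9, elastic_amplitude = 2)
  expect_equal(evaluate_composite(m1, om, shape),
               exp(-0.9 * 1.5^2 / 3) * 2 * shape)
  # grid integral against the trapezoid oracle: DW * (A0 + sum A_i) + bg
  m2 <- composite_spectrum_model(
    q = 1, u2 = 0.5, elastic_amplitude = 1,
    lorentzians = list(lorentzian_component(0.02, 0.6),
                       lorentzian_component(0.08, 0.4)),
    bg_slope = 0.01, bg_intercept = 0.05)
  y <- evaluate_composite(m2, om, shape)
  got <- sum((y[-1] + y[-length(y)]) / 2) * step
  tail_frac <- mean(2 / pi * atan(4 / c(0.02, 0.08)))  # truncated Lorentzian mass
  want <- exp(-0.5 / 3) * (1 + (0.6 + 0.4) * tail_frac) + 0.05 * 8
  expect_equal(got, want, tolerance = 0.01)
  expect_error(evaluate_composite(m2, c(0, 0.1, 0.15), shape[1:3]), "uniform")
})

test_that("composite with one Brownian Lorentzian is the free-diffusion law", {
  om <- seq(-2, 2, by = 0.002)
  d_t <- 0.117; qv <- 1.2
  g <- brownian_hwhm(d_t, qv)
  m <- composite_spectrum_model(
    q = qv, u2 = 0, elastic_amplitude = 0,
    lorentzians = list(lorentzian_component(g, 1)))
  shape <- rep(0, length(om)); shape[1001] <- 1 / 0.002
  y <- evaluate_composite(m, om, shape)
  expect_equal(y, lorentzian_density(om, hbar_mev_ps * d_t * qv^2))
})

test_that("resolution convolution preserves norm and satisfies closures", {
  om <- seq(-3, 3, by = 0.003)
  step <- om[2] - om[1]
  n <- length(om)
  # identity under a discrete unit impulse
  imp <- rep(0, n); imp[(n + 1) / 2] <- 1 / step
  y <- lorentzian_density(om, 0.05)
  expect_equal(convolve_resolution(y, imp, step), y, tolerance = 1e-10)
  # Lorentzian closure: L(G1) (x) L(G2) = L(G1 + G2)
  l1 <- lorentzian_density(om, 0.04)
  l2 <- lorentzian_density(om, 0.07)
  got <- convolve_resolution(l1, l2, step)
  want <- lorentzian_density(om, 0.11)
  mid <- abs(om) < 1.5   # away from truncation edges
  expect_equal(got[mid], want[mid], tolerance = 0.02)
  # Gaussian closure: sigma adds in quadrature
  g1 <- stats::dnorm(om, 0, 0.05); g2 <- stats::dnorm(om, 0, 0.12)
  got <- convolve_resolution(g1, g2, step)
  want <- stats::dnorm(om, 0, sqrt(0.05^2 + 0.12^2))
  expect_equal(got[mid], want[mid], tolerance = 1e-6)
  # commutative and linear
  expect_equal(convolve_resolution(l1, g1, step),
               convolve_resolution(g1 / (sum(g1) * step),
                                   l1 / (sum(l1) * step), step) *
                 (sum(l1) * step) / 1,
               tolerance = 1e-10)
  a <- convolve_resolution(l1 + 2 * l2, g1, step)
  b <- convolve_resolution(l1, g1, step) + 2 * convolve_resolution(l2, g1, step)
  expect_equal(a, b, tolerance = 1e-10)
  # total intensity preserved to quadrature tolerance
  expect_equal(sum(convolve_resolution(g2, g1, step)) * step,
               sum(g2) * step, tolerance = 1e-3)
  expect_error(convolve_resolution(y, imp[-1], step), "share")
})
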