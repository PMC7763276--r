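# Closed-form scattering laws and spectral building blocks shared by the
# synthetic generators and the fitting pipeline.  All pure functions.

#' Jump-diffusion parameters
#'
#' Translational jump diffusion: atoms oscillate around an equilibrium site
#' for an average residence time `tau0`, then undergo continuous diffusion
#' with coefficient `d_t`.  The quasi-elastic linewidth rises as
#' `D_T Q^2` at small Q and saturates at `hbar/tau0` at large Q.
#'
#' @param d_t Translational diffusion coefficient, Angstrom^2/ps. Must be > 0.
#' @param tau0 Mean residence time, ps. Must be >= 0; `tau0 = 0` recovers
#'   simple Brownian diffusion.
#' @return An object of class `"jump_diffusion_params"`.
#' @export
#' @examples
#' jd <- jump_diffusion_params(d_t = 0.117, tau0 = 3.3)  # D2O buffer at 310 K
#' jump_diffusion_hwhm(jd, q = 1)
jump_diffusion_params <- function(d_t, tau0) {
  stopifnot(is.numeric(d_t), length(d_t) == 1L, is.finite(d_t),
            is.numeric(tau0), length(tau0) == 1L, is.finite(tau0))
  if (d_t <= 0) stop("d_t must be > 0")
  if (tau0 < 0) stop("tau0 must be >= 0")
  structure(list(d_t = d_t, tau0 = tau0), class = "jump_diffusion_params")
}

#' Confined-rotation parameters
#'
#' Rotational diffusion restricted to a sphere of radius `r` with rate
#' constant `d_r` (expressed in energy units), plus an immobile fraction `p`
#' of scatterers whose motion is unresolved within the instrument window.
#'
#' @param p Immobile fraction, in \[0, 1\].
#' @param r Confinement sphere radius, Angstrom. Must be > 0.
#' @param d_r Rotational rate constant, meV. Must be >= 0.  The l-th
#'   multipole line has HWHM `d_r * l * (l + 1)`; the single-Lorentzian
#'   approximation used for fitting takes the l = 1 width `2 * d_r`.
#' @return An object of class `"confined_rotation_params"`.
#' @export
confined_rotation_params <- function(p, r, d_r) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(r), length(r) == 1L,
            is.numeric(d_r), length(d_r) == 1L)
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (r <= 0) stop("r must be > 0")
  if (d_r < 0) stop("d_r must be >= 0")
  structure(list(p = p, r = r, d_r = d_r), class = "confined_rotation_params")
}

#' Lorentzian component of a quasi-elastic spectrum
#'
#' @param hwhm Half width at half maximum, meV. Must be > 0.
#' @param amplitude Integrated weight, intensity units. Must be >= 0.
#' @return An object of class `"lorentzian_component"`.
#' @export
lorentzian_component <- function(hwhm, amplitude) {
  if (!is.numeric(hwhm) || hwhm <= 0) stop("hwhm must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  structure(list(hwhm = hwhm, amplitude = amplitude),
            class = "lorentzian_component")
}

#' Composite quasi-elastic spectrum model at one Q
#'
#' Debye-Waller-damped sum of a resolution-shaped elastic line and a set of
#' Lorentzian quasi-elastic components, on top of a linear background:
#' `I(w) = exp(-u2 Q^2 / 3) * [A0 * R(w) + sum_i A_i * L(G_i, w)] + a*w + b`.
#'
#' @param q Momentum transfer, 1/Angstrom.
#' @param u2 Mean square displacement entering the Debye-Waller factor,
#'   Angstrom^2. Must be >= 0.
#' @param elastic_amplitude Elastic weight A0, intensity units. Must be >= 0.
#' @param lorentzians List of [lorentzian_component()] objects (may be empty).
#' @param bg_slope,bg_intercept Linear background, intensity/meV and
#'   intensity units.
#' @return An object of class `"composite_spectrum_model"`.
#' @export
composite_spectrum_model <- function(q, u2 = 0, elastic_amplitude = 0,
                                     lorentzians = list(),
                                     bg_slope = 0, bg_intercept = 0) {
  if (u2 < 0) stop("u2 must be >= 0")
  if (elastic_amplitude < 0) stop("elastic_amplitude must be >= 0")
  stopifnot(is.list(lorentzians))
  for (l in lorentzians) {
    if (!inherits(l, "lorentzian_component"))
      stop("lorentzians must be a list of lorentzian_component objects")
  }
  structure(list(q = q, u2 = u2, elastic_amplitude = elastic_amplitude,
                 lorentzians = lorentzians, bg_slope = bg_slope,
                 bg_intercept = bg_intercept),
            class = "composite_spectrum_model")
}

#' Normalized Lorentzian spectral density
#'
#' `L(G, w) = (1/pi) G / (w^2 + G^2)`, unit-normalized over the whole energy
#' axis and symmetric in `w`.
#'
#' @param omega Energy transfer, meV (vectorized).
#' @param hwhm Half width at half maximum Gamma, meV. Must be > 0.
#' @return Spectral density, 1/meV.
#' @export
#' @examples
#' lorentzian_density(0, 0.1)      # peak value 1 / (pi * 0.1)
lorentzian_density <- function(omega, hwhm) {
  if (!is.numeric(hwhm) || length(hwhm) != 1L || !is.finite(hwhm) || hwhm <= 0)
    stop("hwhm must be a single positive number")
  (hwhm / pi) / (omega^2 + hwhm^2)
}

#' Jump-diffusion quasi-elastic linewidth
#'
#' `Gamma_JD(Q) = hbar * D_T Q^2 / (1 + D_T Q^2 tau0)` in meV.  Increases
#' monotonically in Q and saturates at the asymptote `hbar / tau0`.
#'
#' @param params A [jump_diffusion_params()] object.
#' @param q Momentum transfer, 1/Angstrom (vectorized). Must be >= 0.
#' @return HWHM in meV.
#' @export
jump_diffusion_hwhm <- function(params, q) {
  stopifnot(inherits(params, "jump_diffusion_params"))
  if (any(q < 0)) stop("q must be >= 0")
  x <- params$d_t * q^2
  hbar_mev_ps * x / (1 + x * params$tau0)
}

#' Brownian (free translational diffusion) linewidth
#'
#' `Gamma_B(Q) = hbar * D_T Q^2` in meV; the `tau0 = 0` limit of
#' [jump_diffusion_hwhm()].
#'
#' @param d_t Translational diffusion coefficient, Angstrom^2/ps.
#' @param q Momentum transfer, 1/Angstrom (vectorized). Must be >= 0.
#' @return HWHM in meV.
#' @export
brownian_hwhm <- function(d_t, q) {
  if (d_t <= 0) stop("d_t must be > 0")
  if (any(q < 0)) stop("q must be >= 0")
  hbar_mev_ps * d_t * q^2
}

# First-order spherical Bessel function j1(x) = sin(x)/x^2 - cos(x)/x,
# with the small-x series to avoid cancellation near 0.
spherical_j1 <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 30
  xl <- x[!small]
  out[!small] <- sin(xl) / xl^2 - cos(xl) / xl
  out
}

#' Elastic incoherent structure factor of diffusion in a sphere
#'
#' Volino-Dianoux EISF for isotropic diffusion confined to a sphere of
#' radius `r`: `A0(QR) = (3 j1(QR) / (QR))^2`, with the analytic value 1 at
#' Q = 0.
#'
#' @param r Confinement radius, Angstrom. Must be > 0.
#' @param q Momentum transfer, 1/Angstrom (vectorized). Must be >= 0.
#' @return Dimensionless fraction in \[0, 1\].
#' @export
#' @examples
#' sphere_eisf(r = 2.11, q = seq(0, 2, by = 0.2))
sphere_eisf <- function(r, q) {
  if (r <= 0) stop("r must be > 0")
  if (any(q < 0)) stop("q must be >= 0")
  x <- q * r
  y <- ifelse(x == 0, 1, (3 * spherical_j1(x) / ifelse(x == 0, 1, x))^2)
  pmin(pmax(y, 0), 1)
}

#' EISF of confined rotation with an immobile fraction
#'
#' `A0(Q) = p + (1 - p) * (3 j1(QR) / QR)^2`: a fraction `p` of scatterers
#' is strongly bound (elastic within the instrument window), the remainder
#' diffuses within a sphere of radius `r`.  Tends to `p` as Q grows.
#'
#' @param params A [confined_rotation_params()] object.
#' @param q Momentum transfer, 1/Angstrom (vectorized).
#' @return Dimensionless fraction in \[p, 1\].
#' @export
eisf_with_immobile <- function(params, q) {
  stopifnot(inherits(params, "confined_rotation_params"))
  params$p + (1 - params$p) * sphere_eisf(params$r, q)
}

#' Multipole linewidth of rotational diffusion in a sphere
#'
#' `Gamma_l = d_r * l * (l + 1)` in meV.  The fitting pipeline uses only the
#' l = 1 term, `Gamma_R = 2 d_r`, as a single Q-independent broad Lorentzian.
#'
#' @param params A [confined_rotation_params()] object.
#' @param l Multipole index, integer >= 1.
#' @return HWHM in meV.
#' @export
rotational_hwhm <- function(params, l = 1L) {
  stopifnot(inherits(params, "confined_rotation_params"))
  if (any(l < 1) || any(l != round(l))) stop("l must be an integer >= 1")
  params$d_r * l * (l + 1)
}

# uniform-grid check shared by evaluate/convolve
assert_uniform_grid <- function(omega_grid) {
  if (length(omega_grid) < 2L) stop("omega grid too short")
  d <- diff(omega_grid)
  if (any(d <= 0) || (max(d) - min(d)) > 1e-8 * max(abs(d)))
    stop("omega grid must be uniform and increasing")
  mean(d)
}

#' Evaluate a composite spectrum model on an energy grid
#'
#' The elastic delta function is represented by the supplied normalized
#' resolution lineshape (standard QENS practice); quasi-elastic components
#' are analytic Lorentzians, not yet resolution-broadened.
#'
#' @param model A [composite_spectrum_model()] object.
#' @param omega_grid Uniform energy grid, meV.
#' @param elastic_shape Resolution-shaped density on `omega_grid`,
#'   unit-normalized (`sum(elastic_shape) * step == 1`).
#' @return Intensity values on the grid.
#' @export
evaluate_composite <- function(model, omega_grid, elastic_shape) {
  stopifnot(inherits(model, "composite_spectrum_model"))
  assert_uniform_grid(omega_grid)
  if (length(elastic_shape) != length(omega_grid))
    stop("elastic_shape must match omega_grid")
  dw <- exp(-model$u2 * model$q^2 / 3)
  y <- model$elastic_amplitude * elastic_shape
  for (l in model$lorentzians)
    y <- y + l$amplitude * lorentzian_density(omega_grid, l$hwhm)
  dw * y + model$bg_slope * omega_grid + model$bg_intercept
}

#' Convolve a model spectrum with an instrument resolution lineshape
#'
#' Discrete linear convolution on a shared uniform grid, truncated to the
#' data support (output has the same length as the input).  The resolution
#' is renormalized to unit integral so the total intensity is preserved to
#' quadrature accuracy; its center is taken at its intensity centroid.
#'
#' @param model_values Intensity values on the grid.
#' @param resolution_values Resolution density on the same grid.
#' @param omega_step Grid spacing, meV.
#' @return Convolved intensity values, same length as `model_values`.
#' @export
convolve_resolution <- function(model_values, resolution_values, omega_step) {
  n <- length(model_values)
  if (length(resolution_values) != n)
    stop("model and resolution must share one grid")
  if (!is.numeric(omega_step) || omega_step <= 0)
    stop("omega_step must be > 0")
  r <- resolution_values / (sum(resolution_values) * omega_step)
  i0 <- round(sum(seq_len(n) * r) / sum(r))
  i0 <- min(max(i0, 1L), n)
  full <- stats::convolve(model_values, rev(r), type = "open")
  full[seq_len(n) + i0 - 1L] * omega_step
}
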