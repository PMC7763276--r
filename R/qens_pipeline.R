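# QENS workflow: spectra container, data correction (empty-cell/buffer
# subtraction, buffer interpolation, vanadium normalization), buffer and
# constrained sample fitting, EISF extraction, transport parameters.

#' Per-Q quasi-elastic spectra container
#'
#' Energy spectra `S(Q, omega)` with uncertainties for one measurement role:
#' sample, buffer, empty cell or vanadium standard.
#'
#' @param role One of `"sample"`, `"buffer"`, `"empty"`, `"vanadium"`.
#' @param q_list Momentum transfers, 1/Angstrom.
#' @param omega_grid Uniform energy grid, meV.
#' @param counts Intensity matrix, `length(q_list) x length(omega_grid)`,
#'   non-negative.
#' @param errors Matching matrix of one-sigma uncertainties.
#' @param concentration Co-solute concentration, wt percent.
#' @param temperature Sample temperature, K.
#' @return An object of class `"qens_spectra"`.
#' @export
qens_spectra <- function(role, q_list, omega_grid, counts, errors,
                         concentration = 0, temperature = 310) {
  role <- match.arg(role, c("sample", "buffer", "empty", "vanadium"))
  q_list <- as.numeric(q_list)
  counts <- as.matrix(counts); errors <- as.matrix(errors)
  assert_uniform_grid(omega_grid)
  if (!all(dim(counts) == c(length(q_list), length(omega_grid))))
    stop("counts must be length(q_list) x length(omega_grid)")
  if (!all(dim(errors) == dim(counts))) stop("errors must match counts")
  if (any(counts < -1e-9)) stop("counts must be >= 0")
  structure(list(role = role, q_list = q_list, omega_grid = omega_grid,
                 counts = counts, errors = errors,
                 concentration = concentration, temperature = temperature),
            class = "qens_spectra")
}

#' @export
print.qens_spectra <- function(x, ...) {
  cat(sprintf(
    "<qens_spectra> role=%s, %g wt%%, T=%g K: %d Q in [%.2f, %.2f] 1/A, %d energy bins in [%.3g, %.3g] meV\n",
    x$role, x$concentration, x$temperature, length(x$q_list), min(x$q_list),
    max(x$q_list), length(x$omega_grid), min(x$omega_grid), max(x$omega_grid)))
  invisible(x)
}

assert_same_grids <- function(a, b) {
  if (length(a$q_list) != length(b$q_list) ||
      max(abs(a$q_list - b$q_list)) > 1e-9 ||
      length(a$omega_grid) != length(b$omega_grid) ||
      max(abs(a$omega_grid - b$omega_grid)) > 1e-9)
    stop("spectra grids do not match")
  invisible(TRUE)
}

#' Empty-cell and buffer subtraction
#'
#' `counts_out = sample - empty - buffer_fraction * buffer`, with errors
#' propagated in quadrature.  Bins driven negative by counting noise are
#' clipped to zero; their number is recorded in attribute `"n_clipped"`.
#'
#' @param sample,empty,buffer [qens_spectra()] on identical grids.
#' @param buffer_fraction Scale applied to the buffer before subtraction
#'   (0 disables buffer subtraction, as when the buffer is instead kept as
#'   a fixed-shape component of the sample fit).
#' @return A corrected [qens_spectra()] with role `"sample"`.
#' @export
subtract_background_spectra <- function(sample, empty, buffer,
                                        buffer_fraction = 0) {
  stopifnot(inherits(sample, "qens_spectra"))
  assert_same_grids(sample, empty)
  assert_same_grids(sample, buffer)
  cts <- sample$counts - empty$counts - buffer_fraction * buffer$counts
  err <- sqrt(sample$errors^2 + empty$errors^2 +
                (buffer_fraction * buffer$errors)^2)
  n_clip <- sum(cts < 0)
  cts[cts < 0] <- 0
  out <- qens_spectra("sample", sample$q_list, sample$omega_grid, cts, err,
                      sample$concentration, sample$temperature)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Interpolate buffer spectra between two measured concentrations
#'
#' Linear bin-by-bin interpolation between buffers measured at 0 and 15 wt
#' percent, for samples at intermediate concentrations.
#'
#' @param buf0,buf15 [qens_spectra()] measured at 0 and 15 wt percent, on
#'   identical grids.
#' @param wt Target concentration, wt percent, in \[0, 15\].
#' @return Interpolated buffer [qens_spectra()].
#' @export
interpolate_buffer <- function(buf0, buf15, wt) {
  assert_same_grids(buf0, buf15)
  if (wt < 0 || wt > 15) stop("wt must be in [0, 15]")
  w <- wt / 15
  cts <- (1 - w) * buf0$counts + w * buf15$counts
  err <- sqrt(((1 - w) * buf0$errors)^2 + (w * buf15$errors)^2)
  qens_spectra("buffer", buf0$q_list, buf0$omega_grid, cts, err,
               concentration = wt, temperature = buf0$temperature)
}

#' Vanadium normalization and resolution extraction
#'
#' Divides each Q's spectrum by the integrated vanadium intensity at that Q
#' (relative detector efficiency) and returns the unit-normalized vanadium
#' lineshape per Q as the instrumental resolution `S_res(Q, omega)`.
#'
#' @param spectra [qens_spectra()] to normalize.
#' @param vanadium Vanadium-standard [qens_spectra()] on the same grids.
#' @return List with `spectra` (normalized [qens_spectra()]) and
#'   `resolution` (matrix `n_Q x n_omega`, each row unit-normalized).
#' @export
normalize_vanadium <- function(spectra, vanadium) {
  assert_same_grids(spectra, vanadium)
  step <- assert_uniform_grid(spectra$omega_grid)
  vint <- rowSums(vanadium$counts) * step
  if (any(vint <= 0)) stop("zero vanadium integral at some Q")
  cts <- sweep(spectra$counts, 1, vint, "/")
  err <- sweep(spectra$errors, 1, vint, "/")
  res <- sweep(vanadium$counts, 1, vint, "/")
  list(spectra = qens_spectra(spectra$role, spectra$q_list,
                              spectra$omega_grid, cts, err,
                              spectra$concentration, spectra$temperature),
       resolution = res)
}

# Fast same-support convolution with a fixed kernel: precompute the padded
# kernel FFT once per Q, reuse across optimizer iterations.
make_convolver <- function(resolution_values, omega_step) {
  n <- length(resolution_values)
  r <- resolution_values / (sum(resolution_values) * omega_step)
  i0 <- min(max(round(sum(seq_len(n) * r) / sum(r)), 1L), n)
  m <- stats::nextn(2L * n - 1L, 2)
  rf <- stats::fft(c(r, rep(0, m - n)))
  idx <- seq_len(n) + i0 - 1L
  function(y) {
    yf <- stats::fft(c(y, rep(0, m - length(y))))
    full <- Re(stats::fft(yf * rf, inverse = TRUE)) / m
    full[idx] * omega_step
  }
}

# Levenberg-Marquardt wrapper: weighted residuals, box bounds, deterministic
# multi-start (all starts tried, best deviance kept; an essentially exact
# fit short-circuits the remaining starts).
lm_multistart <- function(resid_fn, starts, lower, upper, nobs = NULL) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < 1e-9) break
  }
  best
}

lm_std_errors <- function(fit) {
  p <- length(fit$par)
  dof <- max(length(fit$fvec) - p, 1L)
  se <- tryCatch({
    cv <- solve(fit$hessian) * fit$deviance / dof
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) rep(NA_real_, p))
  stats::setNames(se, names(fit$par))
}

weighted_mean_se <- function(x, sigma) {
  ok <- is.finite(x) & is.finite(sigma) & sigma > 0
  if (!any(ok)) return(c(mean = mean(x, na.rm = TRUE), se = NA_real_))
  w <- 1 / sigma[ok]^2
  m <- sum(w * x[ok]) / sum(w)
  # combine the propagated error with the observed scatter, whichever larger
  se_prop <- sqrt(1 / sum(w))
  se_obs <- if (sum(ok) > 1)
    sqrt(sum(w * (x[ok] - m)^2) / sum(w) / (sum(ok) - 1)) else 0
  c(mean = m, se = max(se_prop, se_obs))
}

#' Fit the jump-diffusion law to quasi-elastic linewidths
#'
#' Weighted nonlinear least squares of
#' `Gamma(Q) = hbar * D_T Q^2 / (1 + D_T Q^2 tau0)` to measured narrow-line
#' HWHM values, optionally excluding a Q^2 window (e.g. around a coherent
#' "de Gennes narrowing" dip).
#'
#' @param q Momentum transfers, 1/Angstrom.
#' @param hwhm Measured HWHM, meV.
#' @param errors One-sigma uncertainties on `hwhm` (NA/zero treated as equal
#'   weights).
#' @param exclude_q2 Optional `c(lo, hi)` window in Q^2 (1/Angstrom^2) to
#'   drop before fitting.
#' @return List with `d_t`, `d_t_error` (Angstrom^2/ps), `tau0`,
#'   `tau0_error` (ps) and `n_used`.
#' @export
fit_jump_diffusion <- function(q, hwhm, errors = NULL, exclude_q2 = NULL) {
  keep <- is.finite(q) & is.finite(hwhm) & hwhm > 0
  if (!is.null(exclude_q2))
    keep <- keep & !(q^2 >= exclude_q2[1] & q^2 <= exclude_q2[2])
  if (sum(keep) < 4L) stop("fewer than 4 usable Q points")
  q <- q[keep]; hwhm <- hwhm[keep]
  sig <- if (is.null(errors)) rep(1, length(q)) else errors[keep]
  sig[!is.finite(sig) | sig <= 0] <- stats::median(sig[is.finite(sig) & sig > 0],
                                                   na.rm = TRUE)
  if (all(!is.finite(sig))) sig <- rep(1, length(q))
  d0 <- min(max(hwhm[which.min(q)] / (hbar_mev_ps * min(q)^2), 1e-3), 4)
  t0 <- min(max(hbar_mev_ps / max(hwhm), 0.01), 50)
  resid_fn <- function(p) {
    g <- hbar_mev_ps * p[1] * q^2 / (1 + p[1] * q^2 * p[2])
    (g - hwhm) / sig
  }
  starts <- list(c(d_t = d0, tau0 = t0),
                 c(d_t = d0 * 2, tau0 = t0 / 3),
                 c(d_t = d0 / 2, tau0 = t0 * 3))
  fit <- lm_multistart(resid_fn, starts, lower = c(1e-5, 0),
                       upper = c(5, 100), nobs = length(q))
  if (is.null(fit)) stop("jump-diffusion fit failed to converge")
  se <- lm_std_errors(fit)
  list(d_t = fit$par[[1]], d_t_error = se[[1]],
       tau0 = fit$par[[2]], tau0_error = se[[2]], n_used = length(q))
}

# per-Q two-Lorentzian + flat background fit used for buffer spectra
fit_two_lorentzians_q <- function(omega, y, sig, conv) {
  step <- omega[2] - omega[1]
  itot <- sum(y) * step
  bg0 <- stats::median(c(utils::head(y, 10), utils::tail(y, 10)))
  model <- function(p) {
    qe <- p[1] * lorentzian_density(omega, p[3]) +
      p[2] * lorentzian_density(omega, p[4])
    conv(qe) + p[5]
  }
  resid_fn <- function(p) (model(p) - y) / sig
  base <- c(a_n = 0.6 * itot, a_b = 0.3 * itot, g_n = 0.08, g_b = 0.5,
            bg = max(bg0, 0))
  starts <- list(base,
                 replace(base, 3:4, c(0.03, 0.9)),
                 replace(base, 3:4, c(0.2, 1.5)))
  lower <- c(0, 0, 1e-4, 1e-4, 0)
  upper <- c(Inf, Inf, 20, 20, Inf)
  fit <- lm_multistart(resid_fn, starts, lower, upper, nobs = length(y))
  if (is.null(fit)) return(NULL)
  p <- fit$par; se <- lm_std_errors(fit)
  if (p[3] > p[4]) {   # enforce narrow < broad labeling
    p <- p[c(2, 1, 4, 3, 5)]; se <- se[c(2, 1, 4, 3, 5)]
  }
  chi2red <- fit$deviance / max(length(y) - 5L, 1L)
  list(a_n = p[[1]], a_b = p[[2]], g_n = p[[3]], g_b = p[[4]], bg = p[[5]],
       g_n_err = se[[3]], g_b_err = se[[4]], chi2red = chi2red,
       converged = fit$info %in% 1:4)
}

#' Fit the buffer spectra with two Lorentzians and extract transport laws
#'
#' Per Q, fits two resolution-convolved Lorentzians plus a flat background
#' to the buffer (solvent) spectrum and reports the per-Q widths (the
#' classic width-vs-Q^2 table).  The narrow widths are fitted with the
#' jump-diffusion law (excluding an optional Q^2 window around the coherent
#' de Gennes dip); the broad width, which carries no systematic
#' Q-dependence for rotational motion, is summarized as a constant, and the
#' broad/narrow amplitude ratio as a weighted mean.
#'
#' With `refine = TRUE` (default) the headline parameters come from a
#' global separable fit over all Q at once: the narrow width follows the
#' jump-diffusion law, the broad width is one constant, and the per-Q
#' amplitudes and flat backgrounds (in which the model is linear) are
#' profiled out by weighted linear least squares.  Spectra whose Q^2 falls
#' in `dip_window` are left out of the global residuals.
#'
#' @param buffer Buffer [qens_spectra()], vanadium-normalized.
#' @param resolution Resolution matrix from [normalize_vanadium()].
#' @param dip_window Q^2 window (1/Angstrom^2) excluded from the
#'   jump-diffusion fit of the narrow widths; `NULL` disables.
#' @param refine Run the global separable refinement (default TRUE).
#' @return An object of class `"buffer_model"`: `per_q` data.frame,
#'   `jd` (list with `d_t`, `tau0` and errors), `rot_width` and
#'   `rot_width_error` (meV), `amplitude_ratio` (broad/narrow).
#' @export
fit_buffer <- function(buffer, resolution, dip_window = c(2.0, 3.0),
                       refine = TRUE) {
  stopifnot(inherits(buffer, "qens_spectra"))
  nq <- length(buffer$q_list)
  if (nq < 5L) stop("need at least 5 Q points")
  step <- assert_uniform_grid(buffer$omega_grid)
  rows <- vector("list", nq)
  for (i in seq_len(nq)) {
    conv <- make_convolver(resolution[i, ], step)
    sig <- pmax(buffer$errors[i, ], 1e-12)
    f <- fit_two_lorentzians_q(buffer$omega_grid, buffer$counts[i, ], sig, conv)
    rows[[i]] <- if (is.null(f)) {
      data.frame(q = buffer$q_list[i], a_n = NA, a_b = NA, g_n = NA, g_b = NA,
                 g_n_err = NA, g_b_err = NA, chi2red = NA, converged = FALSE)
    } else {
      data.frame(q = buffer$q_list[i], a_n = f$a_n, a_b = f$a_b, g_n = f$g_n,
                 g_b = f$g_b, g_n_err = f$g_n_err, g_b_err = f$g_b_err,
                 chi2red = f$chi2red, converged = f$converged)
    }
  }
  per_q <- do.call(rbind, rows)
  ok <- per_q$converged
  if (sum(ok) < 4L) stop("fewer than 4 Q points converged in buffer fit")
  jd <- fit_jump_diffusion(per_q$q[ok], per_q$g_n[ok], per_q$g_n_err[ok],
                           exclude_q2 = dip_window)
  rot <- weighted_mean_se(per_q$g_b[ok], per_q$g_b_err[ok])
  ratio <- stats::weighted.mean(per_q$a_b[ok] / per_q$a_n[ok],
                                w = per_q$a_n[ok])
  out <- list(per_q = per_q, jd = jd,
              rot_width = rot[["mean"]], rot_width_error = rot[["se"]],
              amplitude_ratio = ratio,
              concentration = buffer$concentration)
  if (refine) {
    glob <- tryCatch(
      buffer_global_fit(buffer, resolution, dip_window,
                        start = c(d_t = jd$d_t, tau0 = jd$tau0,
                                  g_rot = rot[["mean"]])),
      error = function(e) NULL)
    if (!is.null(glob)) {
      out$jd <- glob$jd
      out$rot_width <- glob$rot_width
      out$rot_width_error <- glob$rot_width_error
      out$amplitude_ratio <- glob$amplitude_ratio
      out$per_q$a_n <- glob$amplitudes$a_n
      out$per_q$a_b <- glob$amplitudes$a_b
    }
  }
  structure(out, class = "buffer_model")
}

# Global separable buffer fit: shared (D_T, tau0, Gamma_rot), per-Q narrow
# and broad amplitudes plus flat background profiled by weighted linear LS.
buffer_global_fit <- function(buffer, resolution, dip_window, start) {
  step <- assert_uniform_grid(buffer$omega_grid)
  omega <- buffer$omega_grid
  nq <- length(buffer$q_list)
  g_min <- step / 2
  use <- if (is.null(dip_window)) rep(TRUE, nq)
    else !(buffer$q_list^2 >= dip_window[1] &
             buffer$q_list^2 <= dip_window[2])
  if (sum(use) < 4L) use <- rep(TRUE, nq)
  convs <- lapply(seq_len(nq), function(i) make_convolver(resolution[i, ], step))
  ws <- lapply(seq_len(nq), function(i) 1 / pmax(buffer$errors[i, ], 1e-12))
  inner <- function(i, g_n, g_b) {
    X <- cbind(nar = convs[[i]](lorentzian_density(omega, g_n)),
               bro = convs[[i]](lorentzian_density(omega, g_b)),
               bg = 1)
    fit <- stats::lm.wfit(X, buffer$counts[i, ], ws[[i]]^2)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    list(beta = b, resid = (buffer$counts[i, ] - drop(X %*% b)) * ws[[i]])
  }
  resid_all <- function(th) {
    jd_s <- jump_diffusion_params(th[["d_t"]], th[["tau0"]])
    unlist(lapply(which(use), function(i) {
      g_n <- min(max(jump_diffusion_hwhm(jd_s, buffer$q_list[i]), g_min), 20)
      inner(i, g_n, th[["g_rot"]])$resid
    }), use.names = FALSE)
  }
  base <- c(d_t = min(max(start[["d_t"]], 5e-3), 0.9),
            tau0 = min(max(start[["tau0"]], 0.05), 19),
            g_rot = min(max(start[["g_rot"]], 4 * g_min), 5))
  starts <- list(base, c(d_t = 0.1, tau0 = 3, g_rot = 0.4),
                 c(d_t = 0.05, tau0 = 8, g_rot = 0.8))
  fit <- lm_multistart(resid_all, starts,
                       lower = c(1e-3, 0, 2 * g_min),
                       upper = c(1, 20, 10))
  if (is.null(fit)) stop("global buffer fit failed")
  se <- lm_std_errors(fit)
  th <- fit$par
  jd_s <- jump_diffusion_params(th[["d_t"]], th[["tau0"]])
  amp <- t(vapply(seq_len(nq), function(i) {
    g_n <- min(max(jump_diffusion_hwhm(jd_s, buffer$q_list[i]), g_min), 20)
    inner(i, g_n, th[["g_rot"]])$beta[c("nar", "bro")]
  }, numeric(2)))
  list(jd = list(d_t = th[["d_t"]], d_t_error = se[[1]],
                 tau0 = th[["tau0"]], tau0_error = se[[2]],
                 n_used = sum(use)),
       rot_width = th[["g_rot"]], rot_width_error = se[[3]],
       amplitude_ratio = stats::weighted.mean(
         pmax(amp[, 2], 0) / pmax(amp[, 1], 1e-12), w = pmax(amp[, 1], 0)),
       amplitudes = data.frame(a_n = pmax(amp[, 1], 0),
                               a_b = pmax(amp[, 2], 0)))
}

#' @export
print.buffer_model <- function(x, ...) {
  cat(sprintf(
    "<buffer_model> %g wt%%: D_T = %.3f (%.3f) A^2/ps, tau0 = %.2f (%.2f) ps, rot width = %.3f (%.3f) meV, ratio = %.2f\n",
    x$concentration, x$jd$d_t, x$jd$d_t_error, x$jd$tau0, x$jd$tau0_error,
    x$rot_width, x$rot_width_error, x$amplitude_ratio))
  invisible(x)
}

# Per-Q buffer signal amplitude measured on the buffer-only run: the sum of
# the two fitted Lorentzian weights, in vanadium-normalized units.  Q points
# where the buffer fit failed are filled by interpolation in Q.
measured_buffer_amplitude <- function(buffer_model, q_list) {
  pq <- buffer_model$per_q
  tot <- pq$a_n + pq$a_b
  ok <- is.finite(tot) & pq$converged
  if (!any(ok)) stop("no converged buffer amplitudes to measure the scale from")
  stats::approx(pq$q[ok], tot[ok], xout = q_list, rule = 2)$y
}

#' Constrained composite fit of sample spectra
#'
#' Per Q, fits the full composite model: a resolution-shaped elastic line,
#' two free sample Lorentzians (narrow translational, broad rotational), the
#' buffer's two Lorentzians with widths and internal amplitude ratio fixed
#' from the buffer-only fit, and a linear background.  All quasi-elastic
#' components are convolved with the instrumental resolution.
#'
#' The buffer amplitude can be handled three ways.  `"measured"` (default)
#' pins it, per Q, to the amplitude fitted on the buffer-only measurement
#' times a solvent `displacement` factor: the purely incoherent solvent
#' signal in the sample cell equals the buffer-cell signal up to the volume
#' displaced by the protein, so this uses all the information in the buffer
#' run without doubling its counting noise into the sample (as bin-by-bin
#' subtraction would).  `"free"` lets one common scale float (per Q in the
#' free pass, shared across Q in the global refinement, since vanadium
#' normalization makes the solvent fraction Q-independent).  A numeric
#' value (scalar or per-Q vector) fixes it, e.g. 0 for buffer-free data.
#'
#' The narrow/broad labeling is enforced after each fit (swap guard); Q
#' points whose two sample widths come within 20 percent of each other are
#' flagged `degenerate` and excluded by downstream transport fits.
#'
#' When `refine = TRUE` (default), the free per-Q fit is followed by a
#' global separable fit in which the narrow width follows the
#' jump-diffusion law in Q and the broad rotational width is one
#' Q-independent constant, with all per-Q amplitudes profiled out by
#' weighted linear least squares; the resulting amplitude table drives the
#' EISF.  A second per-Q pass with the broad width pinned provides the
#' classic width-vs-Q^2 diagnostic table.
#'
#' @param sample Sample [qens_spectra()], vanadium-normalized.
#' @param buffer_model A [fit_buffer()] result for the matching condition.
#' @param resolution Resolution matrix from [normalize_vanadium()].
#' @param buffer_scale `"measured"` (default), `"free"`, or a numeric
#'   fixed value (scalar or one per Q).
#' @param displacement Multiplier on the measured buffer amplitude
#'   accounting for solvent displaced by the protein (default 1).
#' @param refine Run the global refinement (default TRUE).
#' @return An object of class `"sample_fit"`: `per_q` data.frame
#'   (amplitudes, widths, errors, background, reduced chi^2, flags; from
#'   the broad-width-constrained pass when refined), `per_q_free` (the
#'   unconstrained pass), `per_q_eisf` (amplitude table of the global fit,
#'   used for the EISF; NULL if refinement was disabled or failed), and
#'   `global` (shared transport parameters with errors).
#' @export
fit_sample <- function(sample, buffer_model, resolution,
                       buffer_scale = "measured", displacement = 1,
                       refine = TRUE) {
  stopifnot(inherits(sample, "qens_spectra"),
            inherits(buffer_model, "buffer_model"))
  step <- assert_uniform_grid(sample$omega_grid)
  omega <- sample$omega_grid
  nq <- length(sample$q_list)
  jd_pars <- jump_diffusion_params(buffer_model$jd$d_t, buffer_model$jd$tau0)
  free_scale <- identical(buffer_scale, "free")
  bs_vec <- if (free_scale) rep(NA_real_, nq)
    else if (identical(buffer_scale, "measured"))
      displacement * measured_buffer_amplitude(buffer_model, sample$q_list)
    else rep_len(as.numeric(buffer_scale), nq)
  g_min <- step / 2   # widths below half a grid step alias onto the elastic line
  rho <- buffer_model$amplitude_ratio

  na_row <- function(qv) data.frame(
    q = qv, buffer_scale = NA, elastic_amplitude = NA, elastic_err = NA,
    amp_narrow = NA, amp_narrow_err = NA, hwhm_narrow = NA,
    hwhm_narrow_err = NA, amp_broad = NA, amp_broad_err = NA,
    hwhm_broad = NA, hwhm_broad_err = NA, bg_slope = NA, bg_intercept = NA,
    chi2red = NA, converged = FALSE, degenerate = NA, at_bound = NA)

  # one per-Q composite fit; widths may be pinned (fix_g_nar / fix_g_bro)
  fit_one_q <- function(i, fix_g_nar = NULL, fix_g_bro = NULL) {
    qv <- sample$q_list[i]
    y <- sample$counts[i, ]
    sig <- pmax(sample$errors[i, ], 1e-12)
    conv <- make_convolver(resolution[i, ], step)
    res_shape <- resolution[i, ] / (sum(resolution[i, ]) * step)
    gb_n <- max(jump_diffusion_hwhm(jd_pars, qv), 1e-4)
    buf_unit <- conv((lorentzian_density(omega, gb_n) +
                        rho * lorentzian_density(omega,
                                                 buffer_model$rot_width)) /
                       (1 + rho))
    itot <- sum(y) * step
    bg0 <- max(stats::median(c(utils::head(y, 10), utils::tail(y, 10))), 0)
    full <- function(p) {
      if (!is.null(fix_g_nar)) p[["g_nar"]] <- fix_g_nar
      if (!is.null(fix_g_bro)) p[["g_bro"]] <- fix_g_bro
      if (!free_scale) p[["bs"]] <- bs_vec[i]
      p
    }
    model <- function(p) {
      p <- full(p)
      qe <- p[["a_nar"]] * lorentzian_density(omega, p[["g_nar"]]) +
        p[["a_bro"]] * lorentzian_density(omega, p[["g_bro"]])
      p[["a_el"]] * res_shape + conv(qe) + p[["bs"]] * buf_unit +
        p[["bg_sl"]] * omega + p[["bg_in"]]
    }
    resid_fn <- function(p) (model(p) - y) / sig
    # data-driven elastic start: peak height above wings over resolution peak
    a_el0 <- max((max(y) - bg0) / max(res_shape), 0.1 * itot)
    rest0 <- max(itot - a_el0, 0.1 * itot)
    base <- c(a_el = a_el0, a_nar = 0.4 * rest0, g_nar = 0.08,
              a_bro = 0.4 * rest0, g_bro = 0.6, bg_sl = 0, bg_in = bg0,
              bs = 0.2 * itot)
    lower <- c(a_el = 0, a_nar = 0, g_nar = g_min, a_bro = 0, g_bro = g_min,
               bg_sl = -Inf, bg_in = 0, bs = 0)
    upper <- c(a_el = Inf, a_nar = Inf, g_nar = 20, a_bro = Inf, g_bro = 20,
               bg_sl = Inf, bg_in = Inf, bs = Inf)
    drop <- c(if (!is.null(fix_g_nar)) "g_nar",
              if (!is.null(fix_g_bro)) "g_bro",
              if (!free_scale) "bs")
    keep <- setdiff(names(base), drop)
    width_grid <- list(c(0.03, 0.3), c(0.08, 0.6), c(0.05, 1.2),
                       c(0.15, 0.45), c(0.02, 0.9))
    starts <- lapply(width_grid, function(w) {
      st <- replace(base, c(3, 5), w)
      st[keep]
    })
    if (length(drop)) starts <- unique(starts)
    fit <- lm_multistart(resid_fn, starts, lower[keep], upper[keep],
                         nobs = length(y))
    if (is.null(fit)) return(na_row(qv))
    p <- full(fit$par)
    se_fit <- lm_std_errors(fit)
    se <- stats::setNames(rep(0, length(base)), names(base))
    se[names(se_fit)] <- se_fit
    if (p[["g_nar"]] > p[["g_bro"]] && is.null(fix_g_nar) &&
        is.null(fix_g_bro)) {   # swap guard: narrow < broad
      sw <- function(v) { v[c("a_nar", "g_nar", "a_bro", "g_bro")] <-
        v[c("a_bro", "g_bro", "a_nar", "g_nar")]; v }
      p <- sw(p); se <- sw(se)
    }
    degenerate <- p[["g_bro"]] < 1.2 * p[["g_nar"]]
    at_bound <- (is.null(fix_g_nar) && p[["g_nar"]] <= 1.05 * g_min) ||
      (is.null(fix_g_bro) && p[["g_bro"]] >= 19.9)
    chi2red <- fit$deviance / max(length(y) - length(keep), 1L)
    data.frame(
      q = qv, buffer_scale = p[["bs"]],
      elastic_amplitude = p[["a_el"]], elastic_err = se[["a_el"]],
      amp_narrow = p[["a_nar"]], amp_narrow_err = se[["a_nar"]],
      hwhm_narrow = p[["g_nar"]], hwhm_narrow_err = se[["g_nar"]],
      amp_broad = p[["a_bro"]], amp_broad_err = se[["a_bro"]],
      hwhm_broad = p[["g_bro"]], hwhm_broad_err = se[["g_bro"]],
      bg_slope = p[["bg_sl"]], bg_intercept = p[["bg_in"]],
      chi2red = chi2red, converged = fit$info %in% 1:4,
      degenerate = degenerate, at_bound = at_bound)
  }

  pass1 <- do.call(rbind, lapply(seq_len(nq), function(i) fit_one_q(i)))
  per_q <- pass1
  per_q_eisf <- NULL
  glob <- NULL
  if (refine) {
    glob <- tryCatch(
      global_transport_fit(sample, buffer_model, resolution, pass1,
                           free_scale = free_scale, bs_vec = bs_vec),
      error = function(e) NULL)
    if (!is.null(glob)) {
      # pass 2: broad (rotational) width has no Q-dependence -> pin it at
      # the global estimate, keep the narrow width free per Q (the classic
      # width-vs-Q^2 diagnostic table)
      per_q <- do.call(rbind, lapply(seq_len(nq), function(i)
        fit_one_q(i, fix_g_bro = glob$g_bro)))
      per_q$hwhm_broad_err <- glob$g_bro_error
      per_q_eisf <- glob$per_q_amplitudes
    }
  }
  structure(list(per_q = per_q, per_q_free = pass1,
                 per_q_eisf = per_q_eisf, global = glob,
                 concentration = sample$concentration,
                 temperature = sample$temperature),
            class = "sample_fit")
}

# Global separable (variable-projection) fit: the three shared width
# parameters (D_T, tau0 of the narrow jump-diffusion line; the Q-independent
# broad width) are optimized over all Q at once, while the per-Q amplitudes
# (elastic, narrow, broad, buffer scale, background) -- in which the model
# is linear once widths are fixed -- are profiled out by weighted linear
# least squares at every step.  This imposes the transport laws exactly
# during the fit instead of after it and is far more stable at realistic
# counting statistics than per-Q free-width fits.
global_transport_fit <- function(sample, buffer_model, resolution, pass1,
                                 free_scale, bs_vec) {
  step <- assert_uniform_grid(sample$omega_grid)
  omega <- sample$omega_grid
  nq <- length(sample$q_list)
  g_min <- step / 2
  rho <- buffer_model$amplitude_ratio
  jd_buf <- jump_diffusion_params(buffer_model$jd$d_t, buffer_model$jd$tau0)
  convs <- lapply(seq_len(nq), function(i) make_convolver(resolution[i, ], step))
  res_shapes <- lapply(seq_len(nq), function(i)
    resolution[i, ] / (sum(resolution[i, ]) * step))
  buf_units <- lapply(seq_len(nq), function(i) {
    gb_n <- max(jump_diffusion_hwhm(jd_buf, sample$q_list[i]), 1e-4)
    convs[[i]]((lorentzian_density(omega, gb_n) +
                  rho * lorentzian_density(omega, buffer_model$rot_width)) /
                 (1 + rho))
  })
  ws <- lapply(seq_len(nq), function(i) 1 / pmax(sample$errors[i, ], 1e-12))
  itot_med <- stats::median(vapply(seq_len(nq), function(i)
    sum(sample$counts[i, ]) * step, numeric(1)))

  # The solvent is purely incoherent, so after vanadium normalization its
  # scale is Q-independent: one shared buffer scale, optimized with the
  # widths, instead of one per Q.  This breaks the near-collinearity of the
  # buffer narrow line with the elastic line at low Q.
  inner <- function(i, g_n, g_b, bs) {
    X <- cbind(el = res_shapes[[i]],
               nar = convs[[i]](lorentzian_density(omega, g_n)),
               bro = convs[[i]](lorentzian_density(omega, g_b)),
               sl = omega, ic = 1)
    y <- sample$counts[i, ] - (if (free_scale) bs else bs_vec[i]) *
      buf_units[[i]]
    w <- ws[[i]]
    fit <- stats::lm.wfit(X, y, w^2)
    b <- fit$coefficients
    b[is.na(b)] <- 0   # collinear column dropped by pivoting
    list(beta = b, resid = (y - drop(X %*% b)) * w, X = X, w = w)
  }
  resid_all <- function(th) {
    jd_s <- jump_diffusion_params(th[["d_t"]], th[["tau0"]])
    bs <- if (free_scale) th[["bs"]] else 0
    unlist(lapply(seq_len(nq), function(i) {
      g_n <- min(max(jump_diffusion_hwhm(jd_s, sample$q_list[i]), g_min), 20)
      inner(i, g_n, th[["g_bro"]], bs)$resid
    }), use.names = FALSE)
  }
  # starts from the free per-Q pass
  ok <- pass1$converged & !pass1$degenerate & !pass1$at_bound
  start_jd <- tryCatch(
    fit_jump_diffusion(pass1$q[ok], pass1$hwhm_narrow[ok],
                       pass1$hwhm_narrow_err[ok]),
    error = function(e) list(d_t = 0.2, tau0 = 3))
  gb0 <- stats::median(pass1$hwhm_broad[ok], na.rm = TRUE)
  if (!is.finite(gb0)) gb0 <- 0.5
  base <- c(d_t = min(max(start_jd$d_t, 5e-3), 0.9),
            tau0 = min(max(start_jd$tau0, 0.05), 50),
            g_bro = min(max(gb0, 4 * g_min), 5))
  starts <- list(base, replace(base, 3, min(2 * base[[3]], 5)),
                 c(d_t = 0.2, tau0 = 3, g_bro = 0.5),
                 c(d_t = 0.1, tau0 = 6, g_bro = 0.35),
                 c(d_t = 0.4, tau0 = 2, g_bro = 0.9))
  # physical bounds: D_T up to ~4x bulk water, residence times ps-scale;
  # they exclude the spurious "saturated narrow line" solution family in
  # which the narrow width loses all Q-dependence
  lower <- c(d_t = 1e-3, tau0 = 0, g_bro = 2 * g_min)
  upper <- c(d_t = 1, tau0 = 20, g_bro = 10)
  if (free_scale) {
    bs0 <- 0.25 * itot_med
    starts <- c(lapply(starts, function(s) c(s, bs = bs0)),
                list(c(base, bs = 0.05 * itot_med),
                     c(base, bs = 0.5 * itot_med)))
    lower <- c(lower, bs = 0)
    upper <- c(upper, bs = Inf)
  }
  fit <- lm_multistart(resid_all, starts, lower, upper)
  if (is.null(fit)) stop("global transport fit failed")
  se <- lm_std_errors(fit)
  th <- fit$par
  jd_s <- jump_diffusion_params(th[["d_t"]], th[["tau0"]])
  # per-Q amplitudes (and their proper covariance errors) at the optimum
  rows <- lapply(seq_len(nq), function(i) {
    g_n <- min(max(jump_diffusion_hwhm(jd_s, sample$q_list[i]), g_min), 20)
    sol <- inner(i, g_n, th[["g_bro"]],
                 if (free_scale) th[["bs"]] else 0)
    xt <- sol$X * sol$w
    bse <- tryCatch(sqrt(pmax(diag(solve(crossprod(xt))), 0)),
                    error = function(e) rep(NA_real_, ncol(sol$X)))
    names(bse) <- colnames(sol$X)
    b <- sol$beta
    data.frame(
      q = sample$q_list[i],
      buffer_scale = if (free_scale) th[["bs"]] else bs_vec[i],
      elastic_amplitude = max(b[["el"]], 0), elastic_err = bse[["el"]],
      amp_narrow = max(b[["nar"]], 0), amp_narrow_err = bse[["nar"]],
      hwhm_narrow = g_n, hwhm_narrow_err = 0,
      amp_broad = max(b[["bro"]], 0), amp_broad_err = bse[["bro"]],
      hwhm_broad = th[["g_bro"]], hwhm_broad_err = se[[3]],
      bg_slope = b[["sl"]], bg_intercept = b[["ic"]],
      chi2red = sum(sol$resid^2) / max(length(omega) - ncol(sol$X), 1L),
      converged = TRUE, degenerate = FALSE, at_bound = FALSE)
  })
  nfree <- length(fit$fvec) - (length(th) + nq * 5)
  list(d_t = th[["d_t"]], d_t_error = se[[1]],
       tau0 = th[["tau0"]], tau0_error = se[[2]],
       g_bro = th[["g_bro"]], g_bro_error = se[[3]],
       buffer_scale = if (free_scale) th[["bs"]] else NA_real_,
       chi2red = fit$deviance / max(nfree, 1L),
       per_q_amplitudes = do.call(rbind, rows))
}

#' @export
print.sample_fit <- function(x, ...) {
  ok <- sum(x$per_q$converged, na.rm = TRUE)
  cat(sprintf(
    "<sample_fit> %g wt%%, T=%g K: %d/%d Q converged, median chi2_red = %.2f\n",
    x$concentration, x$temperature, ok, nrow(x$per_q),
    stats::median(x$per_q$chi2red, na.rm = TRUE)))
  invisible(x)
}

#' Elastic incoherent structure factor from a sample fit
#'
#' `A0(Q) = elastic / (elastic + narrow + broad)` amplitudes of the sample
#' components only; the buffer contribution and background are excluded
#' (they are solvent and instrument, not sample).  Errors by first-order
#' propagation.
#'
#' @param fit A [fit_sample()] result with at least 5 converged Q points.
#' @return An object of class `"eisf_curve"`: list with `q`, `a0`,
#'   `a0_error`.
#' @export
compute_eisf <- function(fit) {
  stopifnot(inherits(fit, "sample_fit"))
  tab <- if (!is.null(fit$per_q_eisf)) fit$per_q_eisf else fit$per_q
  pq <- tab[which(tab$converged & !tab$degenerate & !tab$at_bound), ]
  if (nrow(pq) < 5L) stop("need at least 5 converged Q points")
  s <- pq$elastic_amplitude + pq$amp_narrow + pq$amp_broad
  if (any(s <= 0)) stop("zero total intensity in EISF denominator")
  a0 <- pq$elastic_amplitude / s
  var <- (((s - pq$elastic_amplitude) / s^2) * pq$elastic_err)^2 +
    ((pq$elastic_amplitude / s^2) * pq$amp_narrow_err)^2 +
    ((pq$elastic_amplitude / s^2) * pq$amp_broad_err)^2
  structure(list(q = pq$q, a0 = a0, a0_error = sqrt(var)),
            class = "eisf_curve")
}

#' Fit the confined-rotation EISF with an immobile fraction
#'
#' Weighted least squares of `A0(Q) = p + (1 - p) (3 j1(QR)/QR)^2` with
#' bounds `p` in \[0, 1\] and `R` in (0.1, 20) Angstrom.  A solution pinned
#' at a bound, or a near-flat curve leaving R unidentified, is flagged.
#'
#' @param curve An [compute_eisf()] result (or any list with `q`, `a0`,
#'   `a0_error`).
#' @return List with `p`, `p_error` (fractions), `r`, `r_error` (Angstrom),
#'   `flagged` (logical) and `chi2red`.
#' @export
fit_eisf <- function(curve) {
  q <- curve$q; a0 <- curve$a0
  sig <- curve$a0_error
  sig[!is.finite(sig) | sig <= 0] <- max(stats::median(sig[sig > 0],
                                                       na.rm = TRUE), 1e-4)
  if (length(q) < 5L) stop("need at least 5 EISF points")
  resid_fn <- function(par) {
    (par[1] + (1 - par[1]) * sphere_eisf(par[2], q) - a0) / sig
  }
  p0 <- min(max(min(a0), 0), 1)
  starts <- list(c(p = p0, r = 2), c(p = p0, r = 1), c(p = p0, r = 4),
                 c(p = max(p0 - 0.2, 0), r = 2.5))
  fit <- lm_multistart(resid_fn, starts, lower = c(0, 0.1),
                       upper = c(1, 20), nobs = length(q))
  if (is.null(fit)) stop("EISF fit failed to converge")
  se <- lm_std_errors(fit)
  span <- max(a0) - min(a0)
  flagged <- fit$par[[1]] >= 1 - 1e-6 || fit$par[[1]] <= 1e-6 ||
    fit$par[[2]] <= 0.1 + 1e-6 || fit$par[[2]] >= 20 - 1e-6 ||
    span < 3 * stats::median(sig)   # flat curve: R unidentifiable
  list(p = fit$par[[1]], p_error = se[[1]],
       r = fit$par[[2]], r_error = se[[2]],
       flagged = flagged,
       chi2red = fit$deviance / max(length(q) - 2L, 1L))
}

#' Transport parameters from a sample fit
#'
#' Narrow widths follow the jump-diffusion law and broad widths, which
#' carry no Q-dependence for rotational motion, a constant whose half
#' (`Gamma_R = 2 D_R`) is the rotational rate constant.  When the sample
#' fit carries a global refinement (see [fit_sample()]), its estimates and
#' covariance errors are reported; otherwise the jump-diffusion law is
#' fitted to the per-Q narrow widths and the broad widths are averaged.
#' Q points flagged degenerate (narrow and broad widths within 20 percent)
#' or non-converged are excluded from the per-Q route.
#'
#' @param fit A [fit_sample()] result.
#' @param eisf_fit Optional [fit_eisf()] result supplying `p` and `R`.
#' @param exclude_q2 Optional Q^2 window excluded from the jump-diffusion
#'   fit (default none for protein samples).
#' @return An object of class `"transport_params"`: `d_t` and `d_t_error`
#'   on the 1e-5 cm^2/s reporting scale, `tau0`, `tau0_error` (ps), `d_r`,
#'   `d_r_error` (meV), `p`, `p_error`, `r`, `r_error` (Angstrom; NA when no
#'   EISF fit is supplied), `n_q_used`.
#' @export
fit_transport <- function(fit, eisf_fit = NULL, exclude_q2 = NULL) {
  stopifnot(inherits(fit, "sample_fit"))
  if (!is.null(fit$global)) {
    jd <- list(d_t = fit$global$d_t, d_t_error = fit$global$d_t_error,
               tau0 = fit$global$tau0, tau0_error = fit$global$tau0_error)
    rot <- c(mean = fit$global$g_bro, se = fit$global$g_bro_error)
    n_used <- nrow(fit$per_q)
  } else {
    pq <- fit$per_q
    ok <- which(pq$converged & !pq$degenerate & !pq$at_bound &
                  is.finite(pq$hwhm_narrow_err) & pq$hwhm_narrow_err > 0)
    if (length(ok) < 4L)
      stop("fewer than 4 usable Q points for transport fit")
    jd <- fit_jump_diffusion(pq$q[ok], pq$hwhm_narrow[ok],
                             pq$hwhm_narrow_err[ok], exclude_q2 = exclude_q2)
    rot <- weighted_mean_se(pq$hwhm_broad[ok], pq$hwhm_broad_err[ok])
    n_used <- length(ok)
  }
  structure(list(
    d_t = jd$d_t / d_unit_A2ps_per_1e5cm2s,
    d_t_error = jd$d_t_error / d_unit_A2ps_per_1e5cm2s,
    tau0 = jd$tau0, tau0_error = jd$tau0_error,
    d_r = rot[["mean"]] / 2, d_r_error = rot[["se"]] / 2,
    p = if (is.null(eisf_fit)) NA_real_ else eisf_fit$p,
    p_error = if (is.null(eisf_fit)) NA_real_ else eisf_fit$p_error,
    r = if (is.null(eisf_fit)) NA_real_ else eisf_fit$r,
    r_error = if (is.null(eisf_fit)) NA_real_ else eisf_fit$r_error,
    n_q_used = n_used), class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf(
    paste0("<transport_params> D_T = %.2f (%.2f) x1e-5 cm^2/s, tau0 = %.2f (%.2f) ps,\n",
           "  D_R = %.3f (%.3f) meV, p = %.3f (%.3f), R = %.2f (%.2f) A  [%d Q]\n"),
    x$d_t, x$d_t_error, x$tau0, x$tau0_error, x$d_r, x$d_r_error,
    x$p, x$p_error, x$r, x$r_error, x$n_q_used))
  invisible(x)
}
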