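# Synthetic-data generators: every input the pipelines consume can be made
# from explicit ground truth, so each stage is testable by parameter
# recovery without any external measurement.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Instrument profile
#'
#' Energy grid, Gaussian resolution width and Q coverage of a neutron
#' spectrometer.  Presets emulate the three classes of instrument used for
#' protein dynamics at a reactor source: a cold time-of-flight machine
#' (`"in6_like"`, ~20 ps window), a thermal backscattering machine
#' (`"in13_like"`, ~100 ps, wide Q), and a high-resolution backscattering
#' machine (`"in16_like"`, ~1 ns).  The resolution HWHM defaults to
#' `hbar / time_window` (Heisenberg relation between energy resolution and
#' observable time).
#'
#' @param label `"in6_like"`, `"in13_like"`, `"in16_like"`, or `"custom"`
#'   (then all fields must be supplied).
#' @param omega_range,omega_step Energy grid, meV.
#' @param resolution_hwhm Gaussian resolution HWHM, meV.
#' @param q_grid Momentum transfers, 1/Angstrom.
#' @param time_window Observable time scale, ps.
#' @return An object of class `"instrument_profile"`.
#' @export
#' @examples
#' make_instrument("in6_like")$resolution_hwhm   # ~0.033 meV
make_instrument <- function(label = c("in6_like", "in13_like", "in16_like",
                                      "custom"),
                            omega_range = NULL, omega_step = NULL,
                            resolution_hwhm = NULL, q_grid = NULL,
                            time_window = NULL) {
  label <- match.arg(label)
  preset <- switch(label,
    in6_like = list(omega_range = c(-5, 5), omega_step = 0.011,
                    time_window = 20,
                    q_grid = seq(0.4, 2.0, length.out = 12)),
    in13_like = list(omega_range = c(-0.5, 0.5), omega_step = 0.002,
                     time_window = 100,
                     q_grid = seq(0.3, 4.5, length.out = 16)),
    in16_like = list(omega_range = c(-0.015, 0.015), omega_step = 5e-5,
                     time_window = 1000,
                     q_grid = seq(0.2, 1.9, length.out = 12)),
    custom = list())
  pick <- function(user, def) if (is.null(user)) def else user
  omega_range <- pick(omega_range, preset$omega_range)
  omega_step <- pick(omega_step, preset$omega_step)
  time_window <- pick(time_window, preset$time_window)
  q_grid <- pick(q_grid, preset$q_grid)
  if (is.null(omega_range) || is.null(omega_step) || is.null(q_grid) ||
      (is.null(time_window) && is.null(resolution_hwhm)))
    stop("custom instruments require all fields")
  resolution_hwhm <- pick(resolution_hwhm,
                          if (!is.null(time_window)) hbar_mev_ps / time_window)
  if (resolution_hwhm <= 0) stop("resolution_hwhm must be > 0")
  omega_grid <- seq(omega_range[1], omega_range[2], by = omega_step)
  structure(list(label = label, omega_range = omega_range,
                 omega_step = omega_step, omega_grid = omega_grid,
                 resolution_hwhm = resolution_hwhm, q_grid = q_grid,
                 time_window = time_window),
            class = "instrument_profile")
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf(
    "<instrument_profile> %s: resolution %.4g meV (HWHM), omega [%g, %g] meV step %g, %d Q in [%.2f, %.2f] 1/A\n",
    x$label, x$resolution_hwhm, x$omega_range[1], x$omega_range[2],
    x$omega_step, length(x$q_grid), min(x$q_grid), max(x$q_grid)))
  invisible(x)
}

#' Ground-truth condition for synthetic QENS generation
#'
#' Bundles every parameter of the forward model for one sample condition:
#' solvent jump diffusion and rotation, protein jump diffusion and confined
#' rotation with immobile fraction, Debye-Waller displacement, background
#' and counting statistics.
#'
#' @param concentration Co-solute concentration, wt percent.
#' @param buffer_jd [jump_diffusion_params()] of the solvent.
#' @param buffer_rot_width Solvent rotational line HWHM, meV.
#' @param buffer_ratio Solvent broad/narrow amplitude ratio.
#' @param sample_jd [jump_diffusion_params()] of the protein component.
#' @param sample_rot [confined_rotation_params()] of the protein component.
#' @param u2 Mean square displacement for the Debye-Waller factor,
#'   Angstrom^2.
#' @param qe_split Fraction of the protein quasi-elastic weight assigned to
#'   the narrow translational line (remainder goes to the broad rotational
#'   line).
#' @param buffer_level Buffer intensity inside the sample measurement,
#'   relative to the protein intensity.  The default 0.08 follows from
#'   incoherent cross sections: ~7 wt percent exchanged-proton-free H in
#'   the protein against a deuterated buffer (D 2.05 barn vs H 80.3 barn)
#'   at the experimental solvent-to-protein mass ratio of about 2.
#' @param empty_level Flat empty-cell level as a fraction of peak counts.
#' @param bg_slope,bg_intercept Linear background as fractions of peak
#'   counts (per meV and absolute).
#' @param peak_counts Expected counts at the elastic maximum of the first Q;
#'   `Inf` disables counting noise.
#' @param seed Integer RNG seed for the Poisson noise.
#' @return An object of class `"ground_truth_condition"`.
#' @export
ground_truth_condition <- function(concentration = 0,
                                   buffer_jd = jump_diffusion_params(0.117, 3.3),
                                   buffer_rot_width = 0.4,
                                   buffer_ratio = 0.5,
                                   sample_jd = jump_diffusion_params(0.29, 5.5),
                                   sample_rot = confined_rotation_params(0.726, 2.11, 0.24),
                                   u2 = 1.0, qe_split = 0.5,
                                   buffer_level = 0.08, empty_level = 0.01,
                                   bg_slope = 1e-5, bg_intercept = 5e-4,
                                   peak_counts = 1e4, seed = 1L) {
  stopifnot(inherits(buffer_jd, "jump_diffusion_params"),
            inherits(sample_jd, "jump_diffusion_params"),
            inherits(sample_rot, "confined_rotation_params"))
  if (buffer_rot_width <= 0 || buffer_ratio <= 0)
    stop("buffer widths and ratio must be > 0")
  if (u2 < 0 || qe_split < 0 || qe_split > 1 || buffer_level < 0 ||
      empty_level < 0 || peak_counts <= 0)
    stop("invalid ground-truth parameters")
  structure(list(concentration = concentration, buffer_jd = buffer_jd,
                 buffer_rot_width = buffer_rot_width,
                 buffer_ratio = buffer_ratio, sample_jd = sample_jd,
                 sample_rot = sample_rot, u2 = u2, qe_split = qe_split,
                 buffer_level = buffer_level, empty_level = empty_level,
                 bg_slope = bg_slope, bg_intercept = bg_intercept,
                 peak_counts = peak_counts, seed = seed),
            class = "ground_truth_condition")
}

#' Preset ground-truth conditions
#'
#' Conditions whose transport parameters equal the fitted values reported
#' for mouse acetylcholinesterase in D2O with deuterated sucrose at 310 K
#' (cold time-of-flight data): buffer jump diffusion
#' D_T = 1.17/0.89/0.73/0.61 x1e-5 cm^2/s and tau0 = 3.3/5.2/5.9/5.5 ps at
#' 0/5/10/15 wt percent, protein D_T = 2.9/2.1/2.7 x1e-5 cm^2/s,
#' tau0 = 5.5/3.8/2.3 ps, D_R = 0.24/0.36/0.4 meV, and EISF parameters
#' p = 72.6/75.8/79.8 percent, R = 2.11/2.24/2.3 Angstrom at 0/5/10
#' wt percent.  Used as recovery targets: spectra generated from these
#' conditions must return these numbers when refitted.
#'
#' @param name One of `"ache0wt"`, `"ache5wt"`, `"ache10wt"`,
#'   `"buffer15wt"`.
#' @param ... Overrides passed to [ground_truth_condition()]
#'   (e.g. `peak_counts`, `seed`).
#' @return A [ground_truth_condition()].
#' @export
condition_preset <- function(name = c("ache0wt", "ache5wt", "ache10wt",
                                      "buffer15wt"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    ache0wt = list(concentration = 0,
                   buffer_jd = jump_diffusion_params(0.117, 3.3),
                   sample_jd = jump_diffusion_params(0.29, 5.5),
                   sample_rot = confined_rotation_params(0.726, 2.11, 0.24)),
    ache5wt = list(concentration = 5,
                   buffer_jd = jump_diffusion_params(0.089, 5.2),
                   sample_jd = jump_diffusion_params(0.21, 3.8),
                   sample_rot = confined_rotation_params(0.758, 2.24, 0.36)),
    ache10wt = list(concentration = 10,
                    buffer_jd = jump_diffusion_params(0.073, 5.9),
                    sample_jd = jump_diffusion_params(0.27, 2.3),
                    sample_rot = confined_rotation_params(0.798, 2.3, 0.40)),
    buffer15wt = list(concentration = 15,
                      buffer_jd = jump_diffusion_params(0.061, 5.5)))
  do.call(ground_truth_condition, utils::modifyList(base, list(...)))
}

gaussian_resolution_shape <- function(omega_grid, hwhm) {
  sigma <- hwhm / sqrt(2 * log(2))
  d <- stats::dnorm(omega_grid, 0, sigma)
  d / (sum(d) * (omega_grid[2] - omega_grid[1]))
}

#' Generate a complete synthetic QENS dataset
#'
#' Forward model per Q: vanadium is the Gaussian resolution lineshape;
#' the buffer is two Lorentzians (jump-diffusion narrow width plus constant
#' rotational width, fixed internal ratio) convolved with the resolution;
#' the sample is the Debye-Waller-damped composite of an elastic line with
#' weight from the confined-rotation EISF, a narrow jump-diffusion
#' Lorentzian and a broad rotational Lorentzian (`Gamma = 2 D_R`), plus a
#' scaled buffer contribution and a linear background; the empty cell is a
#' flat low level.  Poisson counting noise is applied under the condition's
#' seed; errors are `sqrt(max(counts, 1))`.
#'
#' @param truth A [ground_truth_condition()].
#' @param instrument An [make_instrument()] profile.
#' @return List with elements `sample`, `buffer`, `empty`, `vanadium`
#'   ([qens_spectra()] objects), `truth`, and `instrument`.
#' @export
#' @examples
#' ds <- gen_qens_dataset(condition_preset("ache0wt", peak_counts = 1e4,
#'                                         seed = 7),
#'                        make_instrument("in6_like"))
#' ds$sample
gen_qens_dataset <- function(truth, instrument) {
  stopifnot(inherits(truth, "ground_truth_condition"),
            inherits(instrument, "instrument_profile"))
  omega <- instrument$omega_grid
  step <- instrument$omega_step
  qs <- instrument$q_grid
  nq <- length(qs); nw <- length(omega)
  widest <- max(2 * truth$sample_rot$d_r, truth$buffer_rot_width)
  if (diff(range(omega)) < 10 * widest)
    warning("omega range narrower than 10x the largest linewidth; truncation bias likely")
  res <- gaussian_resolution_shape(omega, instrument$resolution_hwhm)
  conv <- make_convolver(res, step)
  noise_free <- is.infinite(truth$peak_counts)
  peak <- if (noise_free) 1e6 else truth$peak_counts

  sample_lam <- buffer_lam <- matrix(0, nq, nw)
  for (i in seq_len(nq)) {
    qv <- qs[i]
    # solvent: two Lorentzians, unit total weight
    gbn <- max(jump_diffusion_hwhm(truth$buffer_jd, qv), 1e-6)
    buf_unit <- conv((lorentzian_density(omega, gbn) +
                        truth$buffer_ratio *
                          lorentzian_density(omega, truth$buffer_rot_width)) /
                       (1 + truth$buffer_ratio))
    # protein: elastic fraction from the EISF, remainder split narrow/broad
    a0 <- eisf_with_immobile(truth$sample_rot, qv)
    gsn <- max(jump_diffusion_hwhm(truth$sample_jd, qv), 1e-6)
    gsb <- max(rotational_hwhm(truth$sample_rot, 1L), 1e-6)
    dw <- exp(-truth$u2 * qv^2 / 3)
    protein <- dw * (a0 * res +
                       conv((1 - a0) * (truth$qe_split *
                                          lorentzian_density(omega, gsn) +
                                        (1 - truth$qe_split) *
                                          lorentzian_density(omega, gsb))))
    sample_lam[i, ] <- protein + truth$buffer_level * buf_unit
    buffer_lam[i, ] <- truth$buffer_level * buf_unit
  }
  scale <- peak / max(sample_lam[1, ])
  bg_line <- peak * (truth$bg_intercept + truth$bg_slope * omega)
  if (any(bg_line < 0)) stop("background line negative on the omega grid")
  sample_lam <- scale * sample_lam + bg_line[col(sample_lam)] +
    peak * truth$empty_level
  buffer_lam <- scale * buffer_lam + peak * truth$empty_level
  empty_lam <- matrix(peak * truth$empty_level, nq, nw)
  van_lam <- matrix(peak * res / max(res), nq, nw, byrow = TRUE)

  noisify <- function(lam) {
    cts <- if (noise_free) lam
      else matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    list(counts = cts, errors = sqrt(pmax(cts, 1)))
  }
  out <- with_seed(truth$seed, {
    lapply(list(sample = sample_lam, buffer = buffer_lam,
                empty = empty_lam, vanadium = van_lam), noisify)
  })
  mk <- function(role, x) qens_spectra(role, qs, omega, x$counts, x$errors,
                                       truth$concentration, 310)
  list(sample = mk("sample", out$sample), buffer = mk("buffer", out$buffer),
       empty = mk("empty", out$empty), vanadium = mk("vanadium", out$vanadium),
       truth = truth, instrument = instrument)
}

#' Generate an elastic temperature scan with known MSD law
#'
#' `S_el(Q, T) = S0 exp(-Q^2 u2(T) / 3) (1 + eps)` with
#' `u2(T) = u2_intercept + u2_slope * T` and multiplicative Gaussian noise
#' of fractional standard deviation `noise_frac`.  Errors are set to the
#' known noise level (with a small floor so weights stay finite when
#' `noise_frac = 0`).
#'
#' @param u2_intercept,u2_slope Linear MSD law, Angstrom^2 and Angstrom^2/K;
#'   must be non-negative over `t_grid`.
#' @param instrument An [make_instrument()] profile (supplies the Q grid and
#'   label).
#' @param t_grid Temperatures, K.
#' @param s0 Scale intensity.
#' @param noise_frac Fractional noise level.
#' @param seed Integer RNG seed.
#' @param concentration Recorded concentration, wt percent.
#' @return An [elastic_scan()].
#' @export
gen_elastic_scan <- function(u2_intercept, u2_slope, instrument,
                             t_grid = seq(270, 310, by = 5), s0 = 1000,
                             noise_frac = 0.02, seed = 1L,
                             concentration = 0) {
  stopifnot(inherits(instrument, "instrument_profile"))
  u2 <- u2_intercept + u2_slope * t_grid
  if (any(u2 < 0)) stop("u2(T) must be >= 0 over t_grid")
  q <- instrument$q_grid
  lam <- s0 * exp(-outer(q^2, u2) / 3)
  noisy <- with_seed(seed, {
    lam * (1 + matrix(stats::rnorm(length(lam), 0, noise_frac),
                      nrow(lam), ncol(lam)))
  })
  noisy[noisy < 0] <- 0
  err <- pmax(noise_frac, 1e-6) * lam
  elastic_scan(q, t_grid, noisy, err, concentration = concentration,
               instrument_label = instrument$label)
}

#' Generate a random-walk trajectory with a known diffusion law
#'
#' Three kinds of motion: `"free"` (Gaussian steps, variance `2 D dt` per
#' axis, so the MSD is `6 D tau`), `"confined_sphere"` (the same steps with
#' Metropolis rejection outside radius R, so the long-time MSD plateaus at
#' `(6/5) R^2` for positions uniform in the sphere), and `"jump"`
#' (exponential resting periods of mean `tau0` alternating with diffusive
#' bouts of mean `tau1`, giving a long-time effective coefficient
#' `D tau1 / (tau0 + tau1)` below the bout coefficient).
#'
#' @param kind `"free"`, `"confined_sphere"` or `"jump"`.
#' @param params Named list: `d` (Angstrom^2/ps) for all kinds; `r`
#'   (Angstrom) for `"confined_sphere"`; `tau0`, `tau1` (ps) for `"jump"`.
#' @param n_atoms,n_frames Trajectory size.
#' @param dt Frame spacing, ps.
#' @param seed Integer RNG seed.
#' @return A [trajectory()] of hydrogen-like atoms, one residue per atom.
#' @export
gen_trajectory <- function(kind = c("free", "confined_sphere", "jump"),
                           params = list(d = 0.1), n_atoms = 100,
                           n_frames = 1000, dt = 1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(params$d > 0, n_atoms >= 1, n_frames >= 2, dt > 0)
  sd_step <- sqrt(2 * params$d * dt)
  coords <- with_seed(seed, {
    arr <- array(0, c(n_frames, n_atoms, 3))
    if (kind == "free") {
      for (ax in 1:3) {
        steps <- matrix(stats::rnorm((n_frames - 1) * n_atoms, 0, sd_step),
                        n_frames - 1, n_atoms)
        arr[, , ax] <- rbind(0, apply(steps, 2, cumsum))
      }
      arr
    } else if (kind == "confined_sphere") {
      r <- params$r
      stopifnot(r > 0)
      # start uniform in the sphere (equilibrium), then Metropolis steps
      pos <- matrix(stats::rnorm(n_atoms * 3), n_atoms, 3)
      u <- stats::runif(n_atoms)^(1 / 3) * r
      pos <- pos / sqrt(rowSums(pos^2)) * u
      arr[1, , ] <- pos
      for (t in 2:n_frames) {
        prop <- pos + matrix(stats::rnorm(n_atoms * 3, 0, sd_step), n_atoms, 3)
        bad <- rowSums(prop^2) > r^2
        prop[bad, ] <- pos[bad, ]
        pos <- prop
        arr[t, , ] <- pos
      }
      arr
    } else {
      tau0 <- params$tau0; tau1 <- params$tau1
      stopifnot(tau0 > 0, tau1 > 0)
      p_start <- dt / tau0   # rest -> diffuse per frame
      p_stop <- dt / tau1    # diffuse -> rest per frame
      moving <- stats::runif(n_atoms) < tau1 / (tau0 + tau1)
      pos <- matrix(0, n_atoms, 3)
      arr[1, , ] <- pos
      for (t in 2:n_frames) {
        stepm <- matrix(stats::rnorm(n_atoms * 3, 0, sd_step), n_atoms, 3)
        pos <- pos + stepm * moving
        arr[t, , ] <- pos
        flip <- stats::runif(n_atoms)
        moving <- ifelse(moving, flip >= p_stop, flip < p_start)
      }
      arr
    }
  })
  atoms <- data.frame(element = "H", resid = seq_len(n_atoms), name = "H",
                      is_donor = FALSE, is_acceptor = FALSE,
                      is_hydrogen = TRUE)
  trajectory(coords, dt = dt, atoms = atoms)
}

rotate_towards <- function(u, theta_deg) {
  # unit vector at angle theta from u, random azimuth
  theta <- theta_deg * pi / 180
  v <- stats::rnorm(3)
  v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  cos(theta) * u + sin(theta) * v
}

#' Generate a toy structure with planted hydrogen bonds
#'
#' Places `k_bonds` donor-hydrogen-acceptor triples satisfying the
#' geometric criteria (donor-acceptor distance < 3.2 Angstrom, deviation of
#' the D-H...A angle from linear < 40 degrees) and `m_decoys` triples that
#' violate exactly one criterion (alternating long-distance and bad-angle
#' decoys).  Triples sit on a sparse grid (12 Angstrom spacing) so no
#' cross-triple bonds arise.
#'
#' @param k_bonds,m_decoys Counts of planted true bonds and decoys.
#' @param seed Integer RNG seed.
#' @return A single-frame [trajectory()] with donor/acceptor/hydrogen flags
#'   and attribute `"n_true_bonds"` recording the ground truth.
#' @export
gen_hbond_toy <- function(k_bonds, m_decoys, seed = 1L) {
  stopifnot(k_bonds >= 0, m_decoys >= 0)
  n <- k_bonds + m_decoys
  if (n == 0L) stop("need at least one triple")
  with_seed(seed, {
    side <- ceiling(n^(1 / 3))
    centers <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                     z = seq_len(side)))[seq_len(n), , drop = FALSE] * 12
    coords <- matrix(0, 3 * n, 3)
    flags <- data.frame(element = rep(c("O", "H", "O"), n),
                        resid = rep(seq_len(n), each = 3),
                        name = rep(c("OD", "HD", "OA"), n),
                        is_donor = rep(c(TRUE, FALSE, FALSE), n),
                        is_acceptor = rep(c(FALSE, FALSE, TRUE), n),
                        is_hydrogen = rep(c(FALSE, TRUE, FALSE), n))
    for (i in seq_len(n)) {
      is_bond <- i <= k_bonds
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d_pos <- centers[i, ]
      h_pos <- d_pos + u   # 1.0 Angstrom covalent D-H
      if (is_bond) {
        theta <- stats::runif(1, 0, 30); da <- stats::runif(1, 2.6, 3.1)
      } else if ((i - k_bonds) %% 2 == 1) {
        theta <- stats::runif(1, 0, 30); da <- stats::runif(1, 3.5, 4.5)
      } else {
        theta <- stats::runif(1, 50, 80); da <- stats::runif(1, 2.6, 3.1)
      }
      v <- rotate_towards(u, theta)
      ct <- sum(u * v)
      r_ha <- -ct + sqrt(ct^2 - 1 + da^2)   # solve |u + r v| = da
      a_pos <- h_pos + r_ha * v
      coords[3 * (i - 1) + 1:3, ] <- rbind(d_pos, h_pos, a_pos)
    }
    tr <- trajectory(array(coords, c(1, 3 * n, 3),
                           dimnames = NULL), dt = 1, atoms = flags)
    attr(tr, "n_true_bonds") <- k_bonds
    tr
  })
}
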