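# QENS correction, buffer/sample fitting, EISF and transport extraction.

make_flat_spectra <- function(role, value, nq = 6, nw = 41, err = 0.1) {
  qens_spectra(role, seq(0.5, 3, length.out = nq), seq(-2, 2, length.out = nw),
               matrix(value, nq, nw), matrix(err, nq, nw))
}

test_that("background subtraction is exact and propagates errors", {
  s <- make_flat_spectra("sample", 10)
  e <- make_flat_spectra("empty", 0, err = 0)
  b <- make_flat_spectra("buffer", 3)
  # no empty, no buffer fraction: identity
  out <- subtract_background_spectra(s, e, b, buffer_fraction = 0)
  expect_equal(out$counts, s$counts)
  # sample composed exactly of empty + buffer vanishes
  e2 <- make_flat_spectra("empty", 4)
  b2 <- make_flat_spectra("buffer", 6)
  out2 <- subtract_background_spectra(s, e2, b2, buffer_fraction = 1)
  expect_true(all(out2$counts == 0))
  expect_equal(out2$errors[1, 1], sqrt(0.1^2 + 0.1^2 + 0.1^2))
  # synthetic triple: residual is the injected protein component within noise
  inst <- test_instrument()
  truth <- condition_preset("ache0wt", peak_counts = 1e5, seed = 31)
  ds <- gen_qens_dataset(truth, inst)
  resid <- subtract_background_spectra(ds$sample, ds$empty, ds$buffer, 1)
  # the buffer spectra carry the empty level too, so subtract it back once
  protein_only <- gen_qens_dataset(
    condition_preset("ache0wt", peak_counts = 1e5, seed = 31,
                     buffer_level = 0, empty_level = 0),
    inst)$sample
  i <- 6
  scale_ref <- max(protein_only$counts[i, ])
  dev <- (resid$counts[i, ] + ds$empty$counts[i, ] * 0 -
            protein_only$counts[i, ])
  expect_lt(stats::median(abs(dev)) / scale_ref, 0.05)
})

test_that("buffer interpolation is linear in concentration", {
  b0 <- make_flat_spectra("buffer", 10)
  b15 <- make_flat_spectra("buffer", 40)
  expect_equal(interpolate_buffer(b0, b15, 0)$counts, b0$counts)
  expect_equal(interpolate_buffer(b0, b15, 15)$counts, b15$counts)
  b5 <- interpolate_buffer(b0, b15, 5)
  expect_equal(b5$counts, (2 / 3) * b0$counts + (1 / 3) * b15$counts)
  expect_equal(b5$concentration, 5)
  expect_error(interpolate_buffer(b0, b15, 16), "wt")
})

test_that("vanadium normalization rescales by the vanadium integral", {
  s <- make_flat_spectra("sample", 8)
  v <- make_flat_spectra("vanadium", 2)
  out <- normalize_vanadium(s, v)
  step <- diff(s$omega_grid[1:2])
  expect_equal(out$spectra$counts[1, 1], 8 / (2 * 41 * step))
  expect_equal(rowSums(out$resolution) * step, rep(1, 6))
  # doubling vanadium at one Q halves that Q's normalized intensity
  v2 <- v; v2$counts[3, ] <- 2 * v2$counts[3, ]
  out2 <- normalize_vanadium(s, v2)
  expect_equal(out2$spectra$counts[3, ], out$spectra$counts[3, ] / 2)
  # synthetic vanadium returns the generator's Gaussian resolution width
  inst <- test_instrument()
  ds <- gen_qens_dataset(condition_preset("ache0wt", seed = 12), inst)
  nv <- normalize_vanadium(ds$sample, ds$vanadium)
  om <- inst$omega_grid
  sigma_mom <- sqrt(sum(nv$resolution[1, ] * om^2) /
                      sum(nv$resolution[1, ]))
  sigma_true <- inst$resolution_hwhm / sqrt(2 * log(2))
  expect_equal(sigma_mom, sigma_true, tolerance = 0.05)
})

test_that("buffer fitting recovers jump-diffusion and rotation exactly without noise", {
  inst <- test_instrument()
  truth <- condition_preset("ache0wt", peak_counts = Inf, seed = 1)
  ds <- gen_qens_dataset(truth, inst)
  nb <- normalize_vanadium(ds$buffer, ds$vanadium)
  bm <- fit_buffer(nb$spectra, nb$resolution)
  expect_equal(bm$jd$d_t, 0.117, tolerance = 0.01)
  expect_equal(bm$jd$tau0, 3.3, tolerance = 0.01)
  expect_equal(bm$rot_width, 0.4, tolerance = 0.01)
  expect_equal(bm$amplitude_ratio, 0.5, tolerance = 0.01)
})

test_that("buffer D_T is recovered on average under Poisson noise", {
  inst <- test_instrument()
  d_ts <- vapply(1:8, function(i) {
    truth <- condition_preset("ache0wt", peak_counts = 1e4, seed = 700 + i)
    ds <- gen_qens_dataset(truth, inst)
    nb <- normalize_vanadium(ds$buffer, ds$vanadium)
    fit_buffer(nb$spectra, nb$resolution)$jd$d_t
  }, numeric(1))
  expect_equal(mean(d_ts), 0.117, tolerance = 0.05)
})

test_that("jump-diffusion width fits honour the dip-exclusion window", {
  jd <- jump_diffusion_params(0.117, 3.3)
  q <- seq(0.4, 2, length.out = 12)
  g <- jump_diffusion_hwhm(jd, q)
  set.seed(8)
  gn <- g * (1 + rnorm(12, 0, 0.01))
  with_dip <- fit_jump_diffusion(q, gn, rep(0.002, 12),
                                 exclude_q2 = c(2, 3))
  without <- fit_jump_diffusion(q, gn, rep(0.002, 12))
  expect_equal(with_dip$d_t, 0.117, tolerance = 0.05)
  # on dip-free data the window changes nothing beyond its standard error
  expect_lt(abs(with_dip$d_t - without$d_t), without$d_t_error)
  expect_lt(abs(with_dip$tau0 - without$tau0), without$tau0_error)
  expect_error(fit_jump_diffusion(q[1:3], gn[1:3]), "4 usable")
})

test_that("noise-free sample fits reproduce every injected parameter", {
  inst <- test_instrument()
  truth <- condition_preset("ache0wt", peak_counts = Inf, seed = 1)
  out <- run_synthetic_pipeline(truth, inst)
  expect_equal(out$eisf_fit$p, 0.726, tolerance = 5e-3)
  expect_equal(out$eisf_fit$r, 2.11, tolerance = 5e-3)
  expect_equal(out$transport$d_t, 2.9, tolerance = 5e-3)
  expect_equal(out$transport$tau0, 5.5, tolerance = 5e-3)
  expect_equal(out$transport$d_r, 0.24, tolerance = 5e-3)
  expect_lt(stats::median(out$sample_fit$per_q$chi2red), 1e-3)
})

test_that("noisy sample fits have reduced chi-square near one", {
  inst <- test_instrument()
  truth <- condition_preset("ache5wt", peak_counts = 1e4, seed = 77)
  out <- run_synthetic_pipeline(truth, inst)
  chi2 <- out$sample_fit$per_q$chi2red
  expect_true(all(chi2[is.finite(chi2)] > 0.8 & chi2[is.finite(chi2)] < 2.0))
})

test_that("buffer component removal on buffer-free data shifts widths < 1 sigma", {
  inst <- test_instrument()
  truth <- condition_preset("ache0wt", peak_counts = 1e4, seed = 55,
                            buffer_level = 0)
  ds <- gen_qens_dataset(truth, inst)
  ns <- normalize_vanadium(ds$sample, ds$vanadium)
  # buffer model from a companion buffer measurement (the sample itself is
  # buffer-free)
  ds_b <- gen_qens_dataset(condition_preset("ache0wt", peak_counts = 1e4,
                                            seed = 56), inst)
  nb <- normalize_vanadium(ds_b$buffer, ds_b$vanadium)
  bm <- fit_buffer(nb$spectra, nb$resolution)
  f0 <- fit_sample(ns$spectra, bm, ns$resolution, buffer_scale = 0,
                   refine = FALSE)
  ff <- fit_sample(ns$spectra, bm, ns$resolution, buffer_scale = "free",
                   refine = FALSE)
  d <- abs(f0$per_q$hwhm_narrow - ff$per_q$hwhm_narrow)
  s <- pmax(f0$per_q$hwhm_narrow_err, ff$per_q$hwhm_narrow_err)
  ok <- f0$per_q$converged & ff$per_q$converged &
    is.finite(d) & is.finite(s) & s > 0
  expect_gte(sum(ok), 6)
  expect_gt(mean(d[ok] <= s[ok]), 0.7)
})

test_that("EISF is the elastic fraction of the sample components only", {
  tab <- data.frame(q = seq(0.5, 2, length.out = 6),
                    buffer_scale = 1,
                    elastic_amplitude = 2, elastic_err = 0.01,
                    amp_narrow = 0, amp_narrow_err = 0.01,
                    hwhm_narrow = 0.05, hwhm_narrow_err = 0.01,
                    amp_broad = 0, amp_broad_err = 0.01,
                    hwhm_broad = 0.5, hwhm_broad_err = 0.01,
                    bg_slope = 0, bg_intercept = 0.4, chi2red = 1,
                    converged = TRUE, degenerate = FALSE, at_bound = FALSE)
  sf <- structure(list(per_q = tab, per_q_eisf = NULL),
                  class = "sample_fit")
  expect_equal(compute_eisf(sf)$a0, rep(1, 6))       # no quasi-elastic part
  tab$amp_narrow <- 1.5; tab$amp_broad <- 0.5        # elastic = quasi-elastic
  sf$per_q <- tab
  expect_equal(compute_eisf(sf)$a0, rep(0.5, 6))
  # buffer scale and background never enter the denominator
  tab$buffer_scale <- 100; tab$bg_intercept <- 50
  sf$per_q <- tab
  expect_equal(compute_eisf(sf)$a0, rep(0.5, 6))
})

test_that("EISF is invariant under global intensity rescaling", {
  inst <- test_instrument()
  truth <- condition_preset("ache0wt", peak_counts = 1e4, seed = 21)
  ds <- gen_qens_dataset(truth, inst)
  nb <- normalize_vanadium(ds$buffer, ds$vanadium)
  ns <- normalize_vanadium(ds$sample, ds$vanadium)
  bm <- fit_buffer(nb$spectra, ns$resolution)
  a0_1 <- compute_eisf(fit_sample(ns$spectra, bm, ns$resolution))$a0
  k <- 5
  ns2 <- ns$spectra
  ns2$counts <- k * ns2$counts; ns2$errors <- k * ns2$errors
  bm2 <- bm
  bm2$per_q$a_n <- k * bm2$per_q$a_n; bm2$per_q$a_b <- k * bm2$per_q$a_b
  a0_2 <- compute_eisf(fit_sample(ns2, bm2, ns$resolution))$a0
  expect_equal(a0_1, a0_2, tolerance = 1e-6)
})

test_that("EISF model fitting recovers p and R and flags degenerate curves", {
  q <- seq(0.3, 2.2, length.out = 10)
  pars <- confined_rotation_params(0.5, 2, 0.1)
  curve <- list(q = q, a0 = eisf_with_immobile(pars, q),
                a0_error = rep(0.01, 10))
  fit <- fit_eisf(curve)
  expect_equal(fit$p, 0.5, tolerance = 1e-5)
  expect_equal(fit$r, 2, tolerance = 1e-4)
  expect_false(fit$flagged)
  # p -> 1: flat curve, R unidentifiable, must be flagged
  flat <- list(q = q, a0 = rep(1, 10), a0_error = rep(0.01, 10))
  expect_true(fit_eisf(flat)$flagged)
})

test_that("transport extraction halves the broad width and converts units", {
  tab <- data.frame(q = seq(0.4, 2, length.out = 8), buffer_scale = 0,
                    elastic_amplitude = 1, elastic_err = 0.01,
                    amp_narrow = 0.2, amp_narrow_err = 0.01,
                    hwhm_narrow = jump_diffusion_hwhm(
                      jump_diffusion_params(0.29, 5.5),
                      seq(0.4, 2, length.out = 8)),
                    hwhm_narrow_err = 0.001,
                    amp_broad = 0.2, amp_broad_err = 0.01,
                    hwhm_broad = 0.48, hwhm_broad_err = 0.01,
                    bg_slope = 0, bg_intercept = 0, chi2red = 1,
                    converged = TRUE, degenerate = FALSE, at_bound = FALSE)
  sf <- structure(list(per_q = tab, global = NULL), class = "sample_fit")
  tp <- fit_transport(sf)
  expect_equal(tp$d_t, 2.9, tolerance = 1e-4)    # 0.29 A^2/ps on 1e-5 cm^2/s scale
  expect_equal(tp$tau0, 5.5, tolerance = 1e-3)
  expect_equal(tp$d_r, 0.24, tolerance = 1e-6)   # Gamma_R = 2 D_R
})

test_that("the pipeline runs end to end, deterministically, from files", {
  inst <- test_instrument()
  truth <- condition_preset("ache5wt", peak_counts = 1e4, seed = 88)
  ds <- gen_qens_dataset(truth, inst)
  dir <- withr::local_tempdir()
  for (role in c("sample", "buffer", "empty", "vanadium"))
    write_qens_spectra(ds[[role]], file.path(dir, paste0(role, ".tsv")))
  cfg <- list(sample = file.path(dir, "sample.tsv"),
              buffer = file.path(dir, "buffer.tsv"),
              empty = file.path(dir, "empty.tsv"),
              vanadium = file.path(dir, "vanadium.tsv"),
              concentration = 5, label = "smoke",
              out_dir = file.path(dir, "out1"))
  rep1 <- run_pipeline(cfg)
  expect_s3_class(rep1, "qens_report")
  tp <- rep1$transport
  expect_true(all(is.finite(c(tp$d_t, tp$tau0, tp$d_r, tp$p, tp$r))))
  expect_true(file.exists(file.path(dir, "out1", "transport.tsv")))
  expect_true(file.exists(file.path(dir, "out1", "run_log.json")))
  # byte-identical outputs on a second run with identical inputs
  cfg$out_dir <- file.path(dir, "out2")
  run_pipeline(cfg)
  for (f in c("transport.tsv", "eisf.tsv", "sample_per_q.tsv",
              "run_log.json"))
    expect_identical(readLines(file.path(dir, "out1", f)),
                     readLines(file.path(dir, "out2", f)))
})

test_that("the pipeline interpolates buffers measured at the two endpoints", {
  inst <- test_instrument()
  ds5 <- gen_qens_dataset(condition_preset("ache5wt", peak_counts = 1e4,
                                           seed = 91), inst)
  ds0 <- gen_qens_dataset(condition_preset("ache0wt", peak_counts = 1e4,
                                           seed = 92), inst)
  ds15 <- gen_qens_dataset(condition_preset("buffer15wt", peak_counts = 1e4,
                                            seed = 93), inst)
  rep <- run_pipeline(list(sample = ds5$sample, buffer0 = ds0$buffer,
                           buffer15 = ds15$buffer, vanadium = ds5$vanadium,
                           concentration = 5))
  expect_s3_class(rep, "qens_report")
  # interpolated buffer transport lands between the endpoint conditions
  expect_lt(rep$buffer_model$jd$d_t, 0.125)
  expect_gt(rep$buffer_model$jd$d_t, 0.055)
})

test_that("a three-condition study reproduces the non-monotone D_T ordering", {
  inst <- test_instrument()
  d_t <- vapply(c("ache0wt", "ache5wt", "ache10wt"), function(pr) {
    truth <- condition_preset(pr, peak_counts = 1e5, seed = 321)
    run_synthetic_pipeline(truth, inst)$transport$d_t
  }, numeric(1))
  # generated D_T dips at 5 wt% (2.9 -> 2.1 -> 2.7)
  expect_lt(d_t[["ache5wt"]], d_t[["ache0wt"]])
  expect_lt(d_t[["ache5wt"]], d_t[["ache10wt"]])
})

test_that("estimates sharpen as counting statistics improve", {
  inst <- test_instrument()
  err_at <- function(pk, seeds) {
    stats::median(vapply(seeds, function(s) {
      truth <- condition_preset("ache0wt", peak_counts = pk, seed = s)
      abs(run_synthetic_pipeline(truth, inst)$eisf_fit$p - 0.726)
    }, numeric(1)))
  }
  e_low <- err_at(2e3, 901:903)
  e_high <- err_at(5e4, 901:903)
  expect_lt(e_high, e_low + 1e-6)
  expect_lt(e_high, 0.05)
})

test_that("qens spectra round-trip through the block TSV format", {
  inst <- test_instrument()
  ds <- gen_qens_dataset(condition_preset("ache0wt", seed = 2), inst)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qens_spectra(ds$buffer, path)
  back <- read_qens_spectra(path)
  expect_equal(back$role, "buffer")
  expect_equal(back$q_list, ds$buffer$q_list, tolerance = 1e-9)
  expect_equal(back$omega_grid, ds$buffer$omega_grid, tolerance = 1e-9)
  expect_equal(back$counts, ds$buffer$counts, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$temperature, 310)
})
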