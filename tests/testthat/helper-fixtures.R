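# Shared fixtures: a fast instrument profile, a pipeline driver, and a
# memoized replicate study reused by the acceptance tests.

test_instrument <- function(...) make_instrument("in6_like", ...)

# generation + correction + fits, returning every stage
run_synthetic_pipeline <- function(truth, inst = test_instrument(),
                                   buffer_scale = "measured",
                                   dip_window = c(2, 3)) {
  ds <- gen_qens_dataset(truth, inst)
  nb <- normalize_vanadium(ds$buffer, ds$vanadium)
  ns <- normalize_vanadium(ds$sample, ds$vanadium)
  bm <- fit_buffer(nb$spectra, ns$resolution, dip_window = dip_window)
  sf <- fit_sample(ns$spectra, bm, ns$resolution, buffer_scale = buffer_scale)
  ec <- compute_eisf(sf)
  ef <- fit_eisf(ec)
  tp <- fit_transport(sf, ef)
  list(ds = ds, buffer_model = bm, sample_fit = sf, eisf = ec,
       eisf_fit = ef, transport = tp)
}

# replicate study over seeds; returns a parameter x replicate matrix
replicate_recovery <- function(preset, seeds, peak_counts = 1e4, ...) {
  vapply(seeds, function(s) {
    truth <- condition_preset(preset, peak_counts = peak_counts, seed = s, ...)
    out <- run_synthetic_pipeline(truth)
    c(p = out$eisf_fit$p, p_se = out$eisf_fit$p_error,
      r = out$eisf_fit$r, r_se = out$eisf_fit$r_error,
      d_t = out$transport$d_t, tau0 = out$transport$tau0,
      d_r = out$transport$d_r)
  }, numeric(7))
}

# memoized across test_that blocks (the full pipeline is the expensive part)
.acceptance_env <- new.env(parent = emptyenv())
acceptance_reps <- function(preset, seeds, ...) {
  key <- paste(preset, paste(seeds, collapse = "-"))
  if (is.null(.acceptance_env[[key]]))
    .acceptance_env[[key]] <- replicate_recovery(preset, seeds, ...)
  .acceptance_env[[key]]
}

# brute-force oracles kept independent of the package implementations
brute_contacts <- function(a, b, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    if (sum((a[i, ] - b[j, ])^2) <= cutoff^2) n <- n + 1L
  n
}

brute_hbonds <- function(traj, d_max = 3.2, angle_max = 40) {
  xyz <- traj$coords[1, , ]
  at <- traj$atoms
  n <- 0L
  for (d in which(at$is_donor)) for (h in which(at$is_hydrogen)) {
    if (sqrt(sum((xyz[d, ] - xyz[h, ])^2)) > 1.2) next
    for (a in which(at$is_acceptor)) {
      if (a == d) next
      if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > d_max) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (180 - ang <= angle_max) n <- n + 1L
    }
  }
  n
}
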