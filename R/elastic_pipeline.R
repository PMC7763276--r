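# Elastic-scan reduction: summed intensities and Gaussian-approximation MSD.

#' Elastic temperature scan container
#'
#' Holds `S_el(Q, T)` from a fixed-window elastic scan: the elastic
#' intensity within the instrumental energy resolution, per momentum
#' transfer and temperature.
#'
#' @param q_grid Momentum transfers, 1/Angstrom, strictly increasing.
#' @param t_grid Temperatures, K, strictly increasing.
#' @param intensities Matrix `length(q_grid) x length(t_grid)`, non-negative.
#' @param errors Matching matrix of one-sigma uncertainties.
#' @param concentration Co-solute concentration, wt percent.
#' @param instrument_label Free-text instrument tag.
#' @return An object of class `"elastic_scan"`.
#' @export
elastic_scan <- function(q_grid, t_grid, intensities, errors,
                         concentration = 0, instrument_label = "custom") {
  q_grid <- as.numeric(q_grid); t_grid <- as.numeric(t_grid)
  intensities <- as.matrix(intensities); errors <- as.matrix(errors)
  if (any(diff(q_grid) <= 0) || (length(t_grid) > 1 && any(diff(t_grid) <= 0)))
    stop("q_grid and t_grid must be strictly increasing")
  if (!all(dim(intensities) == c(length(q_grid), length(t_grid))))
    stop("intensities must be length(q_grid) x length(t_grid)")
  if (!all(dim(errors) == dim(intensities)))
    stop("errors must match intensities")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (any(errors < 0)) stop("errors must be >= 0")
  structure(list(q_grid = q_grid, t_grid = t_grid,
                 intensities = intensities, errors = errors,
                 concentration = concentration,
                 instrument_label = instrument_label),
            class = "elastic_scan")
}

#' @export
print.elastic_scan <- function(x, ...) {
  cat(sprintf(
    "<elastic_scan> %s, %g wt%%: %d Q in [%.2f, %.2f] 1/A, %d T in [%g, %g] K\n",
    x$instrument_label, x$concentration, length(x$q_grid), min(x$q_grid),
    max(x$q_grid), length(x$t_grid), min(x$t_grid), max(x$t_grid)))
  invisible(x)
}

#' Q-summed elastic intensities per temperature
#'
#' Sums `S_el(Q, T)` over all available Q at each temperature, with errors
#' propagated as the root sum of squares.  The summed intensity has smaller
#' relative error than any single detector and decreases when the sample
#' becomes more mobile (larger Debye-Waller damping).
#'
#' @param scan An [elastic_scan()] object.
#' @return A data.frame with columns `temperature`, `sum`, `sum_error`.
#' @export
sum_intensities <- function(scan) {
  stopifnot(inherits(scan, "elastic_scan"))
  if (length(scan$q_grid) == 0L) stop("empty Q grid")
  data.frame(temperature = scan$t_grid,
             sum = colSums(scan$intensities),
             sum_error = sqrt(colSums(scan$errors^2)))
}

#' Mean square displacement from the Gaussian approximation
#'
#' Fits `ln S_el(Q) = ln S0 - u2 Q^2 / 3` by weighted linear regression in
#' `Q^2` at one temperature and reports `u2 = -3 * slope`.  The Gaussian
#' approximation holds for `u2 * Q^2` up to about 1, so a second pass drops
#' points with `u2_fit * Q^2 > max_u2q2` (estimated from the first-pass fit)
#' and refits; the Q^2 window actually used is reported.
#'
#' Weights are `1 / sigma_lnS^2` with `sigma_lnS = sigma_S / S`.
#' Non-positive intensities cannot be log-transformed and are excluded with
#' a warning.
#'
#' @param scan An [elastic_scan()] object.
#' @param temperature Temperature (K) to fit; must be one of `scan$t_grid`.
#' @param max_u2q2 Validity bound on `u2 * Q^2` (default 1.0).
#' @return An object of class `"msd_result"`: list with `u2`, `u2_error`
#'   (Angstrom^2), `q2_window` (range used, 1/Angstrom^2), `n_points`.
#' @export
#' @examples
#' inst <- make_instrument("in13_like")
#' scan <- gen_elastic_scan(u2_intercept = -2, u2_slope = 0.012,
#'                          instrument = inst, t_grid = seq(280, 310, 5),
#'                          noise_frac = 0, seed = 1)
#' fit_msd(scan, temperature = 300)
fit_msd <- function(scan, temperature, max_u2q2 = 1.0) {
  stopifnot(inherits(scan, "elastic_scan"))
  it <- which(abs(scan$t_grid - temperature) < 1e-9)
  if (length(it) != 1L) stop("temperature not found in scan")
  s <- scan$intensities[, it]
  e <- scan$errors[, it]
  q2 <- scan$q_grid^2
  ok <- s > 0
  if (any(!ok)) warning(sum(!ok), " non-positive intensities excluded")
  pass <- function(keep) {
    if (sum(keep) < 3L) stop("fewer than 3 usable Q points")
    w <- if (all(e[keep] > 0)) (s[keep] / e[keep])^2 else rep(1, sum(keep))
    fit <- stats::lm(log(s[keep]) ~ q2[keep], weights = w)
    sm <- summary(fit)$coefficients
    list(u2 = -3 * sm[2, 1], u2_error = 3 * sm[2, 2], keep = keep)
  }
  first <- pass(ok)
  keep2 <- ok & (max(first$u2, 0) * q2 <= max_u2q2)
  res <- if (sum(keep2) >= 3L && !identical(keep2, ok)) pass(keep2) else first
  structure(list(u2 = res$u2, u2_error = res$u2_error,
                 q2_window = range(q2[res$keep]),
                 n_points = sum(res$keep)),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> u2 = %.4f +/- %.4f A^2 (%d Q points, Q^2 in [%.3f, %.3f])\n",
              x$u2, x$u2_error, x$n_points, x$q2_window[1], x$q2_window[2]))
  invisible(x)
}

#' Read / write elastic scans as tab-separated text
#'
#' Format: comment headers `# instrument <label>` and
#' `# concentration_wt_pct <value>`, then a header row `Q T1 err_T1 T2
#' err_T2 ...` (temperatures in K) and one row per Q with interleaved
#' intensity and error columns.
#'
#' @param path File path.
#' @return `read_elastic_scan` returns an [elastic_scan()];
#'   `write_elastic_scan` returns `path` invisibly.
#' @export
read_elastic_scan <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  inst <- sub("^#\\s*instrument\\s+", "", grep("^#\\s*instrument", hdr, value = TRUE)[1])
  conc <- as.numeric(sub("^#\\s*concentration_wt_pct\\s+", "",
                         grep("^#\\s*concentration_wt_pct", hdr, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  head_fields <- strsplit(body[1], "\t")[[1]]
  t_grid <- as.numeric(head_fields[seq(2, length(head_fields), by = 2)])
  dat <- do.call(rbind, lapply(body[-1], function(l) as.numeric(strsplit(l, "\t")[[1]])))
  q_grid <- dat[, 1]
  idx <- seq(2, ncol(dat), by = 2)
  elastic_scan(q_grid, t_grid, dat[, idx, drop = FALSE],
               dat[, idx + 1, drop = FALSE],
               concentration = ifelse(is.na(conc), 0, conc),
               instrument_label = ifelse(is.na(inst), "unknown", inst))
}

#' @rdname read_elastic_scan
#' @param scan An [elastic_scan()] object to write.
#' @export
write_elastic_scan <- function(scan, path) {
  stopifnot(inherits(scan, "elastic_scan"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# instrument", scan$instrument_label),
               paste("# concentration_wt_pct", scan$concentration)), con)
  hdr <- c("Q", as.vector(rbind(format(scan$t_grid),
                                paste0("err_", format(scan$t_grid)))))
  writeLines(paste(hdr, collapse = "\t"), con)
  for (i in seq_along(scan$q_grid)) {
    row <- c(scan$q_grid[i],
             as.vector(rbind(scan$intensities[i, ], scan$errors[i, ])))
    writeLines(paste(format(row, digits = 10), collapse = "\t"), con)
  }
  invisible(path)
}
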