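# Tab-separated text formats for QENS spectra and pipeline outputs.

#' Read / write QENS spectra as tab-separated text
#'
#' One file per measurement: comment headers `# role`, `#
#' concentration_wt_pct`, `# temperature_K`, then one block per momentum
#' transfer introduced by `# Q = <value>` with three columns `omega_meV`,
#' `counts`, `error`.
#'
#' @param path File path.
#' @return `read_qens_spectra` returns a [qens_spectra()];
#'   `write_qens_spectra` returns `path` invisibly.
#' @export
read_qens_spectra <- function(path) {
  lines <- readLines(path)
  get_hdr <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\s"), lines, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s+"), "", m[1]))
  }
  role <- get_hdr("role", "sample")
  conc <- as.numeric(get_hdr("concentration_wt_pct", "0"))
  temp <- as.numeric(get_hdr("temperature_K", "310"))
  qlines <- grep("^#\\s*Q\\s*=", lines)
  if (!length(qlines)) stop("no '# Q =' blocks found in ", path)
  q_list <- as.numeric(sub("^#\\s*Q\\s*=\\s*", "", lines[qlines]))
  bounds <- c(qlines, length(lines) + 1L)
  blocks <- lapply(seq_along(qlines), function(i) {
    blk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    blk <- blk[!grepl("^#", blk) & nzchar(trimws(blk))]
    do.call(rbind, lapply(strsplit(trimws(blk), "\\s+"),
                          function(f) as.numeric(f[1:3])))
  })
  omega <- blocks[[1]][, 1]
  counts <- t(vapply(blocks, function(b) b[, 2], numeric(length(omega))))
  errors <- t(vapply(blocks, function(b) b[, 3], numeric(length(omega))))
  qens_spectra(role, q_list, omega, counts, errors, conc, temp)
}

#' @rdname read_qens_spectra
#' @param spectra A [qens_spectra()] object to write.
#' @export
write_qens_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "qens_spectra"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# role", spectra$role),
               paste("# concentration_wt_pct", spectra$concentration),
               paste("# temperature_K", spectra$temperature)), con)
  for (i in seq_along(spectra$q_list)) {
    writeLines(sprintf("# Q = %.10g", spectra$q_list[i]), con)
    writeLines(sprintf("%.10g\t%.10g\t%.10g", spectra$omega_grid,
                       spectra$counts[i, ], spectra$errors[i, ]), con)
  }
  invisible(path)
}

#' Run the complete QENS analysis pipeline
#'
#' Correction (optional empty-cell subtraction, optional buffer
#' interpolation, vanadium normalization), buffer fitting, constrained
#' sample fitting, EISF extraction and fitting, and transport-parameter
#' estimation, with optional tabular output.
#'
#' By default the empty cell is not subtracted bin by bin: its flat
#' spectrum is absorbed exactly by the fitted backgrounds, which avoids
#' injecting its counting noise and the downward clipping of
#' noise-negative bins.  The buffer is likewise handled inside the sample
#' fit with its amplitude measured from the buffer-only run (see
#' [fit_sample()]); set `subtract_empty = TRUE` and/or
#' `buffer_scale = "free"` for the subtraction-style workflow.
#'
#' @param config Named list:
#'   \describe{
#'     \item{sample, empty, vanadium}{[qens_spectra()] objects or file paths
#'       readable by [read_qens_spectra()].  `empty` may be omitted when
#'       `subtract_empty` is FALSE.}
#'     \item{buffer}{Buffer spectra at the sample concentration, or omit and
#'       give `buffer0`/`buffer15` for interpolation.}
#'     \item{buffer0, buffer15}{Buffers at the two measured concentrations;
#'       interpolated to `concentration` when `buffer` is absent.}
#'     \item{concentration}{Target concentration, wt percent.}
#'     \item{dip_window}{Q^2 exclusion window for the buffer narrow-width
#'       fit; default `c(2, 3)`. `NULL` disables.}
#'     \item{subtract_empty}{Subtract the empty-cell spectrum bin by bin
#'       before fitting (default FALSE).}
#'     \item{buffer_scale, displacement}{Passed to [fit_sample()]; defaults
#'       `"measured"` and 1.}
#'     \item{out_dir}{Optional directory for result tables and a JSON run
#'       log.}
#'     \item{label}{Run label recorded in the log.}
#'   }
#' @return List of class `"qens_report"`: `buffer_model`, `sample_fit`,
#'   `eisf`, `eisf_fit`, `transport`, `config_summary`.
#' @export
run_pipeline <- function(config) {
  as_spectra <- function(x) {
    if (is.character(x)) read_qens_spectra(x) else x
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  opt <- function(name, default) {
    if (name %in% names(config)) config[[name]] else default
  }
  sample <- stage("inputs", as_spectra(config$sample))
  vanadium <- stage("inputs", as_spectra(config$vanadium))
  buffer <- stage("inputs", {
    if (!is.null(config$buffer)) as_spectra(config$buffer)
    else interpolate_buffer(as_spectra(config$buffer0),
                            as_spectra(config$buffer15),
                            config$concentration)
  })
  dip_window <- opt("dip_window", c(2, 3))
  subtract_empty <- opt("subtract_empty", FALSE)
  buffer_scale <- opt("buffer_scale", "measured")
  displacement <- opt("displacement", 1)

  corr <- stage("correction", {
    if (subtract_empty) {
      empty <- as_spectra(config$empty)
      zero <- empty
      zero$counts[] <- 0; zero$errors[] <- 0
      sample <- subtract_background_spectra(sample, empty, zero, 0)
      b <- subtract_background_spectra(buffer, empty, zero, 0)
      b$role <- "buffer"
      buffer <- b
    }
    ns <- normalize_vanadium(sample, vanadium)
    nb <- normalize_vanadium(buffer, vanadium)
    list(sample = ns$spectra, buffer = nb$spectra,
         resolution = ns$resolution)
  })
  buffer_model <- stage("buffer_fit",
                        fit_buffer(corr$buffer, corr$resolution,
                                   dip_window = dip_window))
  sample_fit <- stage("sample_fit",
                      fit_sample(corr$sample, buffer_model, corr$resolution,
                                 buffer_scale = buffer_scale,
                                 displacement = displacement))
  eisf <- stage("eisf", compute_eisf(sample_fit))
  eisf_fit <- stage("eisf_fit", fit_eisf(eisf))
  transport <- stage("transport", fit_transport(sample_fit, eisf_fit))

  report <- structure(
    list(buffer_model = buffer_model, sample_fit = sample_fit, eisf = eisf,
         eisf_fit = eisf_fit, transport = transport,
         config_summary = list(
           concentration = sample$concentration,
           temperature = sample$temperature,
           dip_window = dip_window,
           subtract_empty = subtract_empty,
           buffer_scale = if (is.numeric(buffer_scale)) "fixed"
                          else buffer_scale,
           label = if (is.null(config$label)) "run" else config$label)),
    class = "qens_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.qens_report <- function(x, ...) {
  cat(sprintf("<qens_report> '%s' (%g wt%%)\n", x$config_summary$label,
              x$config_summary$concentration))
  print(x$buffer_model)
  print(x$sample_fit)
  print(x$transport)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtab <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wtab(report$buffer_model$per_q, "buffer_per_q.tsv")
  wtab(report$sample_fit$per_q, "sample_per_q.tsv")
  wtab(data.frame(q = report$eisf$q, a0 = report$eisf$a0,
                  a0_error = report$eisf$a0_error), "eisf.tsv")
  tp <- report$transport
  wtab(data.frame(parameter = c("D_T_1e-5cm2s", "tau0_ps", "D_R_meV",
                                "p", "R_A"),
                  value = c(tp$d_t, tp$tau0, tp$d_r, tp$p, tp$r),
                  error = c(tp$d_t_error, tp$tau0_error, tp$d_r_error,
                            tp$p_error, tp$r_error)),
       "transport.tsv")
  log <- list(label = report$config_summary$label,
              concentration = report$config_summary$concentration,
              temperature = report$config_summary$temperature,
              dip_window = report$config_summary$dip_window,
              package_version = as.character(utils::packageVersion("osmoqens")),
              buffer = list(d_t = report$buffer_model$jd$d_t,
                            tau0 = report$buffer_model$jd$tau0,
                            rot_width = report$buffer_model$rot_width,
                            amplitude_ratio = report$buffer_model$amplitude_ratio),
              transport = list(d_t = tp$d_t, tau0 = tp$tau0, d_r = tp$d_r,
                               p = tp$p, r = tp$r))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
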