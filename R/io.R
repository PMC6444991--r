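# delimited-text I/O: comma-separated, UTF-8, '.' decimal, '#' metadata lines

parse_metadata <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      meta[[trimws(kv[1])]] <- if (is.na(val)) trimws(kv[2]) else val
    }
  }
  meta
}

#' Write a transient curve to delimited text
#'
#' Comma-separated columns `time_s`, `delta_T_K`, preceded by `#key = value`
#' metadata lines carrying the baseline temperature and, when a
#' [sensor_config()] is supplied, the actuation geometry and power. Files
#' round-trip losslessly through [read_transient()] at full double precision.
#'
#' @param curve [transient_curve()].
#' @param path Output file path.
#' @param cfg Optional [sensor_config()] recorded in the metadata block.
#' @return `path`, invisibly.
#' @export
write_transient <- function(curve, path, cfg = NULL) {
  stopifnot(inherits(curve, "transient_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# T_inf_K = %.17g", curve$T_inf), con)
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "sensor_config"))
    writeLines(sprintf("# power_W = %.17g", cfg$power), con)
    writeLines(sprintf("# true_radius_mm = %.17g", cfg$true_radius), con)
    writeLines(sprintf("# effective_radius_mm = %.17g", cfg$effective_radius), con)
    writeLines(sprintf("# duration_s = %.17g", cfg$duration), con)
  }
  writeLines("time_s,delta_T_K", con)
  writeLines(sprintf("%.17g,%.17g", curve$times, curve$delta_T), con)
  invisible(path)
}

#' Read a transient curve from delimited text
#'
#' Parses the format written by [write_transient()]. Schema violations
#' (missing columns, non-monotone time) raise an error naming the offending
#' row. When the metadata block carries the actuation settings, the
#' reconstructed [sensor_config()] is attached as attribute `config`.
#'
#' @param path Input file path.
#' @return [transient_curve()], possibly with a `config` attribute.
#' @export
read_transient <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("file not found: %s", path))
  meta <- parse_metadata(path)
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = ",", comment.char = "#"),
    error = function(e) schema_error(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  need <- c("time_s", "delta_T_K")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    schema_error(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  T_inf <- if (!is.null(meta$T_inf_K)) meta$T_inf_K else 306.15
  curve <- transient_curve(tab$time_s, tab$delta_T_K, T_inf = T_inf)
  if (!is.null(meta$power_W) && !is.null(meta$true_radius_mm)) {
    attr(curve, "config") <- sensor_config(
      true_radius = meta$true_radius_mm,
      effective_radius = if (!is.null(meta$effective_radius_mm)) {
        meta$effective_radius_mm
      } else {
        meta$true_radius_mm
      },
      power = meta$power_W,
      duration = if (!is.null(meta$duration_s)) meta$duration_s else max(tab$time_s)
    )
  }
  curve
}

#' Write an impedance spectrum to delimited text
#'
#' Columns `freq_hz`, `z_real_ohm`, `z_imag_ohm`.
#'
#' @param spectrum [impedance_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# drive_voltage_Vpp = %.17g", spectrum$drive_voltage), con)
  writeLines("freq_hz,z_real_ohm,z_imag_ohm", con)
  writeLines(sprintf(
    "%.17g,%.17g,%.17g", spectrum$frequencies,
    Re(spectrum$impedance), Im(spectrum$impedance)
  ), con)
  invisible(path)
}

#' Read an impedance spectrum from delimited text
#'
#' @param path Input file path in the [write_spectrum()] format.
#' @param instrument Validate against the instrument band.
#' @return [impedance_spectrum()].
#' @export
read_spectrum <- function(path, instrument = FALSE) {
  if (!file.exists(path)) schema_error(sprintf("file not found: %s", path))
  meta <- parse_metadata(path)
  tab <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  need <- c("freq_hz", "z_real_ohm", "z_imag_ohm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    schema_error(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  impedance_spectrum(
    tab$freq_hz, complex(real = tab$z_real_ohm, imaginary = tab$z_imag_ohm),
    drive_voltage = if (!is.null(meta$drive_voltage_Vpp)) meta$drive_voltage_Vpp else 2,
    instrument = instrument
  )
}
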