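# Plain-text readers/writers for the formats the pipeline exchanges:
# 2-column CSVs for spectra, decays, melts, titrations and i/V data, and
# JSON for fit records and run reports.

#' Read a decay histogram CSV
#'
#' Format: optional `# channel=parallel|perpendicular|magic_angle` comment
#' line, then header `time_ns,counts`.
#'
#' @param path file path.
#' @param channel override the channel recorded in the file.
#' @return a [decay_histogram()].
#' @export
read_decay_csv <- function(path, channel = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(channel)) {
    channel <- if (grepl("^#\\s*channel=", first))
      sub("^#\\s*channel=\\s*", "", trimws(first)) else "magic_angle"
  }
  df <- utils::read.csv(path, comment.char = "#")
  check_that(all(c("time_ns", "counts") %in% names(df)),
             "decay CSV needs columns time_ns,counts")
  decay_histogram(df$time_ns, df$counts, channel)
}

#' Write a decay histogram CSV
#'
#' @param hist a [decay_histogram()].
#' @param path output path.
#' @export
write_decay_csv <- function(hist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel=%s", hist$channel), con)
  utils::write.csv(data.frame(time_ns = hist$time_ns, counts = hist$counts),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum CSV (`wavelength_nm,value`)
#'
#' @param path file path.
#' @param type `"emission"` or `"absorption"`.
#' @return an [emission_spectrum()] or [absorption_spectrum()].
#' @export
read_spectrum_csv <- function(path, type = c("emission", "absorption")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, comment.char = "#")
  check_that(ncol(df) >= 2, "spectrum CSV needs two columns")
  if (type == "emission") emission_spectrum(df[[1]], df[[2]])
  else absorption_spectrum(df[[1]], df[[2]])
}

#' Read a melt curve CSV (`temperature_C,signal`)
#'
#' @param path file path.
#' @param ligand_conc_M ligand concentration of the sample, M.
#' @return a [melt_curve()].
#' @export
read_melt_csv <- function(path, ligand_conc_M = 0) {
  df <- utils::read.csv(path, comment.char = "#")
  check_that(all(c("temperature_C", "signal") %in% names(df)),
             "melt CSV needs columns temperature_C,signal")
  melt_curve(df$temperature_C, df$signal, ligand_conc_M)
}

#' Read a titration CSV (`conc_M,value[,stderr]`)
#'
#' @param path file path.
#' @param observable observable name, see [titration_series()].
#' @return a [titration_series()].
#' @export
read_titration_csv <- function(path, observable) {
  df <- utils::read.csv(path, comment.char = "#")
  check_that(all(c("conc_M", "value") %in% names(df)),
             "titration CSV needs columns conc_M,value")
  titration_series(df$conc_M, df$value, observable,
                   stderr = if ("stderr" %in% names(df)) df$stderr)
}

#' Read an i/V CSV (`voltage_mV,current_pA`)
#'
#' @param path file path.
#' @return an [iv_series()].
#' @export
read_iv_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_that(all(c("voltage_mV", "current_pA") %in% names(df)),
             "i/V CSV needs columns voltage_mV,current_pA")
  iv_series(df$voltage_mV, df$current_pA)
}

#' Write a run report (or any fit record) as JSON
#'
#' @param report a list.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       force = TRUE)
  invisible(path)
}
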