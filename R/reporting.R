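#' Repeatability summary of a measurement series
#'
#' Mean, sample standard deviation and coefficient of variation, the
#' repeatability statistics reported for dispensed volumes and spectral
#' intensities. The SD uses the `n - 1` (sample) denominator; the CV is
#' `100 * sd / mean` in percent.
#'
#' @param values Numeric measurements, at least two.
#' @return An object of class `run_summary` with fields `n`, `mean`, `sd`
#'   and `cv_percent` (`NA` when the mean is 0), all at full precision;
#'   the print method rounds to two decimals.
#' @export
#' @examples
#' summarize_measurements(c(13.15, 12.89, 13.12, 13.21))
summarize_measurements <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` contains missing data", call. = FALSE)
  n <- length(values)
  if (n < 2) {
    stop("need at least two values for the SD and CV", call. = FALSE)
  }
  m <- mean(values)
  s <- sd(values)
  structure(list(n = n, mean = m, sd = s,
                 cv_percent = if (m != 0) 100 * s / m else NA_real_),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> n = %d, mean %.2f, SD %.2f, CV %.2f%%\n",
              x$n, x$mean, x$sd, x$cv_percent))
  invisible(x)
}

#' @export
as.list.run_summary <- function(x, ...) {
  list(n = x$n, mean = x$mean, sd = x$sd, cv_percent = x$cv_percent)
}

#' Packaged repeatability tables
#'
#' Transcribed measurement series shipped with the package: `"volumes"` —
#' ten repeat dispenses per dipping depth at 100 mm/s; `"areas"` — ten
#' pixel areas per fluid at 1000 mm/s, 3 mm; `"chip"` — per-spot spectral
#' intensities and volumes of a dispensed chip at the 100 nL setpoint.
#'
#' @param which One of `"volumes"`, `"areas"`, `"chip"`.
#' @return A data frame.
#' @export
#' @examples
#' summarize_measurements(repeatability_table("volumes")$depth_2)
repeatability_table <- function(which = c("volumes", "areas", "chip")) {
  which <- match.arg(which)
  file <- switch(which, volumes = "table2.csv", areas = "table4.csv",
                 chip = "table7.csv")
  read.csv(pindrop_extdata(file), check.names = FALSE)
}
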