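#' Acquisition-chain configuration
#'
#' Bundles every physical and algorithmic constant of the read-out chain:
#' the linear conductance calibration of the force-sensing resistors, the
#' voltage-divider constants, ADC resolution, datasheet accuracy, sampling
#' cadence and filter queue length.
#'
#' The defaults are the constants of the reference acquisition chain: a
#' calibration of 0.950 uS per newton with a 9.848 uS zero-force intercept, a
#' 3.3 V supply, a 100 uS fixed divider conductance, a 10-bit ADC, 2.5%
#' relative accuracy, a 500 ms sampling interval and a 5-entry filter queue.
#'
#' @param cal_slope Calibration slope, conductance per unit force (uS/N).
#'   The calibration pair is configurable so that a fit in other units (e.g.
#'   kgf) can be swapped in; the detector is unit-free after normalization.
#' @param cal_intercept Conductance at zero force (uS).
#' @param supply_voltage DC bias voltage of the divider (V).
#' @param ref_conductance Conductance of the fixed divider resistor (uS).
#' @param adc_bits ADC resolution in bits (1--16).
#' @param accuracy_fraction Relative datasheet accuracy of a force reading
#'   (dimensionless, e.g. 0.025 for 2.5%). Converted to a standard type-B
#'   uncertainty as `accuracy_fraction * force / sqrt(3)` (uniform
#'   distribution assumption).
#' @param sampling_interval Time between frames in seconds.
#' @param queue_length Moving-average window / circular queue capacity.
#' @param min_seated_force Smallest per-sensor reference force (N) accepted at
#'   initialization; guards against an unoccupied seat or a dead sensor.
#' @param uncertainty_propagation How the five per-reading uncertainties
#'   combine into the uncertainty of the moving average: `"sum"` (default)
#'   is the root-sum-square `sqrt(sum(u_i^2))`, the conservative rule of the
#'   reference device; `"mean"` is the standard propagation for an unweighted
#'   mean, `sqrt(sum(u_i^2)) / n`. See the package vignette for why `"sum"`
#'   is the default.
#' @param propagate_reference_uncertainty If `TRUE`, the uncertainty of the
#'   initialization reference is combined (in quadrature) into the normalized
#'   bounds; by default the reference is treated as an exact scale factor.
#' @param saturation_margin Voltage margin below the supply voltage at which a
#'   reading is declared saturated. Default: one ADC count-width.
#' @param session_limit_hours Soft cap on session duration (hours); monitoring
#'   stops with an expiry notification once exceeded. Sessions are meant to be
#'   short enough (about 2 h) that sensor drift within one session is
#'   negligible, the reference being re-acquired each session.
#'
#' @return An object of class `readout_config` (a validated named list).
#' @examples
#' cfg <- readout_config()
#' cfg$cal_intercept
#' @export
readout_config <- function(cal_slope = 0.950,
                           cal_intercept = 9.848,
                           supply_voltage = 3.3,
                           ref_conductance = 100,
                           adc_bits = 10L,
                           accuracy_fraction = 0.025,
                           sampling_interval = 0.5,
                           queue_length = 5L,
                           min_seated_force = 10,
                           uncertainty_propagation = c("sum", "mean"),
                           propagate_reference_uncertainty = FALSE,
                           saturation_margin = NULL,
                           session_limit_hours = 2) {
  uncertainty_propagation <- match.arg(uncertainty_propagation)
  stopifnot_scalar_number(cal_slope, "cal_slope", 0, strict = TRUE)
  stopifnot_scalar_number(cal_intercept, "cal_intercept", 0)
  stopifnot_scalar_number(supply_voltage, "supply_voltage", 0, strict = TRUE)
  stopifnot_scalar_number(ref_conductance, "ref_conductance", 0, strict = TRUE)
  if (!is.numeric(adc_bits) || length(adc_bits) != 1L ||
      adc_bits != as.integer(adc_bits) || adc_bits < 1L || adc_bits > 16L) {
    seat_abort("`adc_bits` must be an integer in 1..16", "seatsense_value_error")
  }
  stopifnot_scalar_number(accuracy_fraction, "accuracy_fraction", 0, strict = TRUE)
  if (accuracy_fraction >= 1) {
    seat_abort("`accuracy_fraction` must be < 1", "seatsense_value_error")
  }
  stopifnot_scalar_number(sampling_interval, "sampling_interval", 0, strict = TRUE)
  if (!is.numeric(queue_length) || length(queue_length) != 1L ||
      queue_length != as.integer(queue_length) || queue_length < 1L) {
    seat_abort("`queue_length` must be an integer >= 1", "seatsense_value_error")
  }
  stopifnot_scalar_number(min_seated_force, "min_seated_force", 0, strict = TRUE)
  stopifnot_scalar_number(session_limit_hours, "session_limit_hours", 0, strict = TRUE)
  if (is.null(saturation_margin)) {
    saturation_margin <- supply_voltage / (2^adc_bits - 1)
  }
  stopifnot_scalar_number(saturation_margin, "saturation_margin", 0, strict = TRUE)

  structure(list(
    cal_slope = cal_slope,
    cal_intercept = cal_intercept,
    supply_voltage = supply_voltage,
    ref_conductance = ref_conductance,
    adc_bits = as.integer(adc_bits),
    accuracy_fraction = accuracy_fraction,
    sampling_interval = sampling_interval,
    queue_length = as.integer(queue_length),
    min_seated_force = min_seated_force,
    uncertainty_propagation = uncertainty_propagation,
    propagate_reference_uncertainty = isTRUE(propagate_reference_uncertainty),
    saturation_margin = saturation_margin,
    session_limit_hours = session_limit_hours
  ), class = "readout_config")
}

#' @export
print.readout_config <- function(x, ...) {
  cat("<readout_config>\n")
  cat(sprintf("  calibration: G = %.3f * F + %.3f uS\n", x$cal_slope, x$cal_intercept))
  cat(sprintf("  divider: %.3g V supply, %.4g uS reference, %d-bit ADC\n",
              x$supply_voltage, x$ref_conductance, x$adc_bits))
  cat(sprintf("  accuracy: %.3g%% (type-B, uniform)\n", 100 * x$accuracy_fraction))
  cat(sprintf("  sampling: %.3g s, queue length %d, propagation '%s'\n",
              x$sampling_interval, x$queue_length, x$uncertainty_propagation))
  invisible(x)
}

.config_numeric_keys <- c(
  "cal_slope", "cal_intercept", "supply_voltage", "ref_conductance",
  "adc_bits", "accuracy_fraction", "sampling_interval", "queue_length",
  "min_seated_force", "saturation_margin", "session_limit_hours"
)

#' Read a read-out configuration from a flat key-value file
#'
#' The file format is one `key = value` (or `key: value`) pair per line;
#' blank lines and lines starting with `#` are ignored. Keys are the fields
#' of [readout_config()]; unknown keys are an error. Keys not present keep
#' their defaults.
#'
#' @param path Path to the configuration file.
#' @return A `readout_config`.
#' @seealso [write_readout_config()]
#' @export
read_readout_config <- function(path) {
  if (!file.exists(path)) {
    seat_abort(sprintf("config file not found: %s", path), "seatsense_value_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) != 3L) {
      seat_abort(sprintf("malformed config line: '%s'", ln), "seatsense_value_error")
    }
    key <- m[2]; val <- m[3]
    if (key %in% .config_numeric_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        seat_abort(sprintf("config key '%s' has non-numeric value '%s'", key, val),
                   "seatsense_value_error")
      }
      args[[key]] <- num
    } else if (key == "uncertainty_propagation") {
      args[[key]] <- val
    } else if (key == "propagate_reference_uncertainty") {
      args[[key]] <- toupper(val) %in% c("TRUE", "T", "1", "YES")
    } else {
      seat_abort(sprintf("unknown config key '%s'", key), "seatsense_value_error")
    }
  }
  do.call(readout_config, args)
}

#' Write a read-out configuration to a flat key-value file
#'
#' @param cfg A `readout_config`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_readout_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "readout_config"))
  keys <- setdiff(names(cfg), NULL)
  fmt <- vapply(keys, function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 15))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}
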