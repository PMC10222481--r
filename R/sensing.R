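#' Convert ADC counts to a measured voltage
#'
#' Maps a raw ADC code to the voltage across the fixed divider resistor.
#' The full-scale code (`2^adc_bits - 1`) maps exactly to the supply voltage.
#'
#' @param counts Integer ADC code(s), `0 <= counts <= 2^adc_bits - 1`.
#' @param cfg A [readout_config()].
#' @return Voltage(s) in volts.
#' @examples
#' cfg <- readout_config()
#' counts_to_voltage(511, cfg)
#' @export
counts_to_voltage <- function(counts, cfg) {
  stopifnot(inherits(cfg, "readout_config"))
  max_count <- 2^cfg$adc_bits - 1
  if (length(counts) == 0L || !is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts > max_count)) {
    seat_abort(sprintf("ADC counts outside [0, %d]: corrupt frame", max_count),
               "seatsense_range_error")
  }
  counts * cfg$supply_voltage / max_count
}

#' Convert a divider voltage to sensor conductance
#'
#' Inverts the voltage-divider relation: with a fixed resistor of conductance
#' `G` in series with the sensor under supply `V_DC`, the sensor conductance
#' is `G * V_m / (V_DC - V_m)`. Voltages at or above the saturation margin
#' below the supply indicate a shorted sensor or an invalid frame and raise a
#' saturation error.
#'
#' @param v_m Measured voltage(s) across the fixed resistor (V).
#' @param cfg A [readout_config()].
#' @return Sensor conductance(s) in the same unit as `cfg$ref_conductance`
#'   (uS by default).
#' @examples
#' cfg <- readout_config()
#' voltage_to_conductance(1.65, cfg)  # half supply -> reference conductance
#' @export
voltage_to_conductance <- function(v_m, cfg) {
  stopifnot(inherits(cfg, "readout_config"))
  if (length(v_m) == 0L || !is.numeric(v_m) || any(!is.finite(v_m)) || any(v_m < 0)) {
    seat_abort("measured voltage must be finite and >= 0", "seatsense_range_error")
  }
  limit <- cfg$supply_voltage - cfg$saturation_margin
  if (any(v_m > limit + 1e-12)) {
    seat_abort(sprintf("measured voltage within %.4g V of the supply: sensor saturated",
                       cfg$saturation_margin),
               "seatsense_saturation_error")
  }
  cfg$ref_conductance * v_m / (cfg$supply_voltage - v_m)
}

#' Convert sensor conductance to applied force
#'
#' Inverts the linear calibration `G = cal_slope * F + cal_intercept`.
#' Conductances below the intercept correspond to an unloaded sensor outside
#' the fitted range; the force is clamped to 0 N and flagged via the
#' `"clamped"` attribute rather than reported negative.
#'
#' @param g Sensor conductance(s) (uS).
#' @param cfg A [readout_config()].
#' @return Force(s) in newtons, with a logical attribute `clamped` marking
#'   below-calibration-range inputs.
#' @examples
#' cfg <- readout_config()
#' conductance_to_force(10.798, cfg)  # 1 N
#' @export
conductance_to_force <- function(g, cfg) {
  stopifnot(inherits(cfg, "readout_config"))
  if (length(g) == 0L || !is.numeric(g) || any(!is.finite(g)) || any(g < 0)) {
    seat_abort("conductance must be finite and >= 0", "seatsense_value_error")
  }
  f <- (g - cfg$cal_intercept) / cfg$cal_slope
  clamped <- f < 0
  f[clamped] <- 0
  attr(f, "clamped") <- clamped
  f
}

#' Convert applied force to sensor conductance
#'
#' The forward calibration `G = cal_slope * F + cal_intercept`; exact inverse
#' of [conductance_to_force()] on the loaded range. Used by the simulator's
#' forward signal path.
#'
#' @param f Force(s) in newtons, `>= 0`.
#' @param cfg A [readout_config()].
#' @return Conductance(s) (uS).
#' @export
force_to_conductance <- function(f, cfg) {
  stopifnot(inherits(cfg, "readout_config"))
  if (length(f) == 0L || !is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    seat_abort("force must be finite and >= 0", "seatsense_value_error")
  }
  cfg$cal_slope * f + cfg$cal_intercept
}

#' Type-B standard uncertainty of a force reading
#'
#' The datasheet accuracy `a = accuracy_fraction * F` is converted to a
#' standard uncertainty as `a / sqrt(3)`, the usual uniform-distribution
#' assumption for a type-B evaluation.
#'
#' @param f Force reading(s) in newtons, `>= 0`.
#' @param cfg A [readout_config()].
#' @return Standard uncertainty(ies) in newtons.
#' @examples
#' type_b_uncertainty(100, readout_config())
#' @export
type_b_uncertainty <- function(f, cfg) {
  stopifnot(inherits(cfg, "readout_config"))
  if (length(f) == 0L || !is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    seat_abort("force must be finite and >= 0", "seatsense_value_error")
  }
  cfg$accuracy_fraction * f / sqrt(3)
}

#' Construct a raw four-sensor sample
#'
#' One acquisition tick: four ADC counts keyed by seat position (`Lt`
#' top-left, `Lb` bottom-left, `Rt` top-right, `Rb` bottom-right).
#'
#' @param tick_index Tick number, `>= 0`; wall time is derived as
#'   `tick_index * sampling_interval`.
#' @param counts Numeric vector of four ADC counts, either named by sensor or
#'   in canonical `Lt, Lb, Rt, Rb` order.
#' @param cfg Optional [readout_config()] used to derive the timestamp and to
#'   range-check the counts.
#' @return An object of class `raw_sample`.
#' @export
raw_sample <- function(tick_index, counts, cfg = NULL) {
  if (!is.numeric(tick_index) || length(tick_index) != 1L || tick_index < 0 ||
      tick_index != as.integer(tick_index)) {
    seat_abort("`tick_index` must be a single integer >= 0", "seatsense_value_error")
  }
  if (length(counts) != 4L || !is.numeric(counts) || any(!is.finite(counts))) {
    seat_abort("`counts` must be four finite numbers", "seatsense_value_error")
  }
  if (is.null(names(counts))) {
    names(counts) <- SEAT_SENSORS
  } else if (!setequal(names(counts), SEAT_SENSORS)) {
    seat_abort("`counts` names must be Lt, Lb, Rt, Rb", "seatsense_value_error")
  }
  counts <- counts[SEAT_SENSORS]
  if (any(counts < 0)) {
    seat_abort("ADC counts must be >= 0", "seatsense_range_error")
  }
  ts <- NA_real_
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "readout_config"))
    if (any(counts > 2^cfg$adc_bits - 1)) {
      seat_abort("ADC counts above full scale", "seatsense_range_error")
    }
    ts <- tick_index * cfg$sampling_interval
  }
  structure(list(tick_index = as.integer(tick_index),
                 timestamp = ts,
                 counts = counts),
            class = "raw_sample")
}

#' Convert one raw sample to four force readings
#'
#' Applies, per sensor, counts -> voltage -> conductance -> force and attaches
#' the type-B uncertainty. Saturated sensors raise an error naming the
#' offending sensor(s).
#'
#' @param sample A [raw_sample()].
#' @param cfg A [readout_config()].
#' @return A data frame with one row per sensor and columns `sensor`, `value`
#'   (N), `uncertainty` (N), `clamped` (below-calibration-range flag) and
#'   `tick_index`.
#' @export
sample_to_readings <- function(sample, cfg) {
  stopifnot(inherits(sample, "raw_sample"), inherits(cfg, "readout_config"))
  counts <- sample$counts
  max_count <- 2^cfg$adc_bits - 1
  bad <- !is.finite(counts) | counts < 0 | counts > max_count
  if (any(bad)) {
    seat_abort(sprintf("corrupt frame: counts out of range on sensor(s) %s",
                       paste(names(counts)[bad], collapse = ", ")),
               "seatsense_range_error")
  }
  v <- counts * cfg$supply_voltage / max_count
  sat <- v > cfg$supply_voltage - cfg$saturation_margin + 1e-12
  if (any(sat)) {
    seat_abort(sprintf("sensor(s) %s saturated (voltage at supply rail)",
                       paste(names(counts)[sat], collapse = ", ")),
               "seatsense_saturation_error")
  }
  g <- cfg$ref_conductance * v / (cfg$supply_voltage - v)
  f <- (g - cfg$cal_intercept) / cfg$cal_slope
  clamped <- f < 0
  f[clamped] <- 0
  u <- cfg$accuracy_fraction * f / sqrt(3)
  data.frame(sensor = names(counts),
             value = unname(f),
             uncertainty = unname(u),
             clamped = unname(clamped),
             tick_index = sample$tick_index,
             stringsAsFactors = FALSE)
}
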