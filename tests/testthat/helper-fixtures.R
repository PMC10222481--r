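# shared fixtures built in code

cfg_default <- function(...) readout_config(...)

# forward-encode a named force vector to ADC counts (independent of the
# simulator's encode path: plain arithmetic)
counts_for_forces <- function(forces, cfg) {
  g <- cfg$cal_slope * forces + cfg$cal_intercept
  v <- cfg$supply_voltage * g / (cfg$ref_conductance + g)
  round(v * (2^cfg$adc_bits - 1) / cfg$supply_voltage)
}

# a data.frame frame source holding the same forces for n ticks
frames_for_forces <- function(forces, n, cfg, start_tick = 0L) {
  counts <- counts_for_forces(forces, cfg)
  data.frame(tick = seq_len(n) - 1L + start_tick,
             Lt = counts[["Lt"]], Lb = counts[["Lb"]],
             Rt = counts[["Rt"]], Rb = counts[["Rb"]])
}

frames_to_lines <- function(df) {
  apply(df[, c("tick", "Lt", "Lb", "Rt", "Rb")], 1,
        function(r) paste(as.integer(r), collapse = ","))
}

# a notifier that records every call, for pairing checks
recording_notifier <- function() {
  log <- new.env(parent = emptyenv())
  log$calls <- character(0)
  notifier <- structure(list(
    open_warning = function(message) log$calls <- c(log$calls, "open"),
    close_warning = function() log$calls <- c(log$calls, "close")
  ), class = "seat_notifier")
  list(notifier = notifier, log = log)
}

# build a normalized reading directly (detector unit tests)
nr <- function(sensor, value, half, tick = 10L) {
  structure(list(sensor = sensor, n_value = value,
                 n_lower = value - half, n_upper = value + half,
                 tick_index = as.integer(tick)),
            class = "normalized_reading")
}

complete_profile <- function(email = "ada@example.org", consent = TRUE) {
  list(name = "Ada", surname = "Lovelace", email = email,
       height = 168, weight = 62, gender = "female", consent = consent)
}
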