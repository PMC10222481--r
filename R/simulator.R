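# Seat simulator: stands in for the cushion, the four force-sensing
# resistors, the pressure adapters and the microcontroller. It splits a total
# seat load across the four sensor positions according to a posture, applies
# per-sensor response gains, multiplicative noise and scripted transients,
# then pushes the forces through the forward signal path (calibration ->
# divider voltage -> ADC quantization) to produce serial frames.

POSTURE_LABELS <- c("symmetric",
                    "lean_fwd_left", "lean_fwd_right",
                    "lean_back_left", "lean_back_right",
                    "cross_left_leg", "cross_right_leg")

#' Posture scenario
#'
#' A scripted posture segment. The seat load `W` is split front/rear by
#' `top_fraction` and left/right within each pair by `left_fraction_top` /
#' `left_fraction_bottom`. Leaning postures move the relevant pair's left
#' fraction to `0.5 + lean_delta` (left) or `0.5 - lean_delta` (right);
#' leg-cross postures perturb only the bottom pair by `cross_delta` and raise
#' the front share slightly (`cross_top_shift`), since crossing a leg changes
#' the knee angle and with it the front/rear load split.
#'
#' The split magnitudes are configurable stand-ins, not biomechanical claims.
#'
#' @param label One of `symmetric`, `lean_fwd_left`, `lean_fwd_right`,
#'   `lean_back_left`, `lean_back_right`, `cross_left_leg`, `cross_right_leg`.
#' @param duration_ticks Number of sampling ticks the posture is held.
#' @param lean_delta Left/right split offset for leaning postures (default 0.20).
#' @param cross_delta Bottom-pair split offset for leg crossing (default 0.25).
#' @param top_fraction Fraction of the seat load on the front (top) pair
#'   (default 0.6).
#' @param cross_top_shift Added to `top_fraction` during leg crossing
#'   (default 0.05).
#' @return An object of class `posture_scenario`.
#' @export
posture_scenario <- function(label, duration_ticks,
                             lean_delta = 0.20, cross_delta = 0.25,
                             top_fraction = 0.6, cross_top_shift = 0.05) {
  label <- match.arg(label, POSTURE_LABELS)
  if (!is.numeric(duration_ticks) || length(duration_ticks) != 1L ||
      duration_ticks < 1L || duration_ticks != as.integer(duration_ticks)) {
    seat_abort("`duration_ticks` must be an integer >= 1", "seatsense_value_error")
  }
  lt <- 0.5
  lb <- 0.5
  tf <- top_fraction
  switch(label,
    lean_fwd_left   = { lt <- 0.5 + lean_delta },
    lean_fwd_right  = { lt <- 0.5 - lean_delta },
    lean_back_left  = { lb <- 0.5 + lean_delta },
    lean_back_right = { lb <- 0.5 - lean_delta },
    cross_left_leg  = { lb <- 0.5 + cross_delta; tf <- tf + cross_top_shift },
    cross_right_leg = { lb <- 0.5 - cross_delta; tf <- tf + cross_top_shift },
    symmetric       = { }
  )
  fr <- c(left_fraction_top = lt, left_fraction_bottom = lb, top_fraction = tf)
  if (any(fr <= 0) || any(fr >= 1)) {
    seat_abort("posture load fractions must lie strictly inside (0, 1)",
               "seatsense_value_error")
  }
  structure(list(label = label,
                 left_fraction_top = lt,
                 left_fraction_bottom = lb,
                 top_fraction = tf,
                 duration_ticks = as.integer(duration_ticks)),
            class = "posture_scenario")
}

#' Simulation configuration
#'
#' @param total_force Total load on the seat surface in newtons (default
#'   400 N, roughly the share of body weight carried by the seat for an
#'   average adult; the detector is scale-free after normalization).
#' @param noise_fraction Per-sensor, per-tick multiplicative Gaussian noise
#'   sigma as a fraction of the force (default 0.01, below the 2.5% datasheet
#'   accuracy).
#' @param sensor_gain Four per-sensor response multipliers emulating
#'   fabrication variability (named or in `Lt, Lb, Rt, Rb` order).
#' @param transients Optional data frame of brief movements with columns
#'   `tick`, `sensor`, `magnitude` (N, added), `width` (ticks).
#' @param seed Integer seed; identical seeds give identical traces.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(total_force = 400, noise_fraction = 0.01,
                              sensor_gain = c(Lt = 1, Lb = 1, Rt = 1, Rb = 1),
                              transients = NULL, seed = NULL) {
  stopifnot_scalar_number(total_force, "total_force", 0, strict = TRUE)
  stopifnot_scalar_number(noise_fraction, "noise_fraction", 0)
  if (length(sensor_gain) != 4L || any(sensor_gain <= 0)) {
    seat_abort("`sensor_gain` must be four positive multipliers", "seatsense_value_error")
  }
  if (is.null(names(sensor_gain))) names(sensor_gain) <- SEAT_SENSORS
  sensor_gain <- sensor_gain[SEAT_SENSORS]
  if (!is.null(transients)) {
    stopifnot(is.data.frame(transients),
              all(c("tick", "sensor", "magnitude", "width") %in% names(transients)))
  }
  structure(list(total_force = total_force,
                 noise_fraction = noise_fraction,
                 sensor_gain = sensor_gain,
                 transients = transients,
                 seed = seed),
            class = "simulation_config")
}

#' Noise-free forces of a posture
#'
#' Splits the total seat load across the four sensor positions:
#' `Lt = W * top_fraction * left_fraction_top`, etc. The four forces always
#' sum to the total load.
#'
#' @param scenario A [posture_scenario()].
#' @param sim A [simulation_config()].
#' @return Named numeric vector of forces (N) for `Lt, Lb, Rt, Rb`.
#' @examples
#' posture_to_forces(posture_scenario("symmetric", 1), simulation_config())
#' @export
posture_to_forces <- function(scenario, sim = simulation_config()) {
  stopifnot(inherits(scenario, "posture_scenario"),
            inherits(sim, "simulation_config"))
  W <- sim$total_force
  tf <- scenario$top_fraction
  c(Lt = W * tf * scenario$left_fraction_top,
    Lb = W * (1 - tf) * scenario$left_fraction_bottom,
    Rt = W * tf * (1 - scenario$left_fraction_top),
    Rb = W * (1 - tf) * (1 - scenario$left_fraction_bottom))
}

# forward signal path: force -> conductance -> divider voltage -> ADC counts
encode_forces <- function(forces, cfg) {
  g <- cfg$cal_slope * forces + cfg$cal_intercept
  v <- cfg$supply_voltage * g / (cfg$ref_conductance + g)
  max_count <- 2^cfg$adc_bits - 1
  counts <- round(v * max_count / cfg$supply_voltage)
  # keep strictly below full scale: a full-scale count means a shorted sensor
  high <- counts > max_count - 1L
  if (any(high)) {
    warning(sprintf("simulated force drove sensor(s) %s into ADC saturation; clipped",
                    paste(names(forces)[high], collapse = ", ")), call. = FALSE)
    counts[high] <- max_count - 1L
  }
  counts
}

#' Generate a simulated frame trace for a posture schedule
#'
#' For each tick of each scheduled posture: the noise-free split forces are
#' scaled by the per-sensor gains, perturbed by multiplicative Gaussian noise
#' and any scheduled transient, then encoded through the forward signal path
#' (linear calibration, voltage divider, ADC quantization). Fully
#' reproducible from the seed; the caller's RNG stream is left untouched.
#'
#' @param schedule A [posture_scenario()] or list of them, played in order.
#' @param sim A [simulation_config()].
#' @param cfg A [readout_config()].
#' @return A data frame of class `seat_trace` with columns `tick`, `posture`,
#'   and ADC counts `Lt, Lb, Rt, Rb`; the pre-quantization applied forces are
#'   attached as the `"applied_forces"` attribute (a matrix).
#' @export
generate_trace <- function(schedule, sim = simulation_config(),
                           cfg = readout_config()) {
  if (inherits(schedule, "posture_scenario")) schedule <- list(schedule)
  if (length(schedule) == 0L ||
      !all(vapply(schedule, inherits, logical(1), "posture_scenario"))) {
    seat_abort("`schedule` must be a non-empty list of posture scenarios",
               "seatsense_value_error")
  }
  n_ticks <- sum(vapply(schedule, `[[`, integer(1), "duration_ticks"))
  counts_mat <- matrix(0L, nrow = n_ticks, ncol = 4L,
                       dimnames = list(NULL, SEAT_SENSORS))
  forces_mat <- matrix(0, nrow = n_ticks, ncol = 4L,
                       dimnames = list(NULL, SEAT_SENSORS))
  posture <- character(n_ticks)
  with_seed(sim$seed, {
    tick <- 0L
    for (sc in schedule) {
      base <- posture_to_forces(sc, sim) * sim$sensor_gain
      for (i in seq_len(sc$duration_ticks)) {
        f <- base
        if (sim$noise_fraction > 0) {
          f <- f * (1 + stats::rnorm(4L, 0, sim$noise_fraction))
        }
        if (!is.null(sim$transients)) {
          tr <- sim$transients
          act <- tr$tick <= tick & tick < tr$tick + tr$width
          for (j in which(act)) {
            f[[tr$sensor[j]]] <- f[[tr$sensor[j]]] + tr$magnitude[j]
          }
        }
        f <- pmax(f, 0)
        row <- tick + 1L
        forces_mat[row, ] <- f
        counts_mat[row, ] <- encode_forces(f, cfg)
        posture[row] <- sc$label
        tick <- tick + 1L
      }
    }
  })
  trace <- data.frame(tick = seq_len(n_ticks) - 1L, posture = posture,
                      counts_mat, stringsAsFactors = FALSE)
  attr(trace, "applied_forces") <- forces_mat
  class(trace) <- c("seat_trace", class(trace))
  trace
}

#' Six-posture test protocol
#'
#' The scripted validation protocol: an initialization hold in the correct
#' posture, then each of the six incorrect postures (leaning forward left and
#' right, leaning backward left and right, crossing the left and the right
#' leg) held for a fixed number of ticks, each followed by a return to the
#' correct posture. A correctly working monitor opens a warning once per
#' incorrect posture and closes it once per restoration: 6 event pairs.
#'
#' @param sim A [simulation_config()].
#' @param cfg A [readout_config()].
#' @param init_ticks Initialization hold length (>= queue length; default 10).
#' @param posture_ticks Ticks per incorrect posture (default 20).
#' @param restore_ticks Ticks of restored correct posture after each (default 20).
#' @param lean_delta,cross_delta Posture split offsets (see
#'   [posture_scenario()]).
#' @return A `seat_trace` (see [generate_trace()]).
#' @examples
#' trace <- six_posture_protocol(simulation_config(seed = 1))
#' rec <- run_session(trace)
#' table(rec$events$direction)
#' @export
six_posture_protocol <- function(sim = simulation_config(), cfg = readout_config(),
                                 init_ticks = 10L, posture_ticks = 20L,
                                 restore_ticks = 20L, lean_delta = 0.20,
                                 cross_delta = 0.25) {
  if (init_ticks < cfg$queue_length) {
    seat_abort("`init_ticks` must cover at least one full queue", "seatsense_value_error")
  }
  postures <- POSTURE_LABELS[-1]
  schedule <- list(posture_scenario("symmetric", init_ticks))
  for (p in postures) {
    schedule <- c(schedule,
                  list(posture_scenario(p, posture_ticks,
                                        lean_delta = lean_delta,
                                        cross_delta = cross_delta),
                       posture_scenario("symmetric", restore_ticks)))
  }
  generate_trace(schedule, sim, cfg)
}

#' Read a posture schedule file
#'
#' One directive per line: `<posture_label> <duration_ticks> [lean_delta]`;
#' blank lines and `#` comments are ignored. The optional third field sets
#' `lean_delta` and `cross_delta` for that segment.
#'
#' @param path Path to the schedule file.
#' @return A list of [posture_scenario()]s.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) {
    seat_abort(sprintf("schedule file not found: %s", path), "seatsense_value_error")
  }
  lines <- readLines(path, warn = FALSE)
  schedule <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) < 2L || length(fields) > 3L ||
        !(fields[1] %in% POSTURE_LABELS) ||
        !grepl("^[0-9]+$", fields[2])) {
      seat_abort(sprintf("bad schedule directive at line %d: '%s'", i, lines[i]),
                 "seatsense_value_error")
    }
    args <- list(label = fields[1], duration_ticks = as.integer(fields[2]))
    if (length(fields) == 3L) {
      delta <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(delta)) {
        seat_abort(sprintf("bad delta at line %d: '%s'", i, fields[3]),
                   "seatsense_value_error")
      }
      args$lean_delta <- delta
      args$cross_delta <- delta
    }
    schedule[[length(schedule) + 1L]] <- do.call(posture_scenario, args)
  }
  if (length(schedule) == 0L) {
    seat_abort("schedule file contains no directives", "seatsense_value_error")
  }
  schedule
}
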