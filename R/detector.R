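#' Per-session initialization reference
#'
#' The per-sensor moving-average force captured while the user holds the
#' correct posture at the start of a session. Subsequent filtered forces are
#' divided by it, which cancels inter-sensor response variability and slow
#' environmental drift (the reference is re-acquired every session).
#'
#' @param values Named numeric vector of reference forces (N) for
#'   `Lt, Lb, Rt, Rb`.
#' @param uncertainties Optional named vector of the references' propagated
#'   uncertainties (used only when `propagate_reference_uncertainty` is on).
#' @param cfg A [readout_config()]; supplies `min_seated_force`.
#' @param created_at Timestamp (seconds since session start).
#' @param validate If `TRUE` (default), references below `min_seated_force`
#'   are rejected.
#' @return An object of class `reference_profile`.
#' @export
reference_profile <- function(values, uncertainties = NULL, cfg = readout_config(),
                              created_at = 0, validate = TRUE) {
  if (length(values) != 4L || !is.numeric(values)) {
    seat_abort("reference needs four numeric values", "seatsense_value_error")
  }
  if (is.null(names(values))) names(values) <- SEAT_SENSORS
  if (!setequal(names(values), SEAT_SENSORS)) {
    seat_abort("reference names must be Lt, Lb, Rt, Rb", "seatsense_value_error")
  }
  values <- values[SEAT_SENSORS]
  if (validate) {
    low <- !is.finite(values) | values < cfg$min_seated_force
    if (any(low)) {
      seat_abort(sprintf("reference below minimum seated force on sensor(s) %s",
                         paste(names(values)[low], collapse = ", ")),
                 "seatsense_reference_error")
    }
  }
  if (!is.null(uncertainties)) {
    if (is.null(names(uncertainties))) names(uncertainties) <- SEAT_SENSORS
    uncertainties <- uncertainties[SEAT_SENSORS]
  }
  structure(list(values = values,
                 uncertainties = uncertainties,
                 created_at = created_at),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile>\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Normalize a filtered force by its initialization reference
#'
#' Divides the filtered mean and its interval bounds by the sensor's
#' reference force, yielding a dimensionless reading that is approximately 1
#' when the user sits as they did at initialization. The reference is treated
#' as an exact scale factor by default; set
#' `propagate_reference_uncertainty = TRUE` in the config to combine its
#' uncertainty in quadrature (sensitivity studies).
#'
#' @param filtered A complete `filtered_force` (warm-up values are rejected).
#' @param reference A [reference_profile()].
#' @param cfg A [readout_config()].
#' @return An object of class `normalized_reading` with fields `sensor`,
#'   `n_value`, `n_lower`, `n_upper`, `tick_index`.
#' @export
normalize_reading <- function(filtered, reference, cfg) {
  stopifnot(inherits(filtered, "filtered_force"),
            inherits(reference, "reference_profile"),
            inherits(cfg, "readout_config"))
  if (!isTRUE(filtered$complete)) {
    seat_abort("cannot normalize a warm-up (incomplete) filtered value",
               "seatsense_contract_error")
  }
  ref <- reference$values[[filtered$sensor]]
  if (is.null(ref) || !is.finite(ref) || ref < cfg$min_seated_force) {
    seat_abort(sprintf("invalid reference for sensor '%s'", filtered$sensor),
               "seatsense_reference_error")
  }
  n <- filtered$mean / ref
  if (cfg$propagate_reference_uncertainty && !is.null(reference$uncertainties)) {
    u_ref <- reference$uncertainties[[filtered$sensor]] %||% 0
    half <- sqrt((filtered$uncertainty / ref)^2 + (filtered$mean * u_ref / ref^2)^2)
    lo <- n - half
    hi <- n + half
  } else {
    lo <- filtered$lower / ref
    hi <- filtered$upper / ref
  }
  structure(list(sensor = filtered$sensor,
                 n_value = n,
                 n_lower = lo,
                 n_upper = hi,
                 tick_index = filtered$tick_index),
            class = "normalized_reading")
}

#' Four-condition interval-overlap asymmetry test
#'
#' The posture is symmetric when the uncertainty intervals of the left and
#' right normalized readings intersect, separately for the top (front) and
#' bottom (rear) sensor pairs; the pairs are never compared with each other,
#' so knee-angle-driven front/rear load changes cannot trigger a flag. The
#' flag is raised when at least one of four strict inequalities holds:
#'
#' * `top_left_heavy`: upper bound of n-Rt below lower bound of n-Lt
#' * `bottom_left_heavy`: upper bound of n-Rb below lower bound of n-Lb
#' * `top_right_heavy`: upper bound of n-Lt below lower bound of n-Rt
#' * `bottom_right_heavy`: upper bound of n-Lb below lower bound of n-Rb
#'
#' Touching intervals count as overlap (symmetric): the comparisons are
#' strict.
#'
#' @param nLt,nLb,nRt,nRb [normalize_reading()] results for the four sensors,
#'   all at the same tick.
#' @return An object of class `posture_flag`: `tick_index`, `asymmetric`
#'   (logical) and `triggered_conditions` (character subset of the four
#'   condition names; empty when symmetric).
#' @export
asymmetry_flag <- function(nLt, nLb, nRt, nRb) {
  readings <- list(Lt = nLt, Lb = nLb, Rt = nRt, Rb = nRb)
  for (s in names(readings)) {
    r <- readings[[s]]
    if (!inherits(r, "normalized_reading") || !identical(r$sensor, s)) {
      seat_abort(sprintf("argument n%s must be a normalized reading for sensor '%s'", s, s),
                 "seatsense_contract_error")
    }
  }
  ticks <- vapply(readings, `[[`, integer(1), "tick_index")
  if (length(unique(ticks)) != 1L) {
    seat_abort("the four normalized readings must share a tick index",
               "seatsense_contract_error")
  }
  conds <- c(
    top_left_heavy     = nRt$n_upper < nLt$n_lower,
    bottom_left_heavy  = nRb$n_upper < nLb$n_lower,
    top_right_heavy    = nLt$n_upper < nRt$n_lower,
    bottom_right_heavy = nLb$n_upper < nRb$n_lower
  )
  structure(list(tick_index = ticks[[1]],
                 asymmetric = any(conds),
                 triggered_conditions = names(conds)[conds]),
            class = "posture_flag")
}

#' @export
print.posture_flag <- function(x, ...) {
  cat(sprintf("<posture_flag @%d: %s%s>\n", x$tick_index,
              if (x$asymmetric) "ASYMMETRIC" else "symmetric",
              if (length(x$triggered_conditions))
                paste0(" [", paste(x$triggered_conditions, collapse = ", "), "]")
              else ""))
  invisible(x)
}

shift_event <- function(tick_index, direction, triggered_conditions = character(0),
                        timestamp = NA_real_, session_id = NA_character_,
                        user_id = NA_character_) {
  structure(list(session_id = session_id,
                 user_id = user_id,
                 tick_index = as.integer(tick_index),
                 timestamp = timestamp,
                 direction = direction,
                 triggered_conditions = triggered_conditions),
            class = "shift_event")
}

#' @export
print.shift_event <- function(x, ...) {
  cat(sprintf("<shift_event @%d: %s%s>\n", x$tick_index, x$direction,
              if (length(x$triggered_conditions))
                paste0(" [", paste(x$triggered_conditions, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Detect a posture-flag edge
#'
#' Compares the current flag with the previous one and emits a shift event on
#' an edge: symmetric-to-asymmetric yields a `ToAsymmetric` event (a warning
#' should open), asymmetric-to-symmetric yields `ToSymmetric` (the warning
#' closes). The first evaluated flag after warm-up is compared against an
#' assumed-symmetric baseline, since the user holds the correct posture
#' through initialization.
#'
#' @param previous The previous `posture_flag`, or `NULL` right after warm-up.
#' @param current The current `posture_flag`.
#' @return A `shift_event`, or `NULL` when the flag did not change.
#' @export
detect_transition <- function(previous, current) {
  stopifnot(inherits(current, "posture_flag"))
  prev_asym <- FALSE
  if (!is.null(previous)) {
    stopifnot(inherits(previous, "posture_flag"))
    if (current$tick_index <= previous$tick_index) {
      seat_abort("tick indices must be strictly increasing",
                 "seatsense_contract_error")
    }
    prev_asym <- previous$asymmetric
  }
  if (identical(prev_asym, current$asymmetric)) return(NULL)
  if (current$asymmetric) {
    shift_event(current$tick_index, "ToAsymmetric", current$triggered_conditions)
  } else {
    shift_event(current$tick_index, "ToSymmetric")
  }
}
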