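#' Fixed-capacity circular queue of force readings
#'
#' Per-sensor storage for the moving-average filter: pushing onto a full
#' queue evicts exactly the oldest entry. Entries iterate oldest to newest.
#'
#' @param capacity Queue capacity (default 5, the filter window).
#' @param sensor Optional sensor label; when set, pushes for a different
#'   sensor are rejected.
#' @return An object of class `circular_queue`.
#' @export
circular_queue <- function(capacity = 5L, sensor = NULL) {
  if (!is.numeric(capacity) || length(capacity) != 1L ||
      capacity != as.integer(capacity) || capacity < 1L) {
    seat_abort("`capacity` must be an integer >= 1", "seatsense_value_error")
  }
  structure(list(capacity = as.integer(capacity),
                 sensor = sensor,
                 values = numeric(0),
                 uncertainties = numeric(0)),
            class = "circular_queue")
}

#' @export
print.circular_queue <- function(x, ...) {
  cat(sprintf("<circular_queue %s: %d/%d>\n", x$sensor %||% "?",
              length(x$values), x$capacity))
  invisible(x)
}

#' Queue contents, oldest to newest
#' @param queue A [circular_queue()].
#' @return Numeric vector of stored force values.
#' @export
queue_values <- function(queue) {
  stopifnot(inherits(queue, "circular_queue"))
  queue$values
}

filtered_force <- function(sensor, mean, uncertainty, complete, tick_index) {
  structure(list(sensor = sensor,
                 mean = mean,
                 uncertainty = uncertainty,
                 lower = mean - uncertainty,
                 upper = mean + uncertainty,
                 complete = complete,
                 tick_index = tick_index),
            class = "filtered_force")
}

#' @export
print.filtered_force <- function(x, ...) {
  cat(sprintf("<filtered_force %s @%d: %.4g +/- %.4g N [%.4g, %.4g]%s>\n",
              x$sensor, x$tick_index, x$mean, x$uncertainty, x$lower, x$upper,
              if (x$complete) "" else " (warm-up)"))
  invisible(x)
}

#' Push a reading and compute the filtered force
#'
#' Appends one force reading to the sensor's circular queue (evicting the
#' oldest when full) and returns the moving average over the stored entries
#' with propagated uncertainty and interval bounds. While the queue is still
#' filling, statistics are computed over the available entries but
#' `complete = FALSE`, and downstream consumers (the asymmetry detector) must
#' not act on them.
#'
#' Uncertainty propagation follows `cfg$uncertainty_propagation`:
#' `"sum"` gives `sqrt(sum(u_i^2))` (the conservative rule of the reference
#' device), `"mean"` gives `sqrt(sum(u_i^2)) / n` (standard propagation for
#' an unweighted mean of independent readings).
#'
#' @param queue A [circular_queue()].
#' @param reading A one-row data frame or list with `sensor`, `value`,
#'   `uncertainty`, `tick_index` (as produced by [sample_to_readings()]).
#' @param cfg A [readout_config()].
#' @return A list with the updated `queue` and the `filtered` value
#'   (class `filtered_force`).
#' @examples
#' cfg <- readout_config()
#' q <- circular_queue(5, "Lt")
#' for (i in 0:4) {
#'   out <- push_and_filter(q, list(sensor = "Lt", value = 10,
#'                                  uncertainty = 0.1443, tick_index = i), cfg)
#'   q <- out$queue
#' }
#' out$filtered$mean
#' @export
push_and_filter <- function(queue, reading, cfg) {
  stopifnot(inherits(queue, "circular_queue"), inherits(cfg, "readout_config"))
  sensor <- as.character(reading$sensor %||% reading[["sensor"]])
  if (!is.null(queue$sensor) && !identical(sensor, queue$sensor)) {
    seat_abort(sprintf("reading for sensor '%s' pushed onto queue for '%s'",
                       sensor, queue$sensor),
               "seatsense_contract_error")
  }
  v <- as.numeric(reading$value)
  u <- as.numeric(reading$uncertainty)
  if (!is.finite(v) || !is.finite(u) || u < 0) {
    seat_abort("reading value/uncertainty must be finite, uncertainty >= 0",
               "seatsense_contract_error")
  }
  queue$values <- c(queue$values, v)
  queue$uncertainties <- c(queue$uncertainties, u)
  if (length(queue$values) > queue$capacity) {
    keep <- seq.int(length(queue$values) - queue$capacity + 1L, length(queue$values))
    queue$values <- queue$values[keep]
    queue$uncertainties <- queue$uncertainties[keep]
  }
  n <- length(queue$values)
  m <- mean(queue$values)
  rss <- sqrt(sum(queue$uncertainties^2))
  uk <- if (cfg$uncertainty_propagation == "mean") rss / n else rss
  list(queue = queue,
       filtered = filtered_force(sensor, m, uk,
                                 complete = (n == queue$capacity),
                                 tick_index = as.integer(reading$tick_index)))
}

#' Uncertainty interval of a filtered force
#'
#' @param filtered A `filtered_force` from [push_and_filter()].
#' @return Named numeric `c(lower, upper)` = mean -/+ propagated uncertainty.
#' @export
bounds <- function(filtered) {
  stopifnot(inherits(filtered, "filtered_force"))
  c(lower = filtered$lower, upper = filtered$upper)
}
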