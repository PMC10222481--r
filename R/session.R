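#' Notification hooks
#'
#' A notifier is the seam where a user-facing alert mechanism attaches. The
#' contract is two functions: `open_warning(message)` when a shift to an
#' asymmetric posture is detected, and `close_warning()` when the correct
#' posture is restored (the alert closes autonomously). Two backends are
#' bundled: a console backend that prints and clears a warning line, and a
#' no-op backend.
#'
#' @return A list with functions `open_warning(message)` and
#'   `close_warning()`, of class `seat_notifier`.
#' @export
notifier_console <- function() {
  structure(list(
    open_warning = function(message) {
      cat(sprintf("[WARNING] %s\n", message))
    },
    close_warning = function() {
      cat("[WARNING cleared] correct posture restored\n")
    }
  ), class = "seat_notifier")
}

#' @rdname notifier_console
#' @export
notifier_noop <- function() {
  structure(list(
    open_warning = function(message) invisible(NULL),
    close_warning = function() invisible(NULL)
  ), class = "seat_notifier")
}

#' Create a monitoring session context
#'
#' A session is a small state machine with exactly two states:
#' `INITIALIZATION`, during which the seated user holds the correct posture
#' while the per-sensor filter queues fill and the reference is captured, and
#' `MONITORING`, during which every frame is filtered, normalized and tested
#' for asymmetry. The only allowed transition is initialization to
#' monitoring; a new session always starts in initialization.
#'
#' Wall-clock time is derived as `tick_index * sampling_interval`, which makes
#' sessions replayable and bit-reproducible.
#'
#' @param cfg A [readout_config()].
#' @param user Optional user, a list with at least `user_id` and `consent`
#'   (logical). Without consent, events still drive notifications but are not
#'   persisted.
#' @param notifier A notifier (see [notifier_console()]).
#' @param session_id Identifier for the session; defaults to a deterministic
#'   id derived from the user id.
#' @return A session context (an environment of class `seat_session`).
#' @export
new_session <- function(cfg = readout_config(), user = NULL,
                        notifier = notifier_noop(), session_id = NULL) {
  stopifnot(inherits(cfg, "readout_config"))
  s <- new.env(parent = emptyenv())
  s$state <- "INITIALIZATION"
  s$entered_at <- 0
  s$cfg <- cfg
  s$user <- user
  s$session_id <- session_id %||% paste0("sess-", user$user_id %||% "anon")
  s$notifier <- notifier
  s$queues <- lapply(SEAT_SENSORS, function(sn) circular_queue(cfg$queue_length, sn))
  names(s$queues) <- SEAT_SENSORS
  s$reference <- NULL
  s$prev_flag <- NULL
  s$events <- list()
  s$flags <- list()
  s$frame_errors <- 0L
  s$init_frames <- 0L
  s$monitor_ticks <- 0L
  s$last_tick <- NA_integer_
  s$warning_open <- FALSE
  s$expired <- FALSE
  s$last_readings <- NULL
  class(s) <- c("seat_session", class(s))
  s
}

#' @export
print.seat_session <- function(x, ...) {
  cat(sprintf("<seat_session %s: %s, %d monitoring ticks, %d events>\n",
              x$session_id, x$state, x$monitor_ticks, length(x$events)))
  invisible(x)
}

# push one frame's readings through all four queues; returns named list of
# filtered_force
push_frame <- function(session, sample) {
  readings <- sample_to_readings(sample, session$cfg)
  session$last_readings <- readings
  filtered <- vector("list", 4L)
  names(filtered) <- SEAT_SENSORS
  for (i in seq_len(nrow(readings))) {
    sn <- readings$sensor[i]
    out <- push_and_filter(session$queues[[sn]], readings[i, ], session$cfg)
    session$queues[[sn]] <- out$queue
    filtered[[sn]] <- out$filtered
  }
  filtered
}

# one initialization frame; captures the reference when the queues fill
init_step <- function(session, sample) {
  filtered <- push_frame(session, sample)
  session$init_frames <- session$init_frames + 1L
  session$last_tick <- sample$tick_index
  if (all(vapply(filtered, `[[`, logical(1), "complete"))) {
    vals <- vapply(filtered, `[[`, numeric(1), "mean")
    uncs <- vapply(filtered, `[[`, numeric(1), "uncertainty")
    low <- vals < session$cfg$min_seated_force
    if (any(low)) {
      seat_abort(sprintf(
        "initialization failed: sensor(s) %s below the minimum seated force (user not seated or sensor fault)",
        paste(names(vals)[low], collapse = ", ")),
        "seatsense_init_error")
    }
    session$reference <- reference_profile(vals, uncs, session$cfg,
                                           created_at = sample$tick_index *
                                             session$cfg$sampling_interval)
    session$state <- "MONITORING"
    session$entered_at <- sample$tick_index * session$cfg$sampling_interval
  }
  invisible(session$reference)
}

#' Run the initialization phase on a frame stream
#'
#' Consumes frames while the user holds the correct posture; as soon as the
#' filter queues are full (after `queue_length` valid frames) the per-sensor
#' moving average is stored as the reference and the session would move to
#' monitoring.
#'
#' @param frames A frame source: file path, character lines, a data frame
#'   with columns `tick, Lt, Lb, Rt, Rb`, or a list of [raw_sample()]s.
#' @param cfg A [readout_config()].
#' @param retry_budget Number of malformed frames tolerated before declaring
#'   a connection error.
#' @return A [reference_profile()].
#' @export
run_initialization <- function(frames, cfg = readout_config(), retry_budget = 10L) {
  session <- new_session(cfg)
  stream <- as_frame_stream(frames, cfg)
  for (entry in stream) {
    if (is.null(entry)) {
      session$frame_errors <- session$frame_errors + 1L
      if (session$frame_errors > retry_budget) {
        seat_abort("persistent frame errors during initialization: connection lost",
                   "seatsense_connection_error")
      }
      next
    }
    init_step(session, entry)
    if (session$state == "MONITORING") return(session$reference)
  }
  seat_abort(sprintf(
    "stream ended during initialization (%d of %d frames): connection error",
    session$init_frames, cfg$queue_length),
    "seatsense_connection_error")
}

#' Process one monitoring frame
#'
#' Runs the full per-tick chain: raw counts to forces with uncertainty,
#' moving-average filtering, normalization by the initialization reference,
#' the four-condition asymmetry test, and edge detection. On a shift to an
#' asymmetric posture the notifier's warning opens; on restoration it closes.
#'
#' @param session A `seat_session` in the `MONITORING` state.
#' @param sample A [raw_sample()].
#' @return A list with the `flag` (`posture_flag`) and the `event`
#'   (`shift_event` or `NULL`).
#' @export
monitoring_step <- function(session, sample) {
  stopifnot(inherits(session, "seat_session"))
  if (!identical(session$state, "MONITORING")) {
    seat_abort("monitoring_step called outside the MONITORING state",
               "seatsense_contract_error")
  }
  cfg <- session$cfg
  if (session$monitor_ticks * cfg$sampling_interval >
      cfg$session_limit_hours * 3600) {
    if (!session$expired) {
      session$expired <- TRUE
      session$notifier$open_warning("session expired: please re-initialize")
    }
    return(list(flag = NULL, event = NULL))
  }
  filtered <- push_frame(session, sample)
  normalized <- lapply(SEAT_SENSORS, function(sn) {
    normalize_reading(filtered[[sn]], session$reference, cfg)
  })
  names(normalized) <- SEAT_SENSORS
  flag <- asymmetry_flag(normalized$Lt, normalized$Lb, normalized$Rt, normalized$Rb)
  event <- detect_transition(session$prev_flag, flag)
  session$prev_flag <- flag
  session$monitor_ticks <- session$monitor_ticks + 1L
  session$last_tick <- sample$tick_index
  session$flags[[length(session$flags) + 1L]] <- flag
  if (!is.null(event)) {
    event$timestamp <- event$tick_index * cfg$sampling_interval
    event$session_id <- session$session_id
    event$user_id <- session$user$user_id %||% NA_character_
    session$events[[length(session$events) + 1L]] <- event
    if (event$direction == "ToAsymmetric") {
      session$warning_open <- TRUE
      session$notifier$open_warning(sprintf(
        "asymmetric posture detected (%s)",
        paste(event$triggered_conditions, collapse = ", ")))
    } else {
      session$warning_open <- FALSE
      session$notifier$close_warning()
    }
  }
  list(flag = flag, event = event)
}

#' Per-sensor health snapshot
#'
#' Read-out health of the four sensors at the last processed frame: the
#' decoded force, whether the reading was below the calibration range, and
#' the session counters. Stands in for an indicator panel.
#'
#' @param session A `seat_session`.
#' @return A list with `state`, `frame_errors`, `monitor_ticks`,
#'   `warning_open` and a `sensors` data frame.
#' @export
session_status <- function(session) {
  stopifnot(inherits(session, "seat_session"))
  list(state = session$state,
       frame_errors = session$frame_errors,
       monitor_ticks = session$monitor_ticks,
       warning_open = session$warning_open,
       sensors = session$last_readings)
}

events_to_df <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(session_id = character(0), user_id = character(0),
                      tick_index = integer(0), timestamp = numeric(0),
                      direction = character(0), triggered_conditions = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    session_id = vapply(events, `[[`, character(1), "session_id"),
    user_id = vapply(events, `[[`, character(1), "user_id"),
    tick_index = vapply(events, `[[`, integer(1), "tick_index"),
    timestamp = vapply(events, `[[`, numeric(1), "timestamp"),
    direction = vapply(events, `[[`, character(1), "direction"),
    triggered_conditions = vapply(events, function(e)
      paste(e$triggered_conditions, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

flags_to_df <- function(flags) {
  if (length(flags) == 0L) {
    return(data.frame(tick = integer(0), asymmetric = logical(0),
                      conditions = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    tick = vapply(flags, `[[`, integer(1), "tick_index"),
    asymmetric = vapply(flags, `[[`, logical(1), "asymmetric"),
    conditions = vapply(flags, function(f)
      paste(f$triggered_conditions, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Run a full monitoring session on a frame stream
#'
#' Initialization followed by continuous monitoring until the stream ends (or
#' the soft session-duration limit trips). Every flag edge opens or closes
#' the notifier warning and is appended to the event log; with a store and a
#' consenting user the session record is persisted at the end. Malformed
#' frames are counted and skipped without corrupting state.
#'
#' @param frames A frame source (see [run_initialization()]).
#' @param cfg A [readout_config()].
#' @param user Optional list with `user_id` and `consent`. Events of a
#'   non-consenting user drive notifications but are never persisted.
#' @param notifier A notifier backend.
#' @param store Optional [posture_store()] to persist the session record.
#' @param session_id Session identifier (deterministic default).
#' @param retry_budget Malformed-frame tolerance during initialization.
#' @return A `session_record`: list with `session_id`, `user_id`, `reference`,
#'   `started_at`, `ended_at`, `n_ticks` (monitoring ticks), `frame_errors`,
#'   `events` (data frame) and `flags` (per-tick data frame).
#' @examples
#' trace <- six_posture_protocol(simulation_config(seed = 7))
#' rec <- run_session(trace)
#' rec$events$direction
#' @export
run_session <- function(frames, cfg = readout_config(), user = NULL,
                        notifier = notifier_noop(), store = NULL,
                        session_id = NULL, retry_budget = 10L) {
  session <- new_session(cfg, user = user, notifier = notifier,
                         session_id = session_id)
  stream <- as_frame_stream(frames, cfg)
  for (entry in stream) {
    if (is.null(entry)) {
      session$frame_errors <- session$frame_errors + 1L
      if (session$state == "INITIALIZATION" && session$frame_errors > retry_budget) {
        seat_abort("persistent frame errors during initialization: connection lost",
                   "seatsense_connection_error")
      }
      next
    }
    if (session$state == "INITIALIZATION") {
      init_step(session, entry)
    } else {
      monitoring_step(session, entry)
      if (session$expired) break
    }
  }
  if (session$state == "INITIALIZATION") {
    seat_abort(sprintf(
      "stream ended during initialization (%d of %d frames): connection error",
      session$init_frames, cfg$queue_length),
      "seatsense_connection_error")
  }
  record <- structure(list(
    session_id = session$session_id,
    user_id = session$user$user_id %||% NA_character_,
    consent = isTRUE(session$user$consent),
    reference = session$reference,
    started_at = 0,
    ended_at = if (is.na(session$last_tick)) 0 else
      session$last_tick * cfg$sampling_interval,
    n_ticks = session$monitor_ticks,
    frame_errors = session$frame_errors,
    events = events_to_df(session$events),
    flags = flags_to_df(session$flags)
  ), class = "session_record")
  if (!is.null(store) && !is.null(user)) {
    if (isTRUE(user$consent)) {
      tryCatch(record_session(store, record),
               error = function(e) {
                 buffer_record(store, record)
                 warning(sprintf("event store unavailable (%s): session buffered locally",
                                 conditionMessage(e)), call. = FALSE)
               })
    }
  }
  record
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record %s: %d ticks, %d events, %d frame errors>\n",
              x$session_id, x$n_ticks, nrow(x$events), x$frame_errors))
  if (nrow(x$events)) {
    print(x$events[, c("tick_index", "timestamp", "direction", "triggered_conditions")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Decode and flag a recorded trace end to end
#'
#' Convenience wrapper: runs a full session (initialization + monitoring) on
#' a recorded or simulated frame stream with no user, store or notifications.
#'
#' @param frames A frame source.
#' @param cfg A [readout_config()].
#' @return A `session_record`.
#' @export
process_trace <- function(frames, cfg = readout_config()) {
  run_session(frames, cfg)
}
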