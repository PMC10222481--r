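# Local, queryable event store: a directory with users.csv, sessions.csv and
# events.jsonl. Stands in (behind the same recording semantics) for a remote
# password-protected database; the sink contract is small enough that another
# backend can be swapped in.

USER_FIELDS <- c("name", "surname", "email", "height", "weight", "gender", "consent")

#' Open (or create) a local posture event store
#'
#' @param path Directory for the store; created if missing.
#' @return An object of class `posture_store`.
#' @export
posture_store <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  store <- structure(list(path = path, buffer = new.env(parent = emptyenv())),
                     class = "posture_store")
  store$buffer$records <- list()
  store
}

#' @export
print.posture_store <- function(x, ...) {
  users <- tryCatch(nrow(read_users(x)), error = function(e) NA_integer_)
  cat(sprintf("<posture_store %s: %s user(s)>\n", x$path, users))
  invisible(x)
}

users_path <- function(store) file.path(store$path, "users.csv")
sessions_path <- function(store) file.path(store$path, "sessions.csv")
events_path <- function(store) file.path(store$path, "events.jsonl")

read_users <- function(store) {
  p <- users_path(store)
  if (!file.exists(p)) {
    return(data.frame(user_id = character(0), name = character(0),
                      surname = character(0), email = character(0),
                      height = numeric(0), weight = numeric(0),
                      gender = character(0), consent = logical(0),
                      registered_at = character(0), stringsAsFactors = FALSE))
  }
  utils::read.csv(p, stringsAsFactors = FALSE, colClasses = c(
    user_id = "character", name = "character", surname = "character",
    email = "character", height = "numeric", weight = "numeric",
    gender = "character", consent = "logical", registered_at = "character"))
}

#' Register a user profile
#'
#' All seven profile tags (name, surname, email, height, weight, gender, and
#' the explicit consent boolean) are mandatory; registration is idempotent on
#' the email address (re-registering returns the existing id).
#'
#' @param store A [posture_store()].
#' @param profile Named list with the seven fields above.
#' @return The `user_id` (character).
#' @export
register_user <- function(store, profile) {
  stopifnot(inherits(store, "posture_store"))
  missing_f <- setdiff(USER_FIELDS, names(profile))
  empty_f <- USER_FIELDS[vapply(USER_FIELDS, function(f) {
    v <- profile[[f]]
    is.null(v) || length(v) != 1L || (is.character(v) && !nzchar(v)) || is.na(v)
  }, logical(1))]
  bad <- union(missing_f, empty_f)
  if (length(bad)) {
    seat_abort(sprintf("profile is missing mandatory field(s): %s",
                       paste(bad, collapse = ", ")),
               "seatsense_validation_error")
  }
  if (!is.logical(profile$consent)) {
    seat_abort("`consent` must be an explicit TRUE/FALSE", "seatsense_validation_error")
  }
  for (f in c("height", "weight")) {
    if (!is.numeric(profile[[f]]) || profile[[f]] <= 0) {
      seat_abort(sprintf("`%s` must be a positive number", f),
                 "seatsense_validation_error")
    }
  }
  users <- read_users(store)
  hit <- which(tolower(users$email) == tolower(profile$email))
  if (length(hit)) return(users$user_id[hit[1]])
  uid <- sprintf("u%04d", nrow(users) + 1L)
  row <- data.frame(user_id = uid, name = profile$name, surname = profile$surname,
                    email = profile$email, height = profile$height,
                    weight = profile$weight, gender = profile$gender,
                    consent = profile$consent,
                    registered_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stringsAsFactors = FALSE)
  utils::write.csv(rbind(users, row), users_path(store), row.names = FALSE)
  uid
}

#' Look up a user
#' @param store A [posture_store()].
#' @param user_id User identifier.
#' @return One-row data frame, or an error if unknown.
#' @export
get_user <- function(store, user_id) {
  users <- read_users(store)
  hit <- users[users$user_id == user_id, , drop = FALSE]
  if (nrow(hit) == 0L) {
    seat_abort(sprintf("unknown user '%s'", user_id), "seatsense_notfound_error")
  }
  hit
}

#' Delete a user and all their records (consent revocation)
#' @param store A [posture_store()].
#' @param user_id User identifier.
#' @return Invisibly, the number of events removed.
#' @export
delete_user <- function(store, user_id) {
  users <- read_users(store)
  utils::write.csv(users[users$user_id != user_id, , drop = FALSE],
                   users_path(store), row.names = FALSE)
  ev <- read_events(store)
  removed <- sum(ev$user_id == user_id)
  keep <- ev[ev$user_id != user_id, , drop = FALSE]
  write_events_file(store, keep)
  sess <- read_sessions(store)
  utils::write.csv(sess[sess$user_id != user_id, , drop = FALSE],
                   sessions_path(store), row.names = FALSE)
  invisible(removed)
}

read_sessions <- function(store) {
  p <- sessions_path(store)
  if (!file.exists(p)) {
    return(data.frame(session_id = character(0), user_id = character(0),
                      n_ticks = integer(0), frame_errors = integer(0),
                      started_at = numeric(0), ended_at = numeric(0),
                      stringsAsFactors = FALSE))
  }
  utils::read.csv(p, stringsAsFactors = FALSE, colClasses = c(
    session_id = "character", user_id = "character", n_ticks = "integer",
    frame_errors = "integer", started_at = "numeric", ended_at = "numeric"))
}

event_to_json <- function(event) {
  jsonlite::toJSON(list(
    session_id = event$session_id,
    user_id = event$user_id,
    tick_index = event$tick_index,
    timestamp = event$timestamp,
    direction = event$direction,
    triggered_conditions = I(as.character(event$triggered_conditions))
  ), auto_unbox = TRUE)
}

#' Read back recorded shift events
#'
#' Events are returned in insertion order. By design, queries return the
#' `user_id` only, never the profile fields (data minimization).
#'
#' @param store A [posture_store()].
#' @param session_id,user_id Optional filters.
#' @return Data frame with `session_id`, `user_id`, `tick_index`, `timestamp`,
#'   `direction` and `triggered_conditions` (`;`-joined).
#' @export
read_events <- function(store, session_id = NULL, user_id = NULL) {
  p <- events_path(store)
  empty <- data.frame(session_id = character(0), user_id = character(0),
                      tick_index = integer(0), timestamp = numeric(0),
                      direction = character(0), triggered_conditions = character(0),
                      stringsAsFactors = FALSE)
  if (!file.exists(p)) return(empty)
  lines <- readLines(p, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  rows <- lapply(lines, function(ln) {
    e <- jsonlite::fromJSON(ln)
    data.frame(session_id = e$session_id, user_id = e$user_id,
               tick_index = as.integer(e$tick_index),
               timestamp = as.numeric(e$timestamp),
               direction = e$direction,
               triggered_conditions = paste(e$triggered_conditions, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  if (!is.null(session_id)) ev <- ev[ev$session_id == session_id, , drop = FALSE]
  if (!is.null(user_id)) ev <- ev[ev$user_id == user_id, , drop = FALSE]
  ev
}

write_events_file <- function(store, events_df) {
  p <- events_path(store)
  if (nrow(events_df) == 0L) {
    if (file.exists(p)) file.remove(p)
    return(invisible(NULL))
  }
  lines <- vapply(seq_len(nrow(events_df)), function(i) {
    e <- events_df[i, ]
    conds <- if (nzchar(e$triggered_conditions))
      strsplit(e$triggered_conditions, ";", fixed = TRUE)[[1]] else character(0)
    as.character(event_to_json(list(
      session_id = e$session_id, user_id = e$user_id,
      tick_index = e$tick_index, timestamp = e$timestamp,
      direction = e$direction, triggered_conditions = conds)))
  }, character(1))
  writeLines(lines, p)
  invisible(NULL)
}

#' Append one shift event
#'
#' Durable append to the JSON-lines event log. The user must exist and have
#' consented; within a session, events must strictly alternate starting with
#' `ToAsymmetric` (an integrity error otherwise). If the store directory has
#' become unavailable the event is buffered in memory with a warning.
#'
#' @param store A [posture_store()].
#' @param event A `shift_event` (or list with the same fields, including
#'   `session_id` and `user_id`).
#' @return Invisibly, `TRUE` on durable append, `FALSE` when buffered.
#' @export
append_event <- function(store, event) {
  stopifnot(inherits(store, "posture_store"))
  user <- get_user(store, event$user_id)
  if (!isTRUE(user$consent)) {
    seat_abort(sprintf("user '%s' has not consented to data recording", event$user_id),
               "seatsense_consent_error")
  }
  if (!event$direction %in% c("ToAsymmetric", "ToSymmetric")) {
    seat_abort("event direction must be ToAsymmetric or ToSymmetric",
               "seatsense_value_error")
  }
  prior <- read_events(store, session_id = event$session_id)
  expected <- if (nrow(prior) == 0L) "ToAsymmetric" else
    setdiff(c("ToAsymmetric", "ToSymmetric"), prior$direction[nrow(prior)])
  if (!identical(event$direction, expected)) {
    seat_abort(sprintf(
      "alternation violation in session '%s': expected %s, got %s",
      event$session_id, expected, event$direction),
      "seatsense_integrity_error")
  }
  if (!dir.exists(store$path)) {
    store$buffer$records <- c(store$buffer$records, list(event))
    warning("event store unavailable: event buffered locally", call. = FALSE)
    return(invisible(FALSE))
  }
  cat(event_to_json(event), "\n", sep = "", file = events_path(store), append = TRUE)
  invisible(TRUE)
}

# persist a whole session record: session row + its events in order
record_session <- function(store, record) {
  stopifnot(inherits(store, "posture_store"), inherits(record, "session_record"))
  if (!dir.exists(store$path)) {
    seat_abort("store directory unavailable", "seatsense_connection_error")
  }
  ev <- record$events
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      conds <- if (nzchar(ev$triggered_conditions[i]))
        strsplit(ev$triggered_conditions[i], ";", fixed = TRUE)[[1]] else character(0)
      append_event(store, list(session_id = ev$session_id[i],
                               user_id = ev$user_id[i],
                               tick_index = ev$tick_index[i],
                               timestamp = ev$timestamp[i],
                               direction = ev$direction[i],
                               triggered_conditions = conds))
    }
  }
  sess <- read_sessions(store)
  row <- data.frame(session_id = record$session_id, user_id = record$user_id,
                    n_ticks = record$n_ticks, frame_errors = record$frame_errors,
                    started_at = record$started_at, ended_at = record$ended_at,
                    stringsAsFactors = FALSE)
  utils::write.csv(rbind(sess, row), sessions_path(store), row.names = FALSE)
  invisible(TRUE)
}

buffer_record <- function(store, record) {
  store$buffer$records <- c(store$buffer$records, list(record))
  invisible(NULL)
}

#' Sitting-behavior summary
#'
#' Per-session and overall time balance for a user: total monitoring ticks,
#' ticks spent asymmetric (summing each span from a `ToAsymmetric` event to
#' the following `ToSymmetric`; a span still open at session end is counted
#' up to the final tick), shift count, and the asymmetric time fraction.
#'
#' @param store A [posture_store()].
#' @param user_id User identifier; must exist (error otherwise). A user with
#'   no sessions yields an empty summary.
#' @param include_profile If `TRUE`, joins gender, height and weight onto the
#'   per-session rows for group-level analyses (off by default: data
#'   minimization).
#' @return A list with `sessions` (data frame: `user_id, session_id,
#'   total_ticks, asym_ticks, shift_count, asym_fraction`) and `overall`
#'   (one-row data frame with the same quantities aggregated).
#' @export
behavior_summary <- function(store, user_id, include_profile = FALSE) {
  user <- get_user(store, user_id)  # not-found error if unknown
  sess <- read_sessions(store)
  sess <- sess[sess$user_id == user_id, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sess)), function(i) {
    sid <- sess$session_id[i]
    total <- sess$n_ticks[i]
    ev <- read_events(store, session_id = sid)
    ev <- ev[order(ev$tick_index), , drop = FALSE]
    asym <- 0L
    open_at <- NA_integer_
    for (j in seq_len(nrow(ev))) {
      if (ev$direction[j] == "ToAsymmetric") {
        open_at <- ev$tick_index[j]
      } else if (!is.na(open_at)) {
        asym <- asym + (ev$tick_index[j] - open_at)
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at)) asym <- asym + (total - open_at)
    data.frame(user_id = user_id, session_id = sid, total_ticks = total,
               asym_ticks = asym, shift_count = nrow(ev),
               asym_fraction = if (total > 0) asym / total else 0,
               stringsAsFactors = FALSE)
  })
  sessions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(user_id = character(0), session_id = character(0),
               total_ticks = integer(0), asym_ticks = integer(0),
               shift_count = integer(0), asym_fraction = numeric(0),
               stringsAsFactors = FALSE)
  if (include_profile && nrow(sessions)) {
    sessions$gender <- user$gender
    sessions$height <- user$height
    sessions$weight <- user$weight
  }
  tot <- sum(sessions$total_ticks)
  overall <- data.frame(user_id = user_id,
                        sessions = nrow(sessions),
                        total_ticks = tot,
                        asym_ticks = sum(sessions$asym_ticks),
                        shift_count = sum(sessions$shift_count),
                        asym_fraction = if (tot > 0) sum(sessions$asym_ticks) / tot else 0,
                        stringsAsFactors = FALSE)
  list(sessions = sessions, overall = overall)
}

#' Export events as JSON lines
#' @param store A [posture_store()].
#' @param path Destination file.
#' @param user_id Optional filter.
#' @return `path`, invisibly.
#' @export
export_events <- function(store, path, user_id = NULL) {
  ev <- read_events(store, user_id = user_id)
  write_events_df_jsonl(ev, path)
}

write_events_df_jsonl <- function(ev, path) {
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    conds <- if (nzchar(ev$triggered_conditions[i]))
      strsplit(ev$triggered_conditions[i], ";", fixed = TRUE)[[1]] else character(0)
    as.character(event_to_json(list(
      session_id = ev$session_id[i], user_id = ev$user_id[i],
      tick_index = ev$tick_index[i], timestamp = ev$timestamp[i],
      direction = ev$direction[i], triggered_conditions = conds)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a behavior summary as CSV
#' @param summary Result of [behavior_summary()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_summary_csv <- function(summary, path) {
  utils::write.csv(summary$sessions, path, row.names = FALSE)
  invisible(path)
}
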