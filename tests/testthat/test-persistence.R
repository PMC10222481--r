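ev <- function(session, direction, tick, uid = "u0001",
               conds = if (direction == "ToAsymmetric") "top_left_heavy" else character(0)) {
  list(session_id = session, user_id = uid, tick_index = as.integer(tick),
       timestamp = tick * 0.5, direction = direction, triggered_conditions = conds)
}

test_that("user registration validates the seven profile tags and is idempotent on email", {
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile())
  expect_match(uid, "^u[0-9]+$")
  expect_identical(get_user(store, uid)$email, "ada@example.org")

  # same email registered twice returns the same id
  expect_identical(register_user(store, complete_profile()), uid)

  p <- complete_profile(email = "x@example.org")
  p$email <- NULL
  expect_error(register_user(store, p), class = "seatsense_validation_error")
  p2 <- complete_profile(email = "y@example.org")
  p2$height <- -3
  expect_error(register_user(store, p2), class = "seatsense_validation_error")
})

test_that("events append durably, in order, and read back identically", {
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile())
  append_event(store, ev("s1", "ToAsymmetric", 10, uid))
  append_event(store, ev("s1", "ToSymmetric", 30, uid))
  got <- read_events(store, session_id = "s1")
  expect_identical(got$direction, c("ToAsymmetric", "ToSymmetric"))
  expect_identical(got$tick_index, c(10L, 30L))
  expect_identical(got$triggered_conditions, c("top_left_heavy", ""))

  # byte-identical on re-read (durability round trip)
  again <- read_events(store, session_id = "s1")
  expect_identical(got, again)
})

test_that("alternation is enforced per session, starting with ToAsymmetric", {
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile())
  expect_error(append_event(store, ev("s1", "ToSymmetric", 5, uid)),
               class = "seatsense_integrity_error")
  append_event(store, ev("s1", "ToAsymmetric", 10, uid))
  expect_error(append_event(store, ev("s1", "ToAsymmetric", 20, uid)),
               class = "seatsense_integrity_error")
  # other sessions are independent
  append_event(store, ev("s2", "ToAsymmetric", 3, uid))
})

test_that("no record is ever persisted for a non-consenting or unknown user", {
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile(email = "n@example.org", consent = FALSE))
  expect_error(append_event(store, ev("s1", "ToAsymmetric", 10, uid)),
               class = "seatsense_consent_error")
  expect_error(append_event(store, ev("s1", "ToAsymmetric", 10, "u9999")),
               class = "seatsense_notfound_error")
  expect_identical(nrow(read_events(store)), 0L)
})

test_that("behavior summary computes span arithmetic, open spans and conservation", {
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile())

  rec <- structure(list(session_id = "s1", user_id = uid, consent = TRUE,
                        reference = NULL, started_at = 0, ended_at = 50,
                        n_ticks = 100L, frame_errors = 0L,
                        events = data.frame(
                          session_id = "s1", user_id = uid,
                          tick_index = c(10L, 30L), timestamp = c(5, 15),
                          direction = c("ToAsymmetric", "ToSymmetric"),
                          triggered_conditions = c("top_left_heavy", ""),
                          stringsAsFactors = FALSE),
                        flags = NULL), class = "session_record")
  seatsense:::record_session(store, rec)

  s <- behavior_summary(store, uid)
  expect_identical(s$sessions$asym_ticks, 20L)
  expect_equal(s$sessions$asym_fraction, 0.20)
  expect_identical(s$sessions$shift_count, 2L)

  # open span at session end is closed at the final tick
  rec2 <- rec
  rec2$session_id <- "s2"
  rec2$events <- data.frame(session_id = "s2", user_id = uid, tick_index = 90L,
                            timestamp = 45, direction = "ToAsymmetric",
                            triggered_conditions = "bottom_left_heavy",
                            stringsAsFactors = FALSE)
  seatsense:::record_session(store, rec2)
  s2 <- behavior_summary(store, uid)
  row2 <- s2$sessions[s2$sessions$session_id == "s2", ]
  expect_identical(row2$asym_ticks, 10L)

  # conservation: symmetric + asymmetric ticks = total, per session
  expect_true(all(s2$sessions$asym_ticks <= s2$sessions$total_ticks))
  expect_equal(s2$overall$asym_ticks, 30L)
  expect_equal(s2$overall$total_ticks, 200L)
  expect_equal(s2$overall$asym_fraction, 0.15)

  # a session with no events contributes zero
  rec3 <- rec
  rec3$session_id <- "s3"
  rec3$events <- rec$events[0, ]
  seatsense:::record_session(store, rec3)
  s3 <- behavior_summary(store, uid)
  expect_equal(s3$sessions$asym_fraction[s3$sessions$session_id == "s3"], 0)

  expect_error(behavior_summary(store, "u9999"), class = "seatsense_notfound_error")
})

test_that("event and summary exports round-trip", {
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile())
  append_event(store, ev("s1", "ToAsymmetric", 10, uid))
  append_event(store, ev("s1", "ToSymmetric", 30, uid))

  out <- withr::local_tempfile(fileext = ".jsonl")
  export_events(store, out)
  lines <- readLines(out)
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_identical(parsed$direction, "ToAsymmetric")
  expect_identical(parsed$triggered_conditions, "top_left_heavy")

  rec <- structure(list(session_id = "s1", user_id = uid, consent = TRUE,
                        reference = NULL, started_at = 0, ended_at = 50,
                        n_ticks = 100L, frame_errors = 0L,
                        events = data.frame(session_id = character(0),
                                            user_id = character(0),
                                            tick_index = integer(0),
                                            timestamp = numeric(0),
                                            direction = character(0),
                                            triggered_conditions = character(0)),
                        flags = NULL), class = "session_record")
  seatsense:::record_session(store, rec)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_summary_csv(behavior_summary(store, uid), csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("user_id", "session_id", "total_ticks",
                                  "asym_ticks", "shift_count", "asym_fraction"))
})

test_that("deleting a user removes their profile, events and sessions", {
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile())
  append_event(store, ev("s1", "ToAsymmetric", 10, uid))
  delete_user(store, uid)
  expect_error(get_user(store, uid), class = "seatsense_notfound_error")
  expect_identical(nrow(read_events(store)), 0L)
})
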