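test_that("initialization stores the per-sensor average as soon as the queue fills", {
  cfg <- cfg_default()
  frames <- frames_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), 5, cfg)
  ref <- run_initialization(frames, cfg)
  # constants survive the ADC round trip to within one quantization step
  expect_equal(unname(ref$values), c(120, 80, 120, 80), tolerance = 0.01)
  expect_identical(names(ref$values), c("Lt", "Lb", "Rt", "Rb"))
})

test_that("a sensor stuck at zero counts fails initialization naming that sensor", {
  cfg <- cfg_default()
  frames <- frames_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), 5, cfg)
  frames$Rb <- 0
  err <- tryCatch(run_initialization(frames, cfg), condition = identity)
  expect_s3_class(err, "seatsense_init_error")
  expect_match(conditionMessage(err), "Rb")
})

test_that("a stream that ends during warm-up is a connection error", {
  cfg <- cfg_default()
  frames <- frames_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), 3, cfg)
  expect_error(run_initialization(frames, cfg), class = "seatsense_connection_error")
  expect_error(run_session(frames, cfg), class = "seatsense_connection_error")
})

test_that("the reference reflects only the initialization frames", {
  cfg <- cfg_default()
  a <- frames_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), 5, cfg)
  b <- frames_for_forces(c(Lt = 150, Lb = 70, Rt = 100, Rb = 90), 10, cfg, start_tick = 5L)
  rec <- run_session(rbind(a, b), cfg)
  expect_equal(unname(rec$reference$values), c(120, 80, 120, 80), tolerance = 0.01)
  expect_identical(rec$n_ticks, 10L)
})

test_that("monitoring cannot run before initialization completes", {
  cfg <- cfg_default()
  s <- new_session(cfg)
  sample <- raw_sample(0, counts_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), cfg), cfg)
  expect_error(monitoring_step(s, sample), class = "seatsense_contract_error")
})

test_that("a sustained left shift raises exactly one warning within the filter transit", {
  cfg <- cfg_default()
  sym <- c(Lt = 120, Lb = 80, Rt = 120, Rb = 80)
  # 30% of the top load moved from right to left
  shifted <- c(Lt = 120 + 36, Lb = 80, Rt = 120 - 36, Rb = 80)
  frames <- rbind(frames_for_forces(sym, 20, cfg),
                  frames_for_forces(shifted, 20, cfg, start_tick = 20L))
  rn <- recording_notifier()
  rec <- run_session(frames, cfg, notifier = rn$notifier)
  asym_events <- rec$events[rec$events$direction == "ToAsymmetric", ]
  expect_identical(nrow(asym_events), 1L)
  expect_true(asym_events$tick_index >= 20 && asym_events$tick_index <= 25)
  expect_identical(sum(rn$log$calls == "open"), 1L)
})

test_that("shift and restoration produce an open/close pair and derived timestamps", {
  cfg <- cfg_default()
  sym <- c(Lt = 120, Lb = 80, Rt = 120, Rb = 80)
  shifted <- c(Lt = 156, Lb = 80, Rt = 84, Rb = 80)
  frames <- rbind(frames_for_forces(sym, 10, cfg),
                  frames_for_forces(shifted, 15, cfg, start_tick = 10L),
                  frames_for_forces(sym, 15, cfg, start_tick = 25L))
  rn <- recording_notifier()
  rec <- run_session(frames, cfg, notifier = rn$notifier)
  expect_identical(rec$events$direction, c("ToAsymmetric", "ToSymmetric"))
  expect_identical(rn$log$calls, c("open", "close"))
  # wall time is derived from the tick and the 500 ms sampling interval
  expect_equal(rec$events$timestamp, rec$events$tick_index * 0.5)
})

test_that("open warnings are always matched: never two opens without a close", {
  cfg <- cfg_default()
  set.seed(31)
  for (i in 1:10) {
    sched <- list(posture_scenario("symmetric", 8))
    for (k in 1:3) {
      sched <- c(sched, list(
        posture_scenario(sample(c("lean_fwd_left", "lean_back_right",
                                  "cross_left_leg"), 1), sample(6:15, 1)),
        posture_scenario("symmetric", sample(6:15, 1))))
    }
    rn <- recording_notifier()
    run_session(generate_trace(sched, simulation_config(seed = 100 + i), cfg),
                cfg, notifier = rn$notifier)
    calls <- rn$log$calls
    if (length(calls)) {
      # strict alternation starting with an open
      expect_identical(calls, rep(c("open", "close"), length.out = length(calls)))
    }
  }
})

test_that("malformed frames during monitoring are skipped and counted without corruption", {
  cfg <- cfg_default()
  sym <- frames_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), 20, cfg)
  lines <- apply(sym[, c("tick", "Lt", "Lb", "Rt", "Rb")], 1,
                 function(r) paste(as.integer(r), collapse = ","))
  lines <- append(lines, c("##corrupt##", "1,2,3"), after = 10)
  rec <- run_session(lines, cfg)
  expect_identical(rec$frame_errors, 2L)
  expect_identical(rec$n_ticks, 15L)  # 20 frames minus 5 initialization
  expect_identical(nrow(rec$events), 0L)
})

test_that("identical frame streams produce identical session records", {
  cfg <- cfg_default()
  trace <- six_posture_protocol(simulation_config(seed = 9), cfg,
                                posture_ticks = 10L, restore_ticks = 10L)
  r1 <- run_session(trace, cfg)
  r2 <- run_session(trace, cfg)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$flags, r2$flags)
  expect_identical(r1$reference$values, r2$reference$values)
})

test_that("a non-consenting user gets notifications but no persisted events", {
  cfg <- cfg_default()
  store <- posture_store(withr::local_tempdir())
  uid <- register_user(store, complete_profile(email = "noconsent@example.org",
                                               consent = FALSE))
  trace <- six_posture_protocol(simulation_config(seed = 3), cfg,
                                posture_ticks = 10L, restore_ticks = 10L)
  rn <- recording_notifier()
  rec <- run_session(trace, cfg, user = list(user_id = uid, consent = FALSE),
                     notifier = rn$notifier, store = store)
  expect_true(length(rn$log$calls) > 0)
  expect_identical(nrow(rec$events), 12L)
  expect_identical(nrow(read_events(store)), 0L)
})

test_that("the session duration guard stops monitoring with an expiry notification", {
  cfg <- cfg_default(session_limit_hours = 20 * 0.5 / 3600)  # 20 ticks
  frames <- frames_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), 60, cfg)
  rec <- run_session(frames, cfg)
  expect_lte(rec$n_ticks, 22L)
})

test_that("session status reports sensor read-out health", {
  cfg <- cfg_default()
  frames <- frames_for_forces(c(Lt = 120, Lb = 80, Rt = 120, Rb = 80), 8, cfg)
  s <- new_session(cfg)
  stream <- seatsense::read_frames(frames_to_lines(frames), cfg)$samples
  for (f in stream) {
    if (s$state == "INITIALIZATION") init_status <- session_status(s)
    if (s$state == "INITIALIZATION") seatsense:::init_step(s, f) else monitoring_step(s, f)
  }
  st <- session_status(s)
  expect_identical(st$state, "MONITORING")
  expect_identical(st$monitor_ticks, 3L)
  expect_false(any(st$sensors$clamped))
})
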