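test_that("the four realized speeds and their ordering are reproduced", {
  expect_identical(speed_of("default", "no_input", p2016), 1)
  expect_identical(speed_of("reward", "jump_block", p2016), 3)
  expect_identical(speed_of("default", "slide_laser", p2016), 0.5)
  expect_identical(speed_of("penalty", "no_input", p2016), 0.3)
  expect_identical(speed_of("penalty", "rotate_wind", p2016), 0.3)
  expect_error(speed_of("reward", "no_input", p2016), "contract violation")
  v <- c(speed_of("reward", "jump_block", p2016),
         speed_of("default", "no_input", p2016),
         speed_of("default", "jump_block", p2016),
         speed_of("penalty", "jump_block", p2016))
  expect_true(all(diff(v) < 0))
})

test_that("command transitions implement reward, penalty and override", {
  expect_identical(transition("default", "jump", "jump_block", p2016)$state, "reward")
  # reward overridden by a wrong command
  expect_identical(transition("reward", "rotate", "jump_block", p2016)$state, "penalty")
  # penalty overridden by the correct command
  expect_identical(transition("penalty", "jump", "jump_block", p2016)$state, "reward")
  # re-sending the active correct command is idempotent
  expect_identical(transition("reward", "jump", "jump_block", p2016)$state, "reward")
  # any command on no-input punishes and arms the 4 s timer
  tr <- transition("default", "rotate", "no_input", p2016)
  expect_identical(tr$state, "penalty")
  expect_identical(tr$timer, 4)
  # action-field states carry no timer
  expect_true(is.na(transition("default", "rotate", "jump_block", p2016)$timer))
})

test_that("silent crossings take 6 s (no-input) and 11 s (action)", {
  expect_equal(simulate_race(track_from_string("N", p2016), p2016)$finish_time, 6)
  for (code in c("R", "J", "S")) {
    expect_equal(simulate_race(track_from_string(code, p2016), p2016)$finish_time, 11)
  }
})

test_that("worked single-field examples integrate exactly", {
  trkJ <- track_from_string("J", p2016)
  expect_equal(simulate_race(trkJ, p2016, command_log(0, "jump"))$finish_time,
               5.5 / 3)
  # one false positive on a no-input field: 1 unit, then 4 s at 0.3, then default
  trkN <- track_from_string("N", p2016)
  expect_equal(simulate_race(trkN, p2016, command_log(1, "rotate"))$finish_time, 8.8)
  # wrong command overridden by the correct one
  expect_equal(simulate_race(trkJ, p2016,
                             command_log(c(0, 2), c("rotate", "jump")))$finish_time,
               2 + 4.9 / 3)
  # silent regulation race
  expect_equal(simulate_race(regulation_track(p2016, 11), p2016)$finish_time, 156)
})

test_that("the no-input penalty expires after 4 s and a new field resets state", {
  trk <- track_from_string("NJ", p2016)
  res <- simulate_race(trk, p2016, command_log(0, "slide"))
  # 4 s at 0.3 (1.2 units), remaining 4.8 units at 1.0: exit no-input at 8.8
  expect_equal(res$per_field$exit_time[1], 8.8)
  expect_true("PENALTY_EXPIRED" %in% res$events$type)
  # the following action field is crossed silently at the default speed
  expect_equal(res$finish_time, 8.8 + 11)
  # a command late on a no-input field: penalty truncated by the boundary
  res2 <- simulate_race(trk, p2016, command_log(5, "slide"))
  expect_equal(res2$per_field$exit_time[1], 5 + 1 / 0.3)
  st <- res2$events$state[res2$events$type == "FIELD_ENTER"]
  expect_true(all(st == "default"))
})

test_that("race results conserve time and distance", {
  set.seed(101)
  for (i in 1:50) {
    trk <- rand_track()
    res <- simulate_race(trk, p2016, rand_log(trk))
    dur <- res$per_field$exit_time - res$per_field$entry_time
    expect_equal(sum(dur), res$finish_time, tolerance = 1e-12)
    expect_equal(res$per_field$entry_time[-1],
                 res$per_field$exit_time[-n_fields(trk)])
    expect_equal(res$events$position[res$events$type == "FINISH"],
                 trk$total_length)
    expect_true(!is.unsorted(res$events$time))
  }
})

test_that("the engine rejects malformed command logs", {
  expect_error(command_log(c(2, 1), c("jump", "jump")), "non-decreasing")
  expect_error(command_log(-1, "jump"), ">= 0")
  expect_error(command_log(0, "hop"), "unknown command")
})

test_that("stepped and event-driven integrators agree on worked examples", {
  trkN <- track_from_string("N", p2016)
  trkJ <- track_from_string("J", p2016)
  expect_equal(simulate_race_stepped(trkN, p2016, dt = 1e-3), 6, tolerance = 2e-3)
  expect_equal(simulate_race_stepped(trkJ, p2016, command_log(0, "jump"), dt = 1e-3),
               5.5 / 3, tolerance = 2e-3)
  expect_error(simulate_race_stepped(trkN, p2016, dt = 0), "dt must be > 0")
})

test_that("event-driven and stepped engines agree on fuzzed races", {
  set.seed(2024)
  for (i in 1:200) {
    trk <- rand_track()
    log <- rand_log(trk)
    expect_equal(simulate_race(trk, p2016, log)$finish_time,
                 simulate_race_stepped(trk, p2016, log, dt = 1e-3),
                 tolerance = 2e-3)
  }
})

test_that("a trailing incorrect command never speeds up the race", {
  # The penalty mechanism itself is monotone: appending a command that is
  # incorrect for the field it lands on (or any command on no-input), at or
  # after every other logged command, can only slow the remaining run.
  # (Inserting one *between* fixed-time commands can paradoxically help, by
  # shifting a later command onto the field where it is correct; that
  # interaction is exercised separately.)
  set.seed(7)
  for (i in 1:100) {
    trk <- rand_track()
    log <- rand_log(trk)
    base <- simulate_race(trk, p2016, log)
    t_min <- if (nrow(log)) max(log$time_s) else 0
    if (t_min >= base$finish_time) next
    t_new <- runif(1, t_min, base$finish_time)
    fi <- findInterval(t_new, base$per_field$entry_time)
    kind <- trk$fields$kind[fi]
    wrong <- if (is_action_field(kind)) {
      sample(setdiff(commands(), correct_command(kind)), 1)
    } else sample(commands(), 1)
    log2 <- command_log(c(log$time_s, t_new), c(log$command, wrong))
    expect_gte(simulate_race(trk, p2016, log2)$finish_time,
               base$finish_time - 1e-9)
  }
})

test_that("a mid-log penalty can shift a later command onto its correct field", {
  # Documented counterexample to unrestricted insertion monotonicity: on
  # R then J, a lone rotate at t = 11.5 lands on J (wrong, heavy penalty);
  # slowing the run with an incorrect slide at t = 0 makes the same rotate
  # land on R, where it is correct, and the race finishes earlier.
  trk <- race_track(c("rotate_wind", "jump_block"), p2016)
  base <- simulate_race(trk, p2016, command_log(11.5, "rotate"))$finish_time
  ins <- simulate_race(trk, p2016,
                       command_log(c(0, 11.5), c("slide", "rotate")))$finish_time
  expect_equal(base, 29)
  expect_equal(ins, 11.5 + (5.5 - 11.5 * 0.3) / 3 + 11)
  expect_lt(ins, base)
})

test_that("delaying the sole correct command on an action field never helps", {
  set.seed(8)
  for (i in 1:100) {
    kind <- sample(c("rotate_wind", "jump_block", "slide_laser"), 1)
    trk <- race_track(kind, p2016)
    delays <- sort(runif(2, 0, 11))
    t1 <- simulate_race(trk, p2016,
                        command_log(delays[1], correct_command(kind)))$finish_time
    t2 <- simulate_race(trk, p2016,
                        command_log(delays[2], correct_command(kind)))$finish_time
    expect_gte(t2, t1 - 1e-9)
    expect_lte(t1, 11 + 1e-9)  # still beneficial versus silence
  }
})
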