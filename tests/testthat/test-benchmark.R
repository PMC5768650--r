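test_that("race metrics count incorrect commands and time-to-correct delays", {
  # one jump field entered at 8.0 after a no-input field; wrong rotate at
  # 10.0 then correct jump at 12.5
  trk <- track_from_string("NJ", p2016)
  res <- simulate_race(trk, p2016, command_log(c(10, 12.5), c("rotate", "jump")))
  expect_equal(res$per_field$entry_time[2], 6)
  m <- race_metrics(res, trk)
  expect_equal(m$incorrect_command_count, 1)
  expect_equal(m$noinput_false_positives, 0)
  expect_equal(nrow(m$per_action_field), 1)
  # first correct at 12.5 after entry at 6; wrong-to-correct gap 2.5 s
  expect_equal(m$per_action_field$time_to_correct_command, 6.5)
  expect_equal(m$per_action_field$correction_time, 2.5)
})

test_that("race metrics handle silent runs, spam and unanswered fields", {
  trk <- track_from_string("NJ", p2016)
  m0 <- race_metrics(simulate_race(trk, p2016), trk)
  expect_equal(m0$incorrect_command_count, 0)
  expect_equal(nrow(m0$per_action_field), 0)
  # every spam command on a pure no-input track is a false positive
  trkN <- track_from_string("NN", p2016)
  out <- run_closed_loop(spam_agent(2), trkN, p2016, 3)
  m1 <- race_metrics(out$result, trkN)
  expect_equal(m1$noinput_false_positives, nrow(out$log))
  expect_equal(m1$incorrect_command_count, nrow(out$log))
  # a field with only wrong commands has no time-to-correct
  res <- simulate_race(trk, p2016, command_log(9, "slide"))
  m2 <- race_metrics(res, trk)
  expect_true(is.na(m2$per_action_field$time_to_correct_command))
  expect_true(is.na(m2$per_action_field$correction_time))
  expect_error(race_metrics(res, track_from_string("JJ", p2016)),
               "not produced on this track")
})

test_that("metrics conservation: incorrect = emitted - correct-on-action", {
  set.seed(17)
  for (i in 1:30) {
    trk <- rand_track()
    log <- rand_log(trk)
    res <- simulate_race(trk, p2016, log)
    m <- race_metrics(res, trk)
    expect_equal(m$incorrect_command_count,
                 nrow(res$commands) - sum(res$commands$correct))
  }
})

test_that("deterministic agents benchmark with zero spread", {
  s <- monte_carlo(silent_agent(), regulation_track(p2016, 2), p2016, 10, 1)
  expect_equal(s$n_races, 10L)
  expect_equal(s$mean_finish, 156)
  expect_equal(s$sd_finish, 0)
  o <- monte_carlo(oracle_agent(0), regulation_track(p2016, 2), p2016, 10, 1)
  expect_equal(o$mean_finish, 46)
  expect_equal(o$sd_finish, 0)
  # the regulation policy reshuffles per race, but equal composition keeps
  # the silent finish constant
  s2 <- monte_carlo(silent_agent(), "regulation", p2016, 10, 1)
  expect_equal(s2$sd_finish, 0)
  expect_equal(s2$mean_finish, 156)
})

test_that("benchmark summaries are reproducible per master seed", {
  pr <- accuracy_profile(0.8, rest_none = 0.9)
  a <- monte_carlo(classifier_agent(pr), "regulation", p2016, 30, 42)
  b <- monte_carlo(classifier_agent(pr), "regulation", p2016, 30, 42)
  expect_identical(a, b)
  c1 <- monte_carlo(classifier_agent(pr), "regulation", p2016, 30, 43)
  expect_false(identical(a$finish_times, c1$finish_times))
  expect_equal(length(a$finish_times), 30)
  expect_equal(unname(a$quantiles[2]), unname(stats::median(a$finish_times)))
})

test_that("mean finish decreases with classifier accuracy over matched seeds", {
  means <- vapply(c(0.5, 0.7, 0.9), function(a) {
    monte_carlo(classifier_agent(accuracy_profile(a, rest_none = 0.95)),
                "regulation", p2016, 60, 7)$mean_finish
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("standard error shrinks roughly as 1/sqrt(n) for the spam pilot", {
  s100 <- monte_carlo(spam_agent(2), "regulation", p2016, 100, 5)
  s400 <- monte_carlo(spam_agent(2), "regulation", p2016, 400, 5)
  se100 <- s100$sd_finish / sqrt(100)
  se400 <- s400$sd_finish / sqrt(400)
  expect_lt(se400, se100)
  # ratio should be near 2 (loose band: sd estimates are themselves noisy)
  expect_gt(se100 / se400, 1.4)
  expect_lt(se100 / se400, 2.9)
})

test_that("break-even accuracy search brackets and reports its status", {
  # a profile with heavy false positives makes the crossing interior or
  # high; the default rest row beats silence already at accuracy 1/3
  be <- breakeven_accuracy(p2016, "regulation", n_races = 20, tol = 0.05,
                           master_seed = 3)
  expect_true(be$status %in% c("ok", "below_range", "above_range"))
  expect_equal(be$baseline, 156)
  if (be$status == "ok") expect_true(be$accuracy > 1/3 && be$accuracy <= 1)
  if (be$status == "below_range") expect_equal(be$accuracy, 1/3)
  # perfect accuracy with no false positives always beats silence
  m1 <- monte_carlo(classifier_agent(accuracy_profile(1, rest_none = 1)),
                    "regulation", p2016, 10, 3)
  expect_lt(m1$mean_finish, 156)
  # a family strictly worse than silence (always-wrong commands, heavy
  # false positives) has no crossing: flagged, not an error
  never <- function(a) classifier_profile(rbind(c(0, 0.5, 0.5, 0),
                                                c(0.5, 0, 0.5, 0),
                                                c(0.5, 0.5, 0, 0),
                                                c(0.2, 0.2, 0.2, 0.4)))
  be2 <- breakeven_accuracy(p2016, "regulation", n_races = 5, tol = 0.05,
                            master_seed = 3, profile_fn = never)
  expect_equal(be2$status, "above_range")
  expect_true(is.na(be2$accuracy))
})

test_that("break-even search is deterministic per master seed", {
  be1 <- breakeven_accuracy(p2016, "regulation", n_races = 15, tol = 0.05,
                            master_seed = 9)
  be2 <- breakeven_accuracy(p2016, "regulation", n_races = 15, tol = 0.05,
                            master_seed = 9)
  expect_identical(be1$accuracy, be2$accuracy)
  expect_identical(be1$evaluations, be2$evaluations)
})

test_that("ordering report ranks agents by mean finish with labels intact", {
  agents <- list(silent = silent_agent(), oracle0 = oracle_agent(0),
                 spam1s = spam_agent(1))
  rep <- ordering_report(p2016, agents, regulation_track(p2016, 2),
                         n_races = 10, master_seed = 1)
  expect_setequal(rep$label, names(agents))
  expect_equal(rep$label[1], "oracle0")          # 46 s beats everything
  expect_false(is.unsorted(rep$mean_finish))
  expect_equal(rep$mean_finish[rep$label == "silent"], 156)
  # on a pure no-input track, silence strictly beats 1 s spam (6 vs 20 s/field)
  repN <- ordering_report(p2016, list(silent = silent_agent(),
                                      spam1s = spam_agent(1)),
                          track_from_string("NNNN", p2016),
                          n_races = 5, master_seed = 1)
  expect_lt(repN$mean_finish[repN$label == "silent"],
            repN$mean_finish[repN$label == "spam1s"])
})

test_that("all-none profile never emits and the allnone breakeven baseline holds", {
  # guards the breakeven edge: an agent that cannot emit matches silence
  pr <- classifier_profile(matrix(rep(c(0, 0, 0, 1), each = 4), 4))
  m <- monte_carlo(classifier_agent(pr), "regulation", p2016, 5, 2)
  expect_equal(m$mean_finish, 156)
  expect_equal(m$mean_incorrect_commands, 0)
})
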