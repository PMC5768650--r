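#' Per-race command metrics
#'
#' Beyond the finish time, a race log supports finer BCI performance
#' metrics: the total number of incorrectly sent commands (wrong command
#' on an action field, or any command on a no-input field), the time
#' needed to successfully send a command on an action field (first
#' correct command relative to field entry), and the time needed to
#' correct an incorrect command (first correct command relative to the
#' last preceding incorrect command on the same field).
#'
#' @param result a `race_result` from [simulate_race()] or
#'   [run_closed_loop()].
#' @param track the `race_track` the result was produced on.
#' @return a `metrics_report`: list with `incorrect_command_count`,
#'   `noinput_false_positives`, and `per_action_field`, a data.frame (one
#'   row per action field that received at least one command) with
#'   columns `field_index`, `kind`, `entry_time`, `commands_received`,
#'   `time_to_correct_command` (NA if no correct command arrived) and
#'   `correction_time` (NA unless an incorrect command preceded the first
#'   correct one).
#' @examples
#' p <- default_params_2016()
#' trk <- track_from_string("NJ", p)
#' res <- simulate_race(trk, p, command_log(c(10, 12.5), c("rotate", "jump")))
#' race_metrics(res, trk)$per_action_field
#' @export
race_metrics <- function(result, track) {
  if (!inherits(result, "race_result")) stop("result must be a race_result")
  if (!inherits(track, "race_track")) stop("track must be a race_track")
  if (nrow(result$per_field) != nrow(track$fields) ||
      !all(result$per_field$kind == track$fields$kind)) {
    stop("result was not produced on this track")
  }
  cmds <- result$commands
  pf <- result$per_field
  action_rows <- which(is_action_field(pf$kind) & pf$commands_received > 0)
  per_field <- do.call(rbind, lapply(action_rows, function(i) {
    ci <- cmds[cmds$field_index == i, , drop = FALSE]
    t_first_ok <- if (any(ci$correct)) min(ci$time_s[ci$correct]) else NA_real_
    corr <- NA_real_
    if (!is.na(t_first_ok)) {
      before <- ci$time_s[!ci$correct & ci$time_s <= t_first_ok]
      if (length(before)) corr <- t_first_ok - max(before)
    }
    data.frame(field_index = i, kind = pf$kind[i],
               entry_time = pf$entry_time[i],
               commands_received = pf$commands_received[i],
               time_to_correct_command = t_first_ok - pf$entry_time[i],
               correction_time = corr, stringsAsFactors = FALSE)
  }))
  if (is.null(per_field)) {
    per_field <- data.frame(field_index = integer(0), kind = character(0),
                            entry_time = numeric(0),
                            commands_received = integer(0),
                            time_to_correct_command = numeric(0),
                            correction_time = numeric(0),
                            stringsAsFactors = FALSE)
  }
  structure(list(
    incorrect_command_count = sum(!cmds$correct),
    noinput_false_positives = sum(pf$commands_received[pf$kind == "no_input"]),
    per_action_field = per_field), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Command metrics: %d incorrect commands (%d on no-input fields)\n",
              x$incorrect_command_count, x$noinput_false_positives))
  if (nrow(x$per_action_field)) print(x$per_action_field)
  invisible(x)
}

# Resolve a track policy for race i: either a fixed race_track, or the
# string "regulation" for a freshly shuffled regulation track per race.
.policy_track <- function(track_policy, params, track_seed) {
  if (inherits(track_policy, "race_track")) {
    track_policy
  } else if (identical(track_policy, "regulation")) {
    regulation_track(params, track_seed)
  } else {
    stop("track_policy must be a race_track or the string \"regulation\"")
  }
}

#' Monte-Carlo benchmark of an agent
#'
#' Runs `n_races` independent closed-loop races and summarizes the
#' finish-time distribution.  A live competition holds a single short
#' race, which is vulnerable to random effects; repetition maps an
#' agent's quality parameters to a race-time distribution instead.  Race
#' seeds (and, under the `"regulation"` track policy, per-race track
#' shuffle seeds) are spawned deterministically from `master_seed`, so
#' identical inputs give identical summaries.
#'
#' @param agent a `race_agent` or an [agent_config()].
#' @param track_policy a fixed `race_track`, or `"regulation"` for a
#'   freshly shuffled 16-field regulation track per race.
#' @param params a `game_params` object.
#' @param n_races number of races (>= 1).
#' @param master_seed integer master seed.
#' @return a `benchmark_summary`: list with `n_races`, `mean_finish`,
#'   `sd_finish`, `quantiles` (5%, 50%, 95%), `mean_incorrect_commands`,
#'   the per-race `finish_times` and `incorrect_counts`, and `seeds_used`.
#' @export
monte_carlo <- function(agent, track_policy, params, n_races, master_seed) {
  if (inherits(agent, "agent_config")) agent <- build_agent(agent)
  if (!inherits(agent, "race_agent")) stop("agent must be a race_agent")
  if (n_races < 1) stop("n_races must be >= 1")
  seeds <- .spawn_seeds(master_seed, 2L * n_races)
  race_seeds <- seeds[seq_len(n_races)]
  track_seeds <- seeds[n_races + seq_len(n_races)]
  finish <- numeric(n_races)
  wrong <- integer(n_races)
  for (i in seq_len(n_races)) {
    trk <- .policy_track(track_policy, params, track_seeds[i])
    out <- run_closed_loop(agent, trk, params, race_seeds[i])
    finish[i] <- out$result$finish_time
    wrong[i] <- sum(!out$result$commands$correct)
  }
  structure(list(
    n_races = as.integer(n_races),
    mean_finish = mean(finish),
    sd_finish = if (n_races > 1) stats::sd(finish) else 0,
    quantiles = stats::quantile(finish, c(0.05, 0.5, 0.95), names = TRUE),
    mean_incorrect_commands = mean(wrong),
    finish_times = finish,
    incorrect_counts = wrong,
    seeds_used = race_seeds), class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("Benchmark over %d races: mean finish %.3f s (sd %.3f)\n",
              x$n_races, x$mean_finish, x$sd_finish))
  cat(sprintf("  quantiles 5/50/95%%: %.3f / %.3f / %.3f s\n",
              x$quantiles[1], x$quantiles[2], x$quantiles[3]))
  cat(sprintf("  mean incorrect commands per race: %.2f\n",
              x$mean_incorrect_commands))
  invisible(x)
}

#' Break-even classifier accuracy against the silent baseline
#'
#' The game is balanced so that a realistic BCI accuracy beats sending no
#' command at all.  This function quantifies the claim: it bisects on the
#' diagonal accuracy `a` of [accuracy_profile()] for the smallest
#' accuracy whose mean finish time over `n_races` races is no worse than
#' the silent pilot's on the same track policy.  All bisection
#' evaluations reuse the same spawned seed set (common random numbers),
#' so Monte-Carlo noise largely cancels between evaluations.
#'
#' @param params a `game_params` object.
#' @param track_policy as in [monte_carlo()].
#' @param n_races races per evaluation.
#' @param tol bisection tolerance on the accuracy (> 0).
#' @param master_seed integer master seed.
#' @param profile_fn function mapping an accuracy in [1/3, 1] to a
#'   `classifier_profile`; defaults to [accuracy_profile()] with its
#'   default rest row.
#' @return a `breakeven_result`: list with `accuracy` (NA when out of
#'   range), `status` (`"ok"`, `"below_range"` if even accuracy 1/3
#'   beats silence, or `"above_range"` if accuracy 1 does not),
#'   `baseline` (silent mean finish), and `evaluations` (accuracies and
#'   mean finish times visited).
#' @export
breakeven_accuracy <- function(params, track_policy = "regulation",
                               n_races = 200, tol = 0.01, master_seed = 1,
                               profile_fn = accuracy_profile) {
  if (tol <= 0) stop("tol must be > 0")
  baseline <- monte_carlo(silent_agent(), track_policy, params, n_races,
                          master_seed)$mean_finish
  acc_hist <- numeric(0); mean_hist <- numeric(0)
  eval_mean <- function(a) {
    m <- monte_carlo(classifier_agent(profile_fn(a)), track_policy, params,
                     n_races, master_seed)$mean_finish
    acc_hist <<- c(acc_hist, a); mean_hist <<- c(mean_hist, m)
    m
  }
  lo <- 1 / 3; hi <- 1
  if (eval_mean(hi) > baseline) {
    return(structure(list(accuracy = NA_real_, status = "above_range",
                          baseline = baseline,
                          evaluations = data.frame(accuracy = acc_hist,
                                                   mean_finish = mean_hist)),
                     class = "breakeven_result"))
  }
  if (eval_mean(lo) <= baseline) {
    return(structure(list(accuracy = lo, status = "below_range",
                          baseline = baseline,
                          evaluations = data.frame(accuracy = acc_hist,
                                                   mean_finish = mean_hist)),
                     class = "breakeven_result"))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_mean(mid) <= baseline) hi <- mid else lo <- mid
  }
  structure(list(accuracy = hi, status = "ok", baseline = baseline,
                 evaluations = data.frame(accuracy = acc_hist,
                                          mean_finish = mean_hist)),
            class = "breakeven_result")
}

#' @export
print.breakeven_result <- function(x, ...) {
  cat(sprintf("Break-even accuracy: %s (status %s; silent baseline %.3f s)\n",
              ifelse(is.na(x$accuracy), "out of range",
                     sprintf("%.4f", x$accuracy)), x$status, x$baseline))
  invisible(x)
}

#' Empirical ordering of agents by mean finish time
#'
#' Benchmarks each named agent on the same track policy with common
#' spawned seeds and returns them ordered by mean finish time with
#' standard errors.  The ordering is reported, not asserted: whether
#' silence really beats random spamming depends on the spam rate and the
#' track's no-input/action composition, which this report quantifies.
#'
#' @param params a `game_params` object.
#' @param agents named list of `race_agent` or [agent_config()] objects.
#' @param track_policy as in [monte_carlo()].
#' @param n_races races per agent.
#' @param master_seed integer master seed, shared across agents.
#' @return a data.frame with columns `label`, `mean_finish`, `se_finish`,
#'   `sd_finish`, `mean_incorrect`, `n_races`, sorted by `mean_finish`.
#' @export
ordering_report <- function(params, agents, track_policy = "regulation",
                            n_races = 100, master_seed = 1) {
  if (is.null(names(agents)) || any(names(agents) == "")) {
    stop("agents must be a fully named list")
  }
  rows <- lapply(names(agents), function(lbl) {
    s <- monte_carlo(agents[[lbl]], track_policy, params, n_races, master_seed)
    data.frame(label = lbl, mean_finish = s$mean_finish,
               se_finish = s$sd_finish / sqrt(s$n_races),
               sd_finish = s$sd_finish,
               mean_incorrect = s$mean_incorrect_commands,
               n_races = s$n_races, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_finish), , drop = FALSE]
}
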