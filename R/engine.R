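#' Timestamped command logs
#'
#' A command log records the discrete commands a pilot sent, as
#' `(time_s, command)` pairs with non-decreasing times.  An empty log
#' encodes a silent pilot.
#'
#' @param time_s numeric vector of command times, seconds since race start.
#' @param command character vector of commands (`rotate`, `jump`, `slide`).
#' @return a `command_log` data.frame with columns `time_s` and `command`.
#' @export
command_log <- function(time_s = numeric(0), command = character(0)) {
  if (length(time_s) != length(command)) {
    stop("time_s and command must have equal length")
  }
  time_s <- as.numeric(time_s)
  command <- as.character(command)
  if (length(time_s)) {
    if (anyNA(time_s) || any(time_s < 0)) stop("command times must be >= 0")
    if (is.unsorted(time_s)) stop("command times must be non-decreasing")
    bad <- setdiff(unique(command), commands())
    if (length(bad)) stop("unknown command: ", paste(bad, collapse = ", "))
  }
  structure(data.frame(time_s = time_s, command = command,
                       stringsAsFactors = FALSE),
            class = c("command_log", "data.frame"))
}

#' @rdname command_log
#' @export
empty_command_log <- function() command_log()

#' Avatar speed for a speed-state / field-kind pair
#'
#' The avatar has three speed states -- `default`, `reward`, `penalty` --
#' and its realized speed depends on the kind of field it is on, giving
#' the game's four possible speeds: reward on an action field, the
#' no-input default, the action-field default, and the punish speed.
#' Reward is only reachable on action fields.
#'
#' @param state one of `"default"`, `"reward"`, `"penalty"`.
#' @param kind a field kind (see [field_kinds()]).
#' @param params a `game_params` object.
#' @return the speed in track-units per second.
#' @examples
#' speed_of("reward", "jump_block", default_params_2016())
#' @export
speed_of <- function(state, kind, params) {
  if (!state %in% c("default", "reward", "penalty")) {
    stop("unknown speed state: ", state)
  }
  if (!kind %in% field_kinds()) stop("unknown field kind: ", kind)
  if (kind == "no_input") {
    if (state == "reward") {
      stop("contract violation: reward state is unreachable on a no-input field")
    }
    if (state == "default") params$s_default_noinput else params$s_punish_noinput
  } else {
    switch(state,
           default = params$s_default_action,
           reward  = params$s_reward_action,
           penalty = params$s_punish_action)
  }
}

#' Speed-state transition on receiving a command
#'
#' On a no-input field any command triggers the penalty and (re)starts the
#' penalty timer at its maximum.  On an action field the correct command
#' enters (or re-enters) the reward state and a wrong command enters the
#' penalty state; both last until the field ends or another command
#' overrides them, with no timer.
#'
#' @param state current speed state.
#' @param cmd the received command.
#' @param kind kind of the field the avatar is on.
#' @param params a `game_params` object.
#' @return a list with `state` (new speed state) and `timer` (remaining
#'   penalty duration in seconds, or `NA` when no timer applies).
#' @export
transition <- function(state, cmd, kind, params) {
  if (!cmd %in% commands()) stop("unknown command: ", cmd)
  if (!kind %in% field_kinds()) stop("unknown field kind: ", kind)
  if (kind == "no_input") {
    list(state = "penalty", timer = params$t_max_punish_noinput)
  } else if (identical(cmd, correct_command(kind))) {
    list(state = "reward", timer = NA_real_)
  } else {
    list(state = "penalty", timer = NA_real_)
  }
}

# ---------------------------------------------------------------------------
# Incremental event-driven engine.  State lives in an environment so the
# closed-loop harness can interleave agent decisions with advancement.
# Event ordering at equal times: field boundary, then penalty expiry, then
# command (a command at a boundary instant applies to the field being
# entered).

.engine_init <- function(track, params) {
  e <- new.env(parent = emptyenv())
  e$track <- track
  e$params <- params
  e$nf <- nrow(track$fields)
  e$t <- 0
  e$pos <- 0
  e$ta <- 0   # anchor time/position of the last state event: all motion is
  e$pa <- 0   # computed from the anchors so pausing never alters rounding
  e$fi <- 1L
  e$state <- "default"
  e$deadline <- Inf
  e$pending_t <- numeric(0)
  e$pending_c <- character(0)
  e$finished <- FALSE
  e$finish_time <- NA_real_
  e$ev <- list()                       # event rows, appended in time order
  e$entry <- rep(NA_real_, e$nf); e$entry[1] <- 0
  e$exit <- rep(NA_real_, e$nf)
  e$cmd_t <- numeric(0); e$cmd_c <- character(0)
  e$cmd_f <- integer(0); e$cmd_ok <- logical(0)
  .engine_event(e, "FIELD_ENTER")
  e
}

.engine_event <- function(e, type) {
  e$ev[[length(e$ev) + 1L]] <- list(time = e$t, type = type,
                                    field_index = min(e$fi, e$nf),
                                    state = e$state, position = e$pos)
  invisible(e)
}

# Schedule future command events (must not precede the current engine time).
.engine_schedule <- function(e, time_s, command) {
  if (any(time_s < e$t - 1e-12)) stop("cannot schedule a command in the past")
  ord <- order(c(e$pending_t, time_s))
  e$pending_t <- c(e$pending_t, pmax(time_s, e$t))[ord]
  e$pending_c <- c(e$pending_c, command)[ord]
  invisible(e)
}

.engine_speed <- function(e) {
  speed_of(e$state, e$track$fields$kind[e$fi], e$params)
}

# Advance until the race finishes, the stop time is reached, or (optionally)
# a field boundary is crossed.  Returns "finished", "paused" or "entered".
.engine_run_until <- function(e, t_stop = Inf, stop_on_enter = FALSE) {
  # Tolerance for event-time ties.  Boundary-crossing times are recomputed
  # from accumulated (t, pos) and can differ in the last ulp between a
  # paused (closed-loop) and an uninterrupted (replay) run of the same
  # race; commands emitted exactly on a boundary must resolve the
  # boundary-first tie-break identically in both, so times within eps are
  # treated as equal.
  eps <- 1e-9
  repeat {
    if (e$finished) return("finished")
    kind <- e$track$fields$kind[e$fi]
    fend <- e$track$fields$start_position[e$fi] + e$track$fields$length[e$fi]
    v <- speed_of(e$state, kind, e$params)
    t_bound <- e$ta + (fend - e$pa) / v
    t_exp <- e$deadline
    t_cmd <- if (length(e$pending_t)) e$pending_t[1] else Inf
    t_next <- min(t_bound, t_exp, t_cmd)
    if (t_next > t_stop + eps) {
      e$pos <- e$pa + v * (t_stop - e$ta)
      e$t <- t_stop
      return("paused")
    }
    if (t_bound <= t_exp + eps && t_bound <= t_cmd + eps) {
      # boundary crossing: exact position, state resets, timers cancel
      e$pos <- fend; e$pa <- fend
      e$t <- t_bound; e$ta <- t_bound
      e$exit[e$fi] <- t_bound
      e$state <- "default"
      e$deadline <- Inf
      if (e$fi == e$nf) {
        e$finished <- TRUE
        e$finish_time <- t_bound
        .engine_event(e, "FINISH")
        return("finished")
      }
      e$fi <- e$fi + 1L
      e$entry[e$fi] <- t_bound
      .engine_event(e, "FIELD_ENTER")
      if (stop_on_enter) return("entered")
    } else if (t_exp <= t_cmd) {
      tev <- max(t_exp, e$ta)
      e$pos <- e$pa + v * (tev - e$ta); e$pa <- e$pos
      e$t <- tev; e$ta <- tev
      e$state <- "default"
      e$deadline <- Inf
      .engine_event(e, "PENALTY_EXPIRED")
    } else {
      cmd <- e$pending_c[1]
      tev <- max(t_cmd, e$ta)
      e$pos <- e$pa + v * (tev - e$ta); e$pa <- e$pos
      e$t <- tev; e$ta <- tev
      e$pending_t <- e$pending_t[-1]
      e$pending_c <- e$pending_c[-1]
      tr <- transition(e$state, cmd, kind, e$params)
      e$state <- tr$state
      e$deadline <- if (is.na(tr$timer)) Inf else e$t + tr$timer
      e$cmd_t <- c(e$cmd_t, e$t)
      e$cmd_c <- c(e$cmd_c, cmd)
      e$cmd_f <- c(e$cmd_f, e$fi)
      e$cmd_ok <- c(e$cmd_ok, is_action_field(kind) &&
                      identical(cmd, correct_command(kind)))
      .engine_event(e, "COMMAND_APPLIED")
    }
  }
}

.engine_result <- function(e, log) {
  ev <- do.call(rbind, lapply(e$ev, function(r) {
    data.frame(time = r$time, type = r$type, field_index = r$field_index,
               state = r$state, position = r$position,
               stringsAsFactors = FALSE)
  }))
  cmds <- data.frame(time_s = e$cmd_t, command = e$cmd_c,
                     field_index = e$cmd_f, correct = e$cmd_ok,
                     stringsAsFactors = FALSE)
  per_field <- data.frame(field_index = seq_len(e$nf),
                          kind = e$track$fields$kind,
                          entry_time = e$entry, exit_time = e$exit,
                          commands_received = tabulate(e$cmd_f, nbins = e$nf),
                          stringsAsFactors = FALSE)
  structure(list(finish_time = e$finish_time, events = ev,
                 per_field = per_field, commands = cmds,
                 command_log = log, total_length = e$track$total_length),
            class = "race_result")
}

#' Simulate one race from a timestamped command log
#'
#' Integrates the avatar's piecewise-constant motion exactly, event by
#' event (command arrivals, penalty expirations, field-boundary
#' crossings).  Entering a new field always resets the speed state to
#' default and cancels any pending penalty timer.  At equal timestamps a
#' boundary crossing is processed before a command, so a command arriving
#' exactly at a boundary applies to the field being entered.  The result
#' is a deterministic function of its inputs.
#'
#' @param track a `race_track`.
#' @param params a `game_params` object.
#' @param log a `command_log` (default: empty, i.e. a silent pilot).
#' @return a `race_result`: list with `finish_time` (s), `events`
#'   (time-ordered data.frame of `FIELD_ENTER` / `COMMAND_APPLIED` /
#'   `PENALTY_EXPIRED` / `FINISH` rows), `per_field` (entry/exit times and
#'   command counts), `commands` (each applied command with its field and
#'   correctness) and `total_length`.
#' @examples
#' p <- default_params_2016()
#' simulate_race(track_from_string("N", p), p)$finish_time  # 6 s
#' simulate_race(track_from_string("J", p), p,
#'               command_log(0, "jump"))$finish_time        # 5.5/3 s
#' @export
simulate_race <- function(track, params, log = empty_command_log()) {
  if (!inherits(track, "race_track")) stop("track must be a race_track")
  log <- command_log(log$time_s, log$command)  # re-validates ordering
  e <- .engine_init(track, params)
  if (nrow(log)) .engine_schedule(e, log$time_s, log$command)
  .engine_run_until(e, Inf)
  .engine_result(e, log)
}

#' @export
print.race_result <- function(x, ...) {
  cat(sprintf("Race result: finish time %.3f s over %d fields (%g units)\n",
              x$finish_time, nrow(x$per_field), x$total_length))
  cat(sprintf("  commands applied: %d (%d incorrect)\n",
              nrow(x$commands), sum(!x$commands$correct)))
  invisible(x)
}

#' Time-stepped reference integrator
#'
#' A brute-force forward time-marching implementation of the same race
#' rules, independent of the event-driven engine: the avatar position is
#' advanced in steps of at most `dt`, with steps additionally capped at
#' command times and penalty expiries, and field-boundary crossings
#' located by linear interpolation inside a step.  Used as a
#' cross-checking oracle for [simulate_race()]; the two agree as
#' `dt -> 0`.
#'
#' @inheritParams simulate_race
#' @param dt maximum step size in seconds (> 0).
#' @return finish time in seconds.
#' @export
simulate_race_stepped <- function(track, params, log = empty_command_log(),
                                  dt = 1e-3) {
  if (!(is.numeric(dt) && length(dt) == 1 && dt > 0)) stop("dt must be > 0")
  log <- command_log(log$time_s, log$command)
  kind_id <- match(track$fields$kind, field_kinds()) - 1L
  cmd_id <- match(log$command, commands()) - 1L
  stepped_race_cpp(kind_id, track$fields$length,
                   track$fields$start_position, log$time_s, cmd_id,
                   c(params$s_reward_action, params$s_default_noinput,
                     params$s_default_action, params$s_punish_noinput,
                     params$s_punish_action, params$t_max_punish_noinput),
                   dt)
}
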