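#' Pilot agents
#'
#' Agents are closed-loop pilot models: at decision instants they receive
#' an observation of the race state and may emit timestamped commands.
#' An agent is a list with fields `kind`, `init(params)` (returning the
#' agent's private state) and `decide(state, obs)` (returning
#' `list(state, commands, next_wake)`).  The harness [run_closed_loop()]
#' wakes an agent at its requested `next_wake` times and additionally at
#' every field entry.
#'
#' * `silent_agent()` never sends a command; it models the fall-back that
#'   a racer finishes even without any correct command.
#' * `spam_agent()` sends a uniformly random command every `spam_period`
#'   seconds, the strategy the game is balanced against.
#' * `oracle_agent()` sends the correct command exactly `latency` seconds
#'   after entering each action field and stays silent on no-input fields:
#'   an upper performance bound at a given reaction time.
#'
#' @param spam_period seconds between spam commands (> 0); the first
#'   command is sent at t = 0.
#' @param latency oracle reaction time in seconds (>= 0).
#' @return an object of class `race_agent`.
#' @seealso [classifier_agent()], [run_closed_loop()]
#' @export
silent_agent <- function() {
  structure(list(
    kind = "silent",
    init = function(params) NULL,
    decide = function(state, obs) {
      list(state = state, commands = empty_command_log(), next_wake = Inf)
    }), class = "race_agent")
}

#' @rdname silent_agent
#' @export
spam_agent <- function(spam_period) {
  if (!(is.numeric(spam_period) && length(spam_period) == 1 && spam_period > 0)) {
    stop("spam_period must be a positive number")
  }
  structure(list(
    kind = "spam",
    init = function(params) list(next_tick = 0),
    decide = function(state, obs) {
      t_emit <- character(0); t_at <- numeric(0)
      while (state$next_tick <= obs$time + 1e-9) {
        t_emit <- c(t_emit, sample(commands(), 1L))
        t_at <- c(t_at, obs$time)
        state$next_tick <- state$next_tick + spam_period
      }
      list(state = state, commands = command_log(t_at, t_emit),
           next_wake = state$next_tick)
    }), class = "race_agent")
}

#' @rdname silent_agent
#' @export
oracle_agent <- function(latency = 0) {
  if (!(is.numeric(latency) && length(latency) == 1 && latency >= 0)) {
    stop("latency must be a non-negative number")
  }
  structure(list(
    kind = "oracle",
    init = function(params) list(field = NA_integer_),
    decide = function(state, obs) {
      cmds <- empty_command_log()
      if (!identical(state$field, obs$field_index)) {
        state$field <- obs$field_index
        if (is_action_field(obs$field_kind)) {
          cmds <- command_log(obs$time + latency,
                              correct_command(obs$field_kind))
        }
      }
      list(state = state, commands = cmds, next_wake = Inf)
    }), class = "race_agent")
}

#' Confusion-matrix description of a simulated BCI pilot
#'
#' A classifier pilot is parametrized by a 4x4 row-stochastic confusion
#' matrix mapping intent (rows: rotate, jump, slide, rest) to emitted
#' output (columns: rotate, jump, slide, none), plus timing parameters.
#' The rest row is the sole source of false positives on no-input fields,
#' matching the asynchronous-BCI framing in which idling is itself a
#' classifier state.
#'
#' @param confusion 4x4 numeric matrix, rows summing to 1 (tolerance
#'   1e-9), all entries >= 0.  Row/column order: rotate, jump, slide,
#'   rest/none.
#' @param decision_period seconds between classifier decisions (> 0).
#' @param latency seconds between a decision and the command reaching the
#'   game (>= 0).
#' @param entry_delay strategy parameter: seconds to wait after entering a
#'   field before the first decision (>= 0).
#' @param command_subset the commands this pilot uses (2-class BCIs enter
#'   with a single command); on action fields whose correct command is not
#'   in the subset the pilot intends rest.
#' @return a `classifier_profile` object.
#' @seealso [accuracy_profile()] for the one-parameter accuracy family.
#' @export
classifier_profile <- function(confusion, decision_period = 0.5, latency = 0,
                               entry_delay = 0, command_subset = commands()) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4, 4))) stop("confusion must be a 4x4 matrix")
  if (any(confusion < 0)) stop("confusion entries must be >= 0")
  if (any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("each confusion row must sum to 1 (tolerance 1e-9)")
  }
  if (!(decision_period > 0)) stop("decision_period must be > 0")
  if (latency < 0) stop("latency must be >= 0")
  if (entry_delay < 0) stop("entry_delay must be >= 0")
  if (!all(command_subset %in% commands())) stop("invalid command_subset")
  dimnames(confusion) <- list(c(commands(), "rest"), c(commands(), "none"))
  structure(list(confusion = confusion, decision_period = decision_period,
                 latency = latency, entry_delay = entry_delay,
                 command_subset = command_subset),
            class = "classifier_profile")
}

#' One-parameter accuracy family of classifier profiles
#'
#' Builds a profile whose action-intent rows have `accuracy` on the
#' diagonal with the remaining mass split evenly between the two wrong
#' commands (no misses), and whose rest row emits nothing with
#' probability `rest_none` and otherwise a uniformly random command
#' (false positives).
#'
#' @param accuracy diagonal probability, in [1/3, 1].
#' @param rest_none probability the rest intent emits no command, in [0, 1].
#' @param ... passed to [classifier_profile()] (timing parameters).
#' @return a `classifier_profile`.
#' @export
accuracy_profile <- function(accuracy, rest_none = 0.95, ...) {
  if (accuracy < 1 / 3 || accuracy > 1) stop("accuracy must be in [1/3, 1]")
  if (rest_none < 0 || rest_none > 1) stop("rest_none must be in [0, 1]")
  off <- (1 - accuracy) / 2
  fp <- (1 - rest_none) / 3
  conf <- rbind(c(accuracy, off, off, 0),
                c(off, accuracy, off, 0),
                c(off, off, accuracy, 0),
                c(fp, fp, fp, rest_none))
  classifier_profile(conf, ...)
}

#' Confusion-matrix classifier pilot
#'
#' At each decision tick (the first `entry_delay` seconds after entering a
#' field, then every `decision_period` seconds while on it) the pilot
#' forms an intent -- rest on no-input fields, rest once the reward state
#' has been achieved on the current field, otherwise the field's correct
#' command if it is in the pilot's `command_subset`, else rest -- and
#' emits the output sampled from that intent's confusion row.  A `none`
#' outcome emits nothing; otherwise the command reaches the game
#' `latency` seconds after the tick.  Sampling uses the RNG stream seeded
#' by [run_closed_loop()], so runs are reproducible per seed.
#'
#' @param profile a [classifier_profile()].
#' @return an object of class `race_agent`.
#' @export
classifier_agent <- function(profile) {
  if (!inherits(profile, "classifier_profile")) {
    stop("profile must be a classifier_profile")
  }
  outputs <- c(commands(), "none")
  structure(list(
    kind = "classifier",
    profile = profile,
    init = function(params) list(field = NA_integer_, next_tick = Inf),
    decide = function(state, obs) {
      if (!identical(state$field, obs$field_index)) {
        state$field <- obs$field_index
        state$next_tick <- obs$time + profile$entry_delay
      }
      t_at <- numeric(0); t_emit <- character(0)
      while (state$next_tick <= obs$time + 1e-9) {
        correct <- correct_command(obs$field_kind)
        intent <- if (!is_action_field(obs$field_kind)) "rest"
                  else if (identical(obs$state, "reward")) "rest"
                  else if (correct %in% profile$command_subset) correct
                  else "rest"
        # inversion sampling: one uniform draw per tick, so runs with the
        # same seed stay coupled across different confusion matrices
        u <- stats::runif(1)
        k <- findInterval(u, cumsum(profile$confusion[intent, ]),
                          left.open = TRUE) + 1L
        out <- outputs[min(k, 4L)]
        if (out != "none") {
          t_at <- c(t_at, obs$time + profile$latency)
          t_emit <- c(t_emit, out)
        }
        state$next_tick <- state$next_tick + profile$decision_period
      }
      list(state = state, commands = command_log(t_at, t_emit),
           next_wake = state$next_tick)
    }), class = "race_agent")
}

#' @export
print.race_agent <- function(x, ...) {
  cat("Race agent:", x$kind, "\n")
  invisible(x)
}

#' @export
print.classifier_profile <- function(x, ...) {
  cat(sprintf("Classifier profile: tick %g s, latency %g s, entry delay %g s\n",
              x$decision_period, x$latency, x$entry_delay))
  cat("  commands used:", paste(x$command_subset, collapse = ", "), "\n")
  print(round(x$confusion, 4))
  invisible(x)
}

# Observation handed to agents.  Upcoming fields are limited to the preview
# window; the lookahead distance is preview_horizon x the maximum speed so
# every field is visible at least preview_horizon seconds before it can be
# reached, whatever the pilot does.
.observe <- function(e) {
  fields <- e$track$fields
  lookahead <- e$params$preview_horizon * e$params$s_reward_action
  upcoming <- integer(0)
  if (e$fi < e$nf) {
    idx <- seq.int(e$fi + 1L, e$nf)
    upcoming <- idx[fields$start_position[idx] < e$pos + lookahead]
  }
  list(time = e$t,
       field_index = e$fi,
       field_kind = fields$kind[e$fi],
       distance_to_field_end =
         fields$start_position[e$fi] + fields$length[e$fi] - e$pos,
       upcoming_fields = fields$kind[upcoming],
       upcoming_indices = upcoming,
       state = e$state)
}

#' Run an agent in closed loop over a track
#'
#' Alternates engine advancement with agent decisions: the agent is woken
#' at every field entry and at its own requested decision times, observes
#' the race state (current field, speed state, distance to field end, and
#' the upcoming fields inside the preview window), and may emit commands
#' at or after the current time.  The RNG is seeded once at the start, so
#' the run is a deterministic function of `(agent, track, params, seed)`.
#'
#' The emitted log replayed through [simulate_race()] reproduces the
#' returned result exactly.
#'
#' @param agent a `race_agent`.
#' @param track a `race_track`.
#' @param params a `game_params` object.
#' @param seed integer seed for any agent randomness.
#' @return a list with `log` (the emitted `command_log`) and `result`
#'   (the `race_result`).
#' @examples
#' p <- default_params_2016()
#' trk <- regulation_track(p, seed = 7)
#' run_closed_loop(oracle_agent(0), trk, p, seed = 1)$result$finish_time
#' @export
run_closed_loop <- function(agent, track, params, seed) {
  if (!inherits(agent, "race_agent")) stop("agent must be a race_agent")
  .with_seed(seed, {
    e <- .engine_init(track, params)
    astate <- agent$init(params)
    log_t <- numeric(0); log_c <- character(0)
    wake <- 0
    repeat {
      status <- .engine_run_until(e, wake, stop_on_enter = TRUE)
      if (status == "finished") break
      obs <- .observe(e)
      d <- agent$decide(astate, obs)
      astate <- d$state
      if (nrow(d$commands)) {
        .engine_schedule(e, d$commands$time_s, d$commands$command)
        log_t <- c(log_t, d$commands$time_s)
        log_c <- c(log_c, d$commands$command)
      }
      wake <- max(d$next_wake, e$t + 1e-9)
    }
    ord <- order(log_t)
    log <- command_log(log_t[ord], log_c[ord])
    list(log = log, result = .engine_result(e, log))
  })
}

#' Agent configurations
#'
#' A plain-list description of an agent (`kind` one of `silent`, `spam`,
#' `oracle`, `classifier` plus the kind's parameters and a seed), the form
#' used by the JSON config files and the command-line interface.
#' `build_agent()` turns a configuration into a runnable `race_agent`.
#'
#' @param kind agent kind.
#' @param seed integer seed stored with the configuration.
#' @param spam_period spam agent period (s).
#' @param oracle_latency oracle agent latency (s).
#' @param profile a [classifier_profile()] for `kind = "classifier"`.
#' @return `agent_config()` an `agent_config` list; `build_agent()` a
#'   `race_agent`.
#' @export
agent_config <- function(kind, seed = 0L, spam_period = NULL,
                         oracle_latency = NULL, profile = NULL) {
  kind <- match.arg(kind, c("silent", "spam", "oracle", "classifier"))
  if (kind == "spam" && is.null(spam_period)) stop("spam agent needs spam_period")
  if (kind == "classifier" && !inherits(profile, "classifier_profile")) {
    stop("classifier agent needs a classifier_profile")
  }
  structure(list(kind = kind, seed = as.integer(seed),
                 spam_period = spam_period,
                 oracle_latency = if (kind == "oracle") {
                   if (is.null(oracle_latency)) 0 else oracle_latency
                 },
                 profile = profile),
            class = "agent_config")
}

#' @param config an `agent_config`.
#' @rdname agent_config
#' @export
build_agent <- function(config) {
  if (!inherits(config, "agent_config")) stop("config must be an agent_config")
  switch(config$kind,
         silent = silent_agent(),
         spam = spam_agent(config$spam_period),
         oracle = oracle_agent(config$oracle_latency),
         classifier = classifier_agent(config$profile))
}
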