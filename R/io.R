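#' Read and write command-log CSV files
#'
#' The on-disk format is a CSV with header `time_s,command`, times in
#' seconds (non-decreasing) and commands spelled `rotate`, `jump`,
#' `slide`.  The reader validates the header, each token and the time
#' ordering, and reports the offending line number on failure.  Times are
#' written at full double precision, so a write/read round trip is the
#' identity.
#'
#' @param path file path.
#' @return `read_command_log()` returns a [command_log()];
#'   `write_command_log()` returns `path` invisibly.
#' @export
read_command_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]
  if (length(lines) == 0 || trimws(lines[1]) != "time_s,command") {
    stop("line 1: expected header 'time_s,command'")
  }
  n <- length(lines) - 1L
  time_s <- numeric(n); command <- character(n)
  prev <- -Inf
  for (i in seq_len(n)) {
    ln <- i + 1L
    parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop(sprintf("line %d: expected 'time,command'", ln))
    t <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(t)) stop(sprintf("line %d: invalid time '%s'", ln, parts[1]))
    if (t < 0) stop(sprintf("line %d: negative time", ln))
    cmd <- trimws(parts[2])
    if (!cmd %in% commands()) {
      stop(sprintf("line %d: unknown command '%s'", ln, cmd))
    }
    if (t < prev) stop(sprintf("line %d: time decreases (%g after %g)", ln, t, prev))
    prev <- t
    time_s[i] <- t; command[i] <- cmd
  }
  command_log(time_s, command)
}

#' @param log a [command_log()].
#' @rdname read_command_log
#' @export
write_command_log <- function(log, path) {
  log <- command_log(log$time_s, log$command)
  writeLines(c("time_s,command",
               sprintf("%s,%s", .num_full(log$time_s), log$command)), path)
  invisible(path)
}

# full-precision decimal text for doubles (round-trips exactly)
.num_full <- function(x) {
  vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
}

#' Read and write track JSON files
#'
#' A track serializes as `{fields: [{kind, length, start_position}, ...],
#' total_length}`.  The reader validates the geometry (consecutive start
#' positions, total length).
#'
#' @param track a `race_track`.
#' @param path file path.
#' @return `write_track_json()` returns `path` invisibly;
#'   `read_track_json()` returns a `race_track`.
#' @export
write_track_json <- function(track, path) {
  if (!inherits(track, "race_track")) stop("track must be a race_track")
  jsonlite::write_json(list(fields = track$fields,
                            total_length = track$total_length),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_track_json
#' @export
read_track_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- x$fields
  if (is.null(f) || !all(c("kind", "length", "start_position") %in% names(f))) {
    stop("malformed track JSON: missing fields table")
  }
  if (!all(f$kind %in% field_kinds())) stop("malformed track JSON: unknown kind")
  starts <- cumsum(c(0, f$length[-length(f$length)]))
  if (max(abs(f$start_position - starts)) > 1e-9) {
    stop("malformed track JSON: inconsistent start positions")
  }
  if (abs(sum(f$length) - x$total_length) > 1e-9) {
    stop("malformed track JSON: total_length mismatch")
  }
  trk <- structure(list(fields = data.frame(kind = f$kind, length = f$length,
                                            start_position = starts,
                                            stringsAsFactors = FALSE),
                        total_length = sum(f$length)), class = "race_track")
  trk
}

#' Read and write race-result JSON files
#'
#' Serializes a `race_result` with stable key names
#' (`finish_time_s`, `events`, `per_field`, `commands`, `total_length`)
#' and full numeric precision, so the finish time survives a round trip
#' bit-exactly.
#'
#' @param result a `race_result`.
#' @param path file path.
#' @return `write_race_json()` returns `path` invisibly;
#'   `read_race_json()` returns a `race_result`.
#' @export
write_race_json <- function(result, path) {
  if (!inherits(result, "race_result")) stop("result must be a race_result")
  jsonlite::write_json(
    list(finish_time_s = result$finish_time,
         total_length = result$total_length,
         events = result$events,
         per_field = result$per_field,
         commands = result$commands),
    path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_race_json
#' @export
read_race_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("finish_time_s", "total_length", "events", "per_field", "commands")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("malformed race JSON: missing ", paste(miss, collapse = ", "))
  cmds <- x$commands
  if (length(cmds) == 0) {
    cmds <- data.frame(time_s = numeric(0), command = character(0),
                       field_index = integer(0), correct = logical(0),
                       stringsAsFactors = FALSE)
  }
  structure(list(finish_time = x$finish_time_s, events = x$events,
                 per_field = x$per_field, commands = cmds,
                 command_log = command_log(cmds$time_s, cmds$command),
                 total_length = x$total_length),
            class = "race_result")
}

#' Read and write flat key=value parameter files
#'
#' One `key=value` pair per line, keys exactly the nine [game_params()]
#' field names; blank lines and `#` comments are ignored.  The reader
#' validates the resulting parameter set.
#'
#' @param path file path.
#' @param strict passed to [validate_params()].
#' @return `read_params_file()` a validated `game_params`;
#'   `write_params_file()` `path`, invisibly.
#' @export
read_params_file <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad)) stop("malformed parameter line: ", lines[bad[1]])
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  keys <- trimws(vapply(kv, `[`, "", 1))
  if (anyNA(vals)) stop("non-numeric parameter value for: ",
                        paste(keys[is.na(vals)], collapse = ", "))
  p <- as.list(vals)
  names(p) <- keys
  unknown <- setdiff(keys, c("s_reward_action", "s_default_noinput",
                             "s_default_action", "s_punish_noinput",
                             "s_punish_action", "t_max_punish_noinput",
                             "len_noinput", "len_action", "preview_horizon"))
  if (length(unknown)) stop("unknown parameter key: ", paste(unknown, collapse = ", "))
  if (!"s_punish_action" %in% keys) p$s_punish_action <- p$s_punish_noinput
  if (!"preview_horizon" %in% keys) p$preview_horizon <- 10
  validate_params(p, strict = strict)
}

#' @param params a `game_params` object.
#' @rdname read_params_file
#' @export
write_params_file <- function(params, path) {
  params <- validate_params(params, strict = isTRUE(attr(params, "strict")))
  keys <- names(unclass(params))
  writeLines(sprintf("%s=%s", keys,
                     .num_full(unlist(params[keys], use.names = FALSE))), path)
  invisible(path)
}

#' Read and write agent-configuration JSON files
#'
#' Format: `{kind, seed, spam_period?, oracle_latency?, profile?}` with
#' `profile` as `{confusion: [[...]], decision_period, latency,
#' entry_delay, command_subset}`.
#'
#' @param path file path.
#' @return `read_agent_config()` an [agent_config()];
#'   `write_agent_config()` `path`, invisibly.
#' @export
read_agent_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$kind)) stop("malformed agent config: missing kind")
  profile <- NULL
  if (identical(x$kind, "classifier")) {
    pr <- x$profile
    if (is.null(pr)) stop("classifier config needs a profile")
    profile <- classifier_profile(
      confusion = matrix(unlist(pr$confusion), nrow = 4, byrow = !is.matrix(pr$confusion)),
      decision_period = pr$decision_period %||% 0.5,
      latency = pr$latency %||% 0,
      entry_delay = pr$entry_delay %||% 0,
      command_subset = pr$command_subset %||% commands())
  }
  agent_config(kind = x$kind, seed = x$seed %||% 0L,
               spam_period = x$spam_period,
               oracle_latency = x$oracle_latency,
               profile = profile)
}

#' @param config an [agent_config()].
#' @rdname read_agent_config
#' @export
write_agent_config <- function(config, path) {
  if (!inherits(config, "agent_config")) stop("config must be an agent_config")
  out <- list(kind = config$kind, seed = config$seed)
  if (!is.null(config$spam_period)) out$spam_period <- config$spam_period
  if (!is.null(config$oracle_latency)) out$oracle_latency <- config$oracle_latency
  if (!is.null(config$profile)) {
    pr <- config$profile
    out$profile <- list(confusion = unname(pr$confusion),
                        decision_period = pr$decision_period,
                        latency = pr$latency, entry_delay = pr$entry_delay,
                        command_subset = pr$command_subset)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
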