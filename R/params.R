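#' Field kinds and commands of the race game
#'
#' The track is a sequence of four kinds of field.  Three ("action" fields)
#' have exactly one correct command; on the fourth, the no-input field, the
#' pilot should stay silent and any command is penalized.  There is no
#' explicit "no command" value: silence is the absence of command events.
#'
#' @return `field_kinds()` returns the four field-kind names; `commands()`
#'   the three command names; `correct_command()` the correct command for a
#'   field kind (`NA` for the no-input field).
#' @examples
#' field_kinds()
#' correct_command("jump_block")
#' @export
field_kinds <- function() {
  c("no_input", "rotate_wind", "jump_block", "slide_laser")
}

#' @rdname field_kinds
#' @export
commands <- function() {
  c("rotate", "jump", "slide")
}

#' @param kind a field kind, one of `field_kinds()`.
#' @rdname field_kinds
#' @export
correct_command <- function(kind) {
  map <- c(no_input = NA_character_, rotate_wind = "rotate",
           jump_block = "jump", slide_laser = "slide")
  if (!all(kind %in% names(map))) {
    stop("unknown field kind: ", paste(setdiff(kind, names(map)), collapse = ", "))
  }
  unname(map[kind])
}

#' @rdname field_kinds
#' @export
is_action_field <- function(kind) {
  kind %in% c("rotate_wind", "jump_block", "slide_laser")
}

# one-letter codes used by the track text format
.kind_codes <- c(no_input = "N", rotate_wind = "R", jump_block = "J",
                 slide_laser = "S")

#' Game balancing parameters
#'
#' The race dynamics are governed by six balancing constants (four speeds,
#' a shared punish speed, and the no-input penalty duration) plus the field
#' lengths and the preview horizon.  Speeds are in track-units per second;
#' the unit system is fixed by taking the default no-input speed as
#' 1 unit/s, so all other speeds read as fractions of it.
#'
#' Every valid parameter set obeys the speed ordering
#' `s_reward_action > s_default_noinput > s_default_action > s_punish_noinput`,
#' and in the regulation game the two punish speeds are equal.  Set
#' `strict = FALSE` only for design exploration of unequal punish speeds.
#'
#' @param s_reward_action speed on an action field after the correct command.
#' @param s_default_noinput default speed on a no-input field (defines the unit).
#' @param s_default_action speed on an action field with no command sent.
#' @param s_punish_noinput speed on a no-input field after any command.
#' @param s_punish_action speed on an action field after a wrong command
#'   (defaults to `s_punish_noinput`).
#' @param t_max_punish_noinput duration of the no-input penalty, seconds.
#' @param len_noinput,len_action field lengths, track-units.
#' @param preview_horizon how far ahead (seconds) pilots see upcoming fields.
#' @param strict enforce `s_punish_noinput == s_punish_action`.
#' @return a validated `game_params` object.
#' @seealso [default_params_2016()], [validate_params()]
#' @export
game_params <- function(s_reward_action, s_default_noinput, s_default_action,
                        s_punish_noinput, s_punish_action = s_punish_noinput,
                        t_max_punish_noinput, len_noinput, len_action,
                        preview_horizon = 10, strict = TRUE) {
  p <- structure(
    list(s_reward_action = as.numeric(s_reward_action),
         s_default_noinput = as.numeric(s_default_noinput),
         s_default_action = as.numeric(s_default_action),
         s_punish_noinput = as.numeric(s_punish_noinput),
         s_punish_action = as.numeric(s_punish_action),
         t_max_punish_noinput = as.numeric(t_max_punish_noinput),
         len_noinput = as.numeric(len_noinput),
         len_action = as.numeric(len_action),
         preview_horizon = as.numeric(preview_horizon)),
    class = "game_params", strict = strict)
  validate_params(p, strict = strict)
}

#' The regulation 2016 parameter set
#'
#' Speeds 3 / 1 / 0.5 / 0.3 (reward, no-input default, action default,
#' punish) and a 4 s no-input penalty.  Field lengths are calibrated from
#' the published no-command crossing times of 6 s (no-input) and 11 s
#' (action field): with the no-input default speed defining 1 unit/s,
#' `len_noinput = 6` and `len_action = 11 * 0.5 = 5.5` units.  The preview
#' horizon is 10 s.
#'
#' @return a `game_params` object.
#' @examples
#' p <- default_params_2016()
#' p$len_action / p$s_default_action  # silent crossing time of an action field
#' @export
default_params_2016 <- function() {
  game_params(s_reward_action = 3, s_default_noinput = 1,
              s_default_action = 0.5, s_punish_noinput = 0.3,
              s_punish_action = 0.3, t_max_punish_noinput = 4,
              len_noinput = 6, len_action = 5.5, preview_horizon = 10)
}

#' Validate a parameter set
#'
#' Checks positivity of all speeds and lengths, non-negativity of the
#' penalty duration, the speed-ordering chain, and (in strict mode) the
#' equality of the two punish speeds.
#'
#' @param p a `game_params` object or a bare named list with the same fields.
#' @param strict enforce equality of the punish speeds.
#' @return `p`, invisibly classed as `game_params`, if valid; otherwise an
#'   error naming the violated constraint.
#' @export
validate_params <- function(p, strict = TRUE) {
  need <- c("s_reward_action", "s_default_noinput", "s_default_action",
            "s_punish_noinput", "s_punish_action", "t_max_punish_noinput",
            "len_noinput", "len_action", "preview_horizon")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  num <- vapply(p[need], function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("non-numeric or non-scalar parameter: ",
                      paste(need[!num], collapse = ", "))
  pos <- c("s_reward_action", "s_default_noinput", "s_default_action",
           "s_punish_noinput", "s_punish_action", "len_noinput", "len_action",
           "preview_horizon")
  bad <- pos[vapply(p[pos], function(x) x <= 0, logical(1))]
  if (length(bad)) stop("parameter must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (p$t_max_punish_noinput < 0) stop("t_max_punish_noinput must be >= 0")
  if (!(p$s_reward_action > p$s_default_noinput)) {
    stop("speed ordering violated: s_reward_action > s_default_noinput required")
  }
  if (!(p$s_default_noinput > p$s_default_action)) {
    stop("speed ordering violated: s_default_noinput > s_default_action required")
  }
  if (!(p$s_default_action > p$s_punish_noinput)) {
    stop("speed ordering violated: s_default_action > s_punish_noinput required")
  }
  if (!(p$s_default_action > p$s_punish_action)) {
    stop("speed ordering violated: s_default_action > s_punish_action required")
  }
  if (strict && p$s_punish_noinput != p$s_punish_action) {
    stop("s_punish_noinput must equal s_punish_action in the regulation game ",
         "(use strict = FALSE to explore unequal punish speeds)")
  }
  structure(p, class = "game_params", strict = strict)
}

#' @export
print.game_params <- function(x, ...) {
  cat("Game parameters (track-units/s, s, units):\n")
  for (k in names(x)) cat(sprintf("  %-22s %g\n", k, x[[k]]))
  invisible(x)
}

#' Length of a field of the given kind under a parameter set
#' @param kind field kind(s).
#' @param params a `game_params` object.
#' @return numeric length(s) in track-units.
#' @keywords internal
field_length <- function(kind, params) {
  ifelse(kind == "no_input", params$len_noinput, params$len_action)
}
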