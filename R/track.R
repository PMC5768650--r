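#' Construct a track from a sequence of field kinds
#'
#' A track is an ordered sequence of typed fields.  Lengths come from the
#' governing parameter set and cumulative start positions are derived, so a
#' track is fully determined by its kind sequence plus the parameters.
#'
#' @param kinds character vector of field kinds (see [field_kinds()]).
#' @param params a `game_params` object.
#' @return a `race_track`: a list with `fields` (a data.frame with columns
#'   `kind`, `length`, `start_position`) and `total_length`.
#' @export
race_track <- function(kinds, params) {
  if (length(kinds) < 1) stop("a track needs at least one field")
  if (!all(kinds %in% field_kinds())) {
    stop("unknown field kind: ",
         paste(unique(setdiff(kinds, field_kinds())), collapse = ", "))
  }
  len <- field_length(kinds, params)
  fields <- data.frame(kind = kinds, length = len,
                       start_position = cumsum(c(0, len[-length(len)])),
                       stringsAsFactors = FALSE)
  structure(list(fields = fields, total_length = sum(len)),
            class = "race_track")
}

#' Seeded random track with a given field-kind composition
#'
#' The regulation race layout has 16 fields, four of each kind, shuffled
#' into an order unknown to competitors; all competitors race the same
#' order.  `random_track()` generalizes the composition (e.g. to study
#' unequal no-input vs action prevalence); `regulation_track()` is the
#' named 4/4/4/4 preset.
#'
#' @param params a `game_params` object.
#' @param counts named integer vector: number of fields per kind, names
#'   from [field_kinds()].
#' @param seed non-negative integer seed for the shuffle; the same seed
#'   always yields the same track.
#' @return a `race_track`.
#' @examples
#' trk <- regulation_track(default_params_2016(), seed = 1)
#' table(trk$fields$kind)
#' @export
random_track <- function(params, counts, seed) {
  if (!all(names(counts) %in% field_kinds()) || is.null(names(counts))) {
    stop("counts must be named by field kinds")
  }
  if (any(counts < 0) || sum(counts) < 1) stop("counts must be non-negative, total >= 1")
  pool <- rep(names(counts), times = counts)
  kinds <- .with_seed(seed, sample(pool, length(pool), replace = FALSE))
  race_track(kinds, params)
}

#' @rdname random_track
#' @export
regulation_track <- function(params, seed) {
  random_track(params,
               counts = c(no_input = 4L, rotate_wind = 4L, jump_block = 4L,
                          slide_laser = 4L),
               seed = seed)
}

#' Parse and serialize the one-letter track text format
#'
#' One character per field: `N` (no-input), `R` (spinning winds / rotate),
#' `J` (stumbling blocks / jump), `S` (sticky lasers / slide).
#' Case-insensitive; whitespace is ignored.
#'
#' @param spec a non-empty track string, e.g. `"NRJS"`.
#' @param params a `game_params` object.
#' @return `track_from_string()` returns a `race_track`;
#'   `track_to_string()` its inverse.
#' @examples
#' track_to_string(track_from_string("nrjs", default_params_2016()))
#' @export
track_from_string <- function(spec, params) {
  if (!is.character(spec) || length(spec) != 1 || is.na(spec)) {
    stop("track spec must be a single string")
  }
  chars <- strsplit(spec, "")[[1]]
  chars <- chars[!grepl("\\s", chars)]
  if (length(chars) == 0) stop("track spec is empty")
  up <- toupper(chars)
  known <- match(up, .kind_codes)
  if (anyNA(known)) {
    pos <- which(is.na(known))[1]
    stop(sprintf("invalid track symbol '%s' at position %d (expected N/R/J/S)",
                 chars[pos], pos))
  }
  race_track(names(.kind_codes)[known], params)
}

#' @param track a `race_track`.
#' @rdname track_from_string
#' @export
track_to_string <- function(track) {
  paste(unname(.kind_codes[track$fields$kind]), collapse = "")
}

#' @export
print.race_track <- function(x, ...) {
  cat(sprintf("Race track: %d fields, total length %g units\n",
              nrow(x$fields), x$total_length))
  cat("  ", track_to_string(x), "\n", sep = "")
  tb <- table(factor(x$fields$kind, levels = field_kinds()))
  cat("  counts:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Number of fields in a track
#' @param track a `race_track`.
#' @return integer field count.
#' @export
n_fields <- function(track) nrow(track$fields)

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards: track generation never perturbs other streams.
.with_seed <- function(seed, expr) {
  if (length(seed) != 1 || is.na(seed) || seed < 0 || seed != trunc(seed)) {
    stop("seed must be a single non-negative integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically spawn independent sub-seeds from a master seed.
.spawn_seeds <- function(master_seed, n) {
  .with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
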