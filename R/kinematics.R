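#' Movement-categorisation configuration
#'
#' Parameters controlling how coordinate series are turned into categorical
#' movement series.
#'
#' @param radius no-movement radius in pixels: a frame-to-frame Euclidean
#'   displacement below this counts as no movement (default 0.1 px). The
#'   categorisation is sensitive to this choice; see the package vignette for
#'   a radius-sweep recipe.
#' @param mirror_assistant whether the assistant's series is mirrored
#'   (left/right swapped) before recurrence analysis, so that geometrically
#'   complementary approach movements count as matches (default `TRUE`).
#' @param fps frames per second (default 30).
#' @return An object of class `motion_config`.
#' @export
motion_config <- function(radius = 0.1, mirror_assistant = TRUE, fps = 30) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("`radius` must be a single positive number of pixels")
  }
  if (fps <= 0) stop("`fps` must be positive")
  structure(list(radius = radius, mirror_assistant = isTRUE(mirror_assistant),
                 fps = fps),
            class = "motion_config")
}

movement_levels <- c("LEFT", "RIGHT", "NONE")

#' Construct a categorical movement series
#'
#' One symbol per frame transition: `LEFT`, `RIGHT` or `NONE`.
#'
#' @param symbols character or factor vector over `LEFT`/`RIGHT`/`NONE`.
#' @param fps frames per second.
#' @param person_id label of the person the series describes.
#' @return An object of class `categorical_series`.
#' @export
categorical_series <- function(symbols, fps = 30, person_id = "person") {
  f <- factor(as.character(symbols), levels = movement_levels)
  if (anyNA(f)) {
    stop("symbols must all be one of ", paste(movement_levels, collapse = ", "))
  }
  if (length(f) < 1L) stop("empty symbol series")
  if (fps <= 0) stop("`fps` must be positive")
  structure(list(symbols = f, fps = fps, person_id = person_id),
            class = "categorical_series")
}

#' @export
print.categorical_series <- function(x, ...) {
  tab <- table(x$symbols)
  cat("<categorical_series> ", x$person_id, ": ", length(x$symbols),
      " symbols @ ", x$fps, " fps (",
      paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
length.categorical_series <- function(x) length(x$symbols)

#' Inter-person nose-to-nose spatial distance
#'
#' Per-frame Euclidean distance in pixels between the participant's and the
#' assistant's nose coordinates — the head-based measure of interpersonal
#' spatial distance (approach/avoidance).
#'
#' @param dyad a [dyad_track()] whose tracks both contain a `nose` bodypart.
#' @param bodypart body part used for the distance (default `"nose"`).
#' @return An object of class `distance_series` with fields `values` (px)
#'   and `fps`.
#' @export
nose_distance <- function(dyad, bodypart = "nose") {
  stopifnot(inherits(dyad, "dyad_track"))
  for (tr in list(dyad$participant, dyad$assistant)) {
    if (!bodypart %in% tr$bodyparts) {
      stop("track '", tr$person_id, "' has no bodypart '", bodypart, "'")
    }
  }
  dx <- dyad$participant$x[, bodypart] - dyad$assistant$x[, bodypart]
  dy <- dyad$participant$y[, bodypart] - dyad$assistant$y[, bodypart]
  structure(list(values = sqrt(dx^2 + dy^2), fps = dyad$participant$fps,
                 dyad_id = dyad$dyad_id),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat("<distance_series> ", length(x$values), " frames @ ", x$fps,
      " fps, mean ", round(mean(x$values), 2), " px\n", sep = "")
  invisible(x)
}

#' Categorise movement direction from a coordinate series
#'
#' Translates one body part's trajectory into a per-transition symbol series:
#' `NONE` when the full 2-D Euclidean displacement between consecutive frames
#' is below `cfg$radius`; otherwise `LEFT` when the horizontal displacement
#' is negative and `RIGHT` when positive. A supra-threshold displacement that
#' is exactly vertical (zero horizontal component) is assigned `NONE`;
#' direction is defined horizontally because approach movements toward the
#' shared table are horizontal in the camera frame.
#'
#' @param track a [pose_track()] with at least 2 frames.
#' @param bodypart which body part to categorise (default `"nose"`, i.e.
#'   head movement).
#' @param cfg a [motion_config()].
#' @return A [categorical_series()] of length `frames - 1`.
#' @export
categorize_movement <- function(track, bodypart = "nose", cfg = motion_config()) {
  stopifnot(inherits(track, "pose_track"))
  if (!bodypart %in% track$bodyparts) {
    stop("track has no bodypart '", bodypart, "'")
  }
  if (track$frames < 2L) stop("need at least 2 frames to categorise movement")
  dx <- diff(track$x[, bodypart])
  dy <- diff(track$y[, bodypart])
  disp <- sqrt(dx^2 + dy^2)
  sym <- rep("NONE", length(dx))
  moving <- disp >= cfg$radius
  sym[moving & dx < 0] <- "LEFT"
  sym[moving & dx > 0] <- "RIGHT"
  categorical_series(sym, fps = track$fps, person_id = track$person_id)
}

#' Mirror a categorical movement series
#'
#' Swaps `LEFT` and `RIGHT` (leaving `NONE` untouched). Applied to the
#' assistant's series so that complementary approach movements — both people
#' leaning toward the table between them — become matches. The operation is
#' an involution: mirroring twice restores the input.
#'
#' @param series a [categorical_series()].
#' @return The mirrored [categorical_series()].
#' @export
mirror_series <- function(series) {
  stopifnot(inherits(series, "categorical_series"))
  s <- as.character(series$symbols)
  out <- s
  out[s == "LEFT"] <- "RIGHT"
  out[s == "RIGHT"] <- "LEFT"
  categorical_series(out, fps = series$fps, person_id = series$person_id)
}

#' Write / read a symbol series as single-column text
#'
#' Symbols are encoded `L`/`R`/`N` under a `symbol` header.
#'
#' @param series a [categorical_series()].
#' @param path file path.
#' @param fps,person_id metadata attached on reading.
#' @return `write_symbol_series()` returns `path` invisibly;
#'   `read_symbol_series()` returns a [categorical_series()].
#' @export
write_symbol_series <- function(series, path) {
  stopifnot(inherits(series, "categorical_series"))
  code <- c(LEFT = "L", RIGHT = "R", NONE = "N")
  writeLines(c("symbol", code[as.character(series$symbols)]), path)
  invisible(path)
}

#' @rdname write_symbol_series
#' @export
read_symbol_series <- function(path, fps = 30, person_id = "person") {
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1] != "symbol") {
    stop("expected a single-column file with a 'symbol' header")
  }
  decode <- c(L = "LEFT", R = "RIGHT", N = "NONE")
  sym <- decode[lines[-1L]]
  if (anyNA(sym)) stop("unknown symbol code at line ", which(is.na(sym))[1] + 1L)
  categorical_series(sym, fps = fps, person_id = person_id)
}
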