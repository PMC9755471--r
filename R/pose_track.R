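#' Construct a pose track
#'
#' A `pose_track` holds the per-frame pose-estimation output for one person:
#' pixel coordinates and tracking likelihood for a set of named body parts,
#' sampled at a fixed frame rate. Coordinates follow the image convention
#' (origin top-left, x increasing rightward, y increasing downward).
#'
#' @param x,y numeric matrices (frames x bodyparts) of pixel coordinates.
#' @param likelihood numeric matrix of per-frame per-bodypart tracking
#'   confidence in `[0, 1]`; defaults to all ones.
#' @param bodyparts character vector of body-part names, one per column.
#'   Typical exports track six: hand_left, hand_right, nose, ear, neck, trunk.
#' @param fps frames per second (default 30).
#' @param person_id label for the tracked person.
#' @param frame_size optional `c(width, height)` in pixels; when declared,
#'   coordinates must lie within the frame.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(x, y, likelihood = NULL, bodyparts = colnames(x),
                       fps = 30, person_id = "person", frame_size = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (is.null(bodyparts)) {
    stop("`bodyparts` must be supplied (or `x` must have column names)")
  }
  bodyparts <- as.character(bodyparts)
  if (length(bodyparts) < 1L) stop("`bodyparts` must name at least one body part")
  if (anyDuplicated(bodyparts)) stop("duplicated body-part names")
  if (!identical(dim(x), dim(y))) stop("`x` and `y` must have identical dimensions")
  if (ncol(x) != length(bodyparts)) {
    stop("number of coordinate columns (", ncol(x), ") does not match ",
         length(bodyparts), " body parts")
  }
  if (is.null(likelihood)) {
    likelihood <- matrix(1, nrow(x), ncol(x))
  }
  likelihood <- as.matrix(likelihood)
  if (!identical(dim(likelihood), dim(x))) {
    stop("`likelihood` must have the same dimensions as the coordinates")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) stop("`fps` must be a single positive number")
  storage.mode(x) <- "double"
  storage.mode(y) <- "double"
  storage.mode(likelihood) <- "double"
  if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE)) {
    stop("likelihood values must lie in [0, 1]")
  }
  if (!is.null(frame_size)) {
    if (length(frame_size) != 2L || any(frame_size <= 0)) {
      stop("`frame_size` must be c(width, height), both positive")
    }
    if (any(x < 0 | x > frame_size[1], na.rm = TRUE) ||
        any(y < 0 | y > frame_size[2], na.rm = TRUE)) {
      stop("coordinates fall outside the declared frame size")
    }
  }
  colnames(x) <- colnames(y) <- colnames(likelihood) <- bodyparts
  structure(
    list(person_id = person_id, bodyparts = bodyparts,
         frames = nrow(x), fps = fps,
         x = x, y = y, likelihood = likelihood,
         frame_size = frame_size),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat("<pose_track> ", x$person_id, ": ", x$frames, " frames @ ", x$fps,
      " fps, bodyparts: ", paste(x$bodyparts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pair two pose tracks into a dyad
#'
#' @param participant,assistant `pose_track` objects with equal frame count
#'   and frame rate.
#' @param dyad_id label for the dyad.
#' @param group group label, `"high"` or `"low"` (identification-with-all-
#'   humanity grouping of the participant).
#' @return An object of class `dyad_track`.
#' @export
dyad_track <- function(participant, assistant, dyad_id = "dyad",
                       group = c("high", "low")) {
  group <- match.arg(group)
  if (!inherits(participant, "pose_track") || !inherits(assistant, "pose_track")) {
    stop("`participant` and `assistant` must be pose_track objects")
  }
  if (participant$frames != assistant$frames) {
    stop("participant and assistant tracks differ in frame count (",
         participant$frames, " vs ", assistant$frames, ")")
  }
  if (participant$fps != assistant$fps) stop("participant and assistant tracks differ in fps")
  structure(
    list(participant = participant, assistant = assistant,
         dyad_id = dyad_id, group = group),
    class = "dyad_track"
  )
}

#' @export
print.dyad_track <- function(x, ...) {
  cat("<dyad_track> ", x$dyad_id, " (group: ", x$group, "), ",
      x$participant$frames, " frames @ ", x$participant$fps, " fps\n", sep = "")
  invisible(x)
}

#' Read a pose-estimation export table
#'
#' Parses the DeepLabCut CSV dialect: three header rows (`scorer`,
#' `bodyparts`, `coords`), a frame-index column, then an `x`, `y`,
#' `likelihood` column triplet per body part.
#'
#' @param path path to the delimited table.
#' @param person_id label to attach to the returned track.
#' @param fps frames per second of the recording (default 30; the format
#'   itself does not carry a frame rate).
#' @param frame_size optional `c(width, height)` used for validation.
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, person_id = "person", fps = 30,
                            frame_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 3L)
  if (length(lines) < 3L) stop("format error: expected 3 header rows (scorer / bodyparts / coords)")
  hdr <- lapply(lines, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- vapply(hdr, function(h) tolower(h[1]), character(1))
  if (!identical(labels, c("scorer", "bodyparts", "coords"))) {
    stop("format error: header rows must be scorer / bodyparts / coords, got: ",
         paste(labels, collapse = " / "))
  }
  bp_row <- hdr[[2]][-1]
  coord_row <- hdr[[3]][-1]
  if (length(coord_row) != length(bp_row)) {
    stop("format error: bodyparts and coords rows differ in length")
  }
  n_col <- length(coord_row)
  if (n_col == 0L || n_col %% 3L != 0L) {
    stop("format error: expected (x, y, likelihood) triplets, found ",
         n_col, " data columns")
  }
  for (j in seq(1L, n_col, by = 3L)) {
    trip <- tolower(coord_row[j + 0:2])
    if (!identical(trip, c("x", "y", "likelihood"))) {
      stop("format error in column ", j + 1L, " (bodypart '", bp_row[j],
           "'): expected x, y, likelihood; found ",
           paste(coord_row[j + 0:2], collapse = ", "))
    }
    if (length(unique(bp_row[j + 0:2])) != 1L) {
      stop("format error in column ", j + 1L,
           ": bodypart names within a triplet disagree (",
           paste(bp_row[j + 0:2], collapse = ", "), ")")
    }
  }
  bodyparts <- bp_row[seq(1L, n_col, by = 3L)]
  raw <- utils::read.table(path, sep = ",", skip = 3L, header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(raw) != n_col + 1L) {
    stop("format error: data rows have ", ncol(raw) - 1L,
         " value columns, header declares ", n_col)
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw))
  bad <- which(is.na(vals) & raw[-1L] != "", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("parse error: non-numeric value at data row ", bad[1, 1],
         ", column ", bad[1, 2] + 1L)
  }
  if (anyNA(vals)) {
    stop("parse error: empty cell at data row ",
         which(is.na(vals), arr.ind = TRUE)[1, 1])
  }
  idx <- seq(0L, n_col - 1L)
  pose_track(
    x = vals[, idx %% 3L == 0L, drop = FALSE],
    y = vals[, idx %% 3L == 1L, drop = FALSE],
    likelihood = vals[, idx %% 3L == 2L, drop = FALSE],
    bodyparts = bodyparts, fps = fps, person_id = person_id,
    frame_size = frame_size
  )
}

#' Write a pose track as a pose-estimation export table
#'
#' Emits the same three-header-row CSV dialect read by [read_pose_table()],
#' with 6-decimal precision, so that write-then-read round-trips.
#'
#' @param track a [pose_track()].
#' @param path output file path.
#' @param scorer value for the scorer header row.
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path, scorer = "dyadcrqa", digits = 6L) {
  stopifnot(inherits(track, "pose_track"))
  if (length(track$bodyparts) < 1L) stop("track has no body parts")
  nb <- length(track$bodyparts)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path, "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    paste(c("scorer", rep(scorer, 3L * nb)), collapse = ","),
    paste(c("bodyparts", rep(track$bodyparts, each = 3L)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), nb)), collapse = ",")
  ), con)
  m <- matrix(NA_real_, track$frames, 3L * nb)
  m[, seq(1L, 3L * nb, 3L)] <- track$x
  m[, seq(2L, 3L * nb, 3L)] <- track$y
  m[, seq(3L, 3L * nb, 3L)] <- track$likelihood
  body <- cbind(seq_len(track$frames) - 1L,
                formatC(m, digits = digits, format = "f"))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Median-filter the coordinates of a pose track
#'
#' Applies a centred running median of odd width to every x and y channel
#' independently, suppressing single-frame tracking outliers. At the series
#' boundaries the window shrinks symmetrically to the available
#' neighbourhood, so the first and last frames pass through unchanged.
#' Likelihood values are carried through untouched.
#'
#' @param track a [pose_track()].
#' @param window odd window width in frames (default 7).
#' @return A filtered [pose_track()].
#' @export
median_filter_track <- function(track, window = 7L) {
  stopifnot(inherits(track, "pose_track"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L) {
    stop("`window` must be a positive integer")
  }
  if (window %% 2L == 0L) stop("`window` must be odd, got ", window)
  if (window > track$frames) {
    stop("`window` (", window, ") exceeds the number of frames (", track$frames, ")")
  }
  out <- track
  out$x <- apply(track$x, 2L, running_median, window = window)
  out$y <- apply(track$y, 2L, running_median, window = window)
  dim(out$x) <- dim(out$y) <- dim(track$x)
  colnames(out$x) <- colnames(out$y) <- track$bodyparts
  out
}

# Centred running median; the window shrinks symmetrically at both edges.
running_median <- function(v, window) {
  n <- length(v)
  if (window == 1L || n == 1L) return(v)
  out <- stats::runmed(v, k = window, endrule = "keep")
  h <- (window - 1L) %/% 2L
  for (i in seq_len(min(h, n))) {
    m <- i - 1L
    out[i] <- stats::median(v[(i - m):min(n, i + m)])
    j <- n - i + 1L
    out[j] <- stats::median(v[max(1L, j - m):(j + m)])
  }
  out
}

#' Interpolate low-likelihood samples
#'
#' Optional cleaning step, off by default in the pipeline: coordinates whose
#' tracking likelihood falls below `min_likelihood` are replaced by linear
#' interpolation from the neighbouring confident frames (constant
#' extrapolation at the ends).
#'
#' @param track a [pose_track()].
#' @param min_likelihood threshold in `[0, 1]`.
#' @return A [pose_track()] with low-confidence coordinates interpolated.
#' @export
drop_low_likelihood <- function(track, min_likelihood) {
  stopifnot(inherits(track, "pose_track"))
  if (min_likelihood < 0 || min_likelihood > 1) stop("`min_likelihood` must be in [0, 1]")
  out <- track
  for (b in seq_along(track$bodyparts)) {
    low <- track$likelihood[, b] < min_likelihood
    if (!any(low)) next
    if (all(low)) {
      stop("all frames of bodypart '", track$bodyparts[b],
           "' fall below the likelihood threshold")
    }
    keep <- which(!low)
    out$x[low, b] <- stats::approx(keep, track$x[keep, b], xout = which(low),
                                   rule = 2)$y
    out$y[low, b] <- stats::approx(keep, track$y[keep, b], xout = which(low),
                                   rule = 2)$y
  }
  out
}
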