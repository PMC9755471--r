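#' Configuration of the coupled-dyad simulator
#'
#' Describes one simulated dyad: a leader (the participant) whose head makes
#' discrete left/right/no-movement steps, and a follower (the assistant) who
#' copies the leader's movements — mirrored, as the face-to-face camera
#' geometry dictates — `lead_lag` frames later with probability `fidelity`,
#' and otherwise moves independently. Defaults emulate the study conditions
#' the analysis was designed for: 5-minute interactions at 30 fps (9000
#' frames), head steps around 1 px/frame, and a leader lag of a few hundred
#' milliseconds.
#'
#' @param n_frames number of video frames (default 9000 = 5 min at 30 fps).
#' @param fps frames per second (default 30).
#' @param lead_lag follower delay in frames; positive means the participant
#'   leads (default 11 frames, about 370 ms).
#' @param fidelity probability in `[0, 1]` that the follower copies the
#'   leader at each transition (default 0.9).
#' @param symbol_rates probabilities of `LEFT`, `RIGHT`, `NONE` for fresh
#'   leader symbols; must sum to 1.
#' @param persistence probability in `[0, 1)` of carrying the previous
#'   symbol forward instead of drawing fresh (default 0.3, mild
#'   autocorrelation as in real head movement). The stationary marginal
#'   distribution remains `symbol_rates`.
#' @param separation mean nose-to-nose distance in pixels (default 200).
#' @param approach_amplitude amplitude in px of a slow sinusoidal
#'   lean-toward-the-table excursion shared (mirrored) by both people
#'   (default 20).
#' @param approach_freq excursion frequency in Hz (default 1/30).
#' @param step_px size in px of one categorical movement step (default 1,
#'   matching head displacements of about a pixel per frame).
#' @param noise_sd standard deviation in px of Gaussian measurement jitter
#'   added to every emitted coordinate (default 0.5).
#' @param reversion mean-reversion rate per frame of the bounded head
#'   random walk (default 0.005).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_frames = 9000, fps = 30, lead_lag = 11,
                       fidelity = 0.9,
                       symbol_rates = c(LEFT = 0.35, RIGHT = 0.35, NONE = 0.30),
                       persistence = 0.3, separation = 200,
                       approach_amplitude = 20, approach_freq = 1 / 30,
                       step_px = 1, noise_sd = 0.5, reversion = 0.005,
                       seed = NULL) {
  n_frames <- as.integer(n_frames)
  lead_lag <- as.integer(lead_lag)
  if (length(symbol_rates) != 3L || any(symbol_rates < 0) ||
      abs(sum(symbol_rates) - 1) > 1e-8) {
    stop("`symbol_rates` must be 3 non-negative probabilities summing to 1")
  }
  if (is.na(fidelity) || fidelity < 0 || fidelity > 1) stop("`fidelity` must be in [0, 1]")
  if (persistence < 0 || persistence >= 1) stop("`persistence` must be in [0, 1)")
  if (n_frames <= 2L * abs(lead_lag)) {
    stop("`n_frames` must exceed twice the absolute lead lag")
  }
  if (n_frames < 3L) stop("`n_frames` must be at least 3")
  if (fps <= 0) stop("`fps` must be positive")
  if (noise_sd < 0 || approach_amplitude < 0 || step_px < 0 || separation < 0) {
    stop("`noise_sd`, `approach_amplitude`, `step_px` and `separation` must be non-negative")
  }
  if (reversion < 0 || reversion >= 1) stop("`reversion` must be in [0, 1)")
  structure(list(n_frames = n_frames, fps = fps, lead_lag = lead_lag,
                 fidelity = fidelity,
                 symbol_rates = stats::setNames(as.numeric(symbol_rates),
                                                c("LEFT", "RIGHT", "NONE")),
                 persistence = persistence, separation = separation,
                 approach_amplitude = approach_amplitude,
                 approach_freq = approach_freq, step_px = step_px,
                 noise_sd = noise_sd, reversion = reversion, seed = seed),
            class = "sim_config")
}

# First-order persistence chain over symbol codes 1:3 (LEFT, RIGHT, NONE):
# with probability `persistence` the previous symbol is carried forward,
# otherwise a fresh draw from `rates`. Vectorised via segment indexing.
symbol_chain <- function(n, rates, persistence) {
  fresh <- sample.int(3L, n, replace = TRUE, prob = rates)
  if (persistence <= 0) return(fresh)
  keep <- stats::runif(n) < persistence
  keep[1L] <- FALSE
  fresh[!keep][cumsum(!keep)]
}

#' Simulate a coupled dyad at the categorical level
#'
#' Draws the participant's symbol series from the persistence chain defined
#' by `cfg`, then builds the assistant's series by copying the participant's
#' symbol `lead_lag` transitions earlier with probability `fidelity` and
#' drawing from an independent chain otherwise. Series are emitted in the
#' aligned (post-mirroring) frame, i.e. a copy is a direct symbol match.
#'
#' @param cfg a [sim_config()].
#' @return A list with `participant` and `assistant`
#'   ([categorical_series()] of length `n_frames - 1`) and `truth`
#'   (lead lag, fidelity, latent leader symbols, copy indicator).
#' @export
simulate_dyad_categorical <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_frames - 1L
    d <- cfg$lead_lag
    leader <- symbol_chain(m, cfg$symbol_rates, cfg$persistence)
    own <- symbol_chain(m, cfg$symbol_rates, cfg$persistence)
    copy <- stats::runif(m) < cfg$fidelity
    src <- seq_len(m) - d
    sel <- copy & src >= 1L & src <= m
    a <- own
    a[sel] <- leader[src[sel]]
    list(
      participant = categorical_series(movement_levels[leader], fps = cfg$fps,
                                       person_id = "participant"),
      assistant = categorical_series(movement_levels[a], fps = cfg$fps,
                                     person_id = "assistant"),
      truth = list(lead_lag = d, fidelity = cfg$fidelity,
                   leader_symbols = movement_levels[leader], copied = sel)
    )
  })
}

# Fixed body-part offsets (px) relative to the nose; the assistant's are
# mirrored in x. Order matches the six-part tracking layout.
bodypart_offsets <- function() {
  data.frame(
    bodypart = c("hand_left", "hand_right", "nose", "ear", "neck", "trunk"),
    dx = c(-60, 60, 0, -15, 0, 0),
    dy = c(150, 150, 0, 10, 60, 160)
  )
}

#' Simulate a coupled dyad at the coordinate level
#'
#' Generates full six-bodypart pose tracks for both members of a dyad in a
#' 1280 x 720 px frame. The participant's nose follows a bounded
#' (mean-reverting) random walk driven by categorical left/right steps plus
#' a slow sinusoidal approach excursion; the assistant reproduces the
#' participant's realised horizontal displacements sign-flipped (the camera
#' sees complementary approach movements) `lead_lag` frames later with
#' probability `fidelity`, and steps independently otherwise. Non-nose body
#' parts ride on the nose at fixed offsets. All emitted coordinates receive
#' Gaussian jitter of sd `noise_sd`; likelihood is 1 everywhere.
#'
#' @param cfg a [sim_config()].
#' @param dyad_id,group labels for the returned [dyad_track()].
#' @param write_dir optional directory; when given, both tracks are written
#'   as pose tables via [write_pose_table()] together with a plain-text
#'   ground-truth sidecar, and the file paths are returned in `files`.
#' @return A list with `dyad` (a [dyad_track()]), `truth` (ground truth:
#'   lead lag, fidelity, separation, leader symbols, latent nose
#'   coordinates) and `files` (or `NULL`).
#' @export
simulate_dyad_coordinates <- function(cfg = sim_config(), dyad_id = "dyad",
                                      group = c("high", "low"),
                                      write_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  group <- match.arg(group)
  width <- 1280; height <- 720
  with_seed(cfg$seed, {
    n <- cfg$n_frames
    m <- n - 1L
    d <- cfg$lead_lag
    kappa <- cfg$reversion
    cp <- width / 2 - cfg$separation / 2
    ca <- cp + cfg$separation
    cy <- height / 2

    leader <- symbol_chain(m, cfg$symbol_rates, cfg$persistence)
    dir_p <- (leader == 2L) - (leader == 1L)   # RIGHT = +x (toward the table)
    phase <- stats::runif(1, 0, 2 * pi)
    exc <- cfg$approach_amplitude *
      sin(2 * pi * cfg$approach_freq * (seq_len(n) - 1L) / cfg$fps + phase)
    ext_p <- cfg$step_px * dir_p + diff(exc)
    x_p <- cp + c(0, as.numeric(stats::filter(ext_p, 1 - kappa, method = "recursive")))
    dx_p <- diff(x_p)

    own <- symbol_chain(m, cfg$symbol_rates, cfg$persistence)
    ext_a <- cfg$step_px * ((own == 2L) - (own == 1L))
    copy <- stats::runif(m) < cfg$fidelity
    src <- seq_len(m) - d
    sel <- copy & src >= 1L & src <= m
    ext_a[sel] <- -dx_p[src[sel]]
    x_a <- ca + c(0, as.numeric(stats::filter(ext_a, 1 - kappa, method = "recursive")))

    off <- bodypart_offsets()
    nb <- nrow(off)
    emit <- function(x_nose, mirror) {
      sgn <- if (mirror) -1 else 1
      x <- outer(x_nose, sgn * off$dx, `+`)
      y <- outer(rep(cy, n), off$dy, `+`)
      if (cfg$noise_sd > 0) {
        x <- x + stats::rnorm(length(x), 0, cfg$noise_sd)
        y <- y + stats::rnorm(length(y), 0, cfg$noise_sd)
      }
      list(x = pmin(pmax(x, 0), width), y = pmin(pmax(y, 0), height))
    }
    pe <- emit(x_p, mirror = FALSE)
    ae <- emit(x_a, mirror = TRUE)
    participant <- pose_track(pe$x, pe$y, bodyparts = off$bodypart,
                              fps = cfg$fps, person_id = "participant",
                              frame_size = c(width, height))
    assistant <- pose_track(ae$x, ae$y, bodyparts = off$bodypart,
                            fps = cfg$fps, person_id = "assistant",
                            frame_size = c(width, height))
    dy <- dyad_track(participant, assistant, dyad_id = dyad_id, group = group)
    truth <- list(lead_lag = d, fidelity = cfg$fidelity,
                  separation = cfg$separation,
                  leader_symbols = movement_levels[leader],
                  latent_x_participant = x_p, latent_x_assistant = x_a,
                  copied = sel)
    files <- NULL
    if (!is.null(write_dir)) {
      if (!dir.exists(write_dir)) dir.create(write_dir, recursive = TRUE)
      fp <- file.path(write_dir, paste0(dyad_id, "_participant.csv"))
      fa <- file.path(write_dir, paste0(dyad_id, "_assistant.csv"))
      ft <- file.path(write_dir, paste0(dyad_id, "_truth.txt"))
      write_pose_table(participant, fp)
      write_pose_table(assistant, fa)
      writeLines(c(
        paste0("dyad_id=", dyad_id), paste0("group=", group),
        paste0("n_frames=", n), paste0("fps=", cfg$fps),
        paste0("lead_lag=", d), paste0("fidelity=", cfg$fidelity),
        paste0("separation=", cfg$separation),
        paste0("noise_sd=", cfg$noise_sd),
        paste0("seed=", if (is.null(cfg$seed)) "NA" else cfg$seed)
      ), ft)
      files <- list(participant = fp, assistant = fa, truth = ft)
    }
    list(dyad = dy, truth = truth, files = files)
  })
}

#' Simulate a two-group dyadic study
#'
#' Generates coordinate-level dyads for a high-IWAH and a low-IWAH group.
#' Defaults mirror the design the analysis targets: 16 high vs 12 low dyads
#' of 9000 frames (5 min at 30 fps), with the high group coupled more
#' faithfully, at a shorter leader lag, and seated closer together.
#'
#' @param n_high,n_low number of dyads per group (defaults 16 and 12; both
#'   must be at least 2).
#' @param cfg_high,cfg_low [sim_config()]s for the two groups (any `seed`
#'   inside them is overridden by per-dyad seeds derived from `seed`).
#' @param seed integer seed governing the whole study.
#' @return An object of class `dyad_study`: `dyads` (list of
#'   [dyad_track()]), `groups` (factor), `truths`, and the configurations.
#' @export
simulate_group_study <- function(n_high = 16, n_low = 12,
                                 cfg_high = sim_config(lead_lag = 11,
                                                       fidelity = 0.95,
                                                       separation = 150),
                                 cfg_low = sim_config(lead_lag = 22,
                                                      fidelity = 0.85,
                                                      separation = 220),
                                 seed = 1) {
  if (n_high < 2L || n_low < 2L) stop("each group needs at least 2 dyads")
  stopifnot(inherits(cfg_high, "sim_config"), inherits(cfg_low, "sim_config"))
  groups <- factor(rep(c("high", "low"), c(n_high, n_low)),
                   levels = c("high", "low"))
  dyads <- vector("list", n_high + n_low)
  truths <- vector("list", n_high + n_low)
  for (i in seq_along(dyads)) {
    cfg <- if (groups[i] == "high") cfg_high else cfg_low
    cfg$seed <- (as.numeric(seed) * 1009 + 104729 * i) %% 2147483647
    sim <- simulate_dyad_coordinates(cfg, dyad_id = sprintf("dyad_%02d", i),
                                     group = as.character(groups[i]))
    dyads[[i]] <- sim$dyad
    truths[[i]] <- sim$truth
  }
  structure(list(dyads = dyads, groups = groups, truths = truths,
                 cfg_high = cfg_high, cfg_low = cfg_low, seed = seed),
            class = "dyad_study")
}

#' @export
print.dyad_study <- function(x, ...) {
  cat("<dyad_study> ", length(x$dyads), " dyads (",
      sum(x$groups == "high"), " high / ", sum(x$groups == "low"),
      " low), ", x$dyads[[1]]$participant$frames, " frames @ ",
      x$dyads[[1]]$participant$fps, " fps\n", sep = "")
  invisible(x)
}
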