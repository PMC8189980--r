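#' Point-light clip constructor
#'
#' A point-light clip stores per-frame, per-point 2-D dot coordinates in
#' screen-centred degrees of visual angle, at a fixed frame rate. Coordinates
#' are kept as `frames x points` matrices (`x`, `y`) for fast access;
#' [clip_table()] gives the long form.
#'
#' @param clip_id Identifier string.
#' @param fps Frames per second (stimulus native rate).
#' @param x,y Numeric `frames x points` matrices of dot coordinates (deg).
#' @param condition One of `"biological"`, `"scrambled"`, `"rotational"`.
#' @return An object of class `point_light_clip`.
#' @export
point_light_clip <- function(clip_id, fps, x, y, condition) {
  condition <- match.arg(condition, c("biological", "scrambled", "rotational"))
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y)))
    stop("x and y coordinate matrices must have identical dimensions")
  if (anyNA(x) || anyNA(y))
    stop("clip coordinates must not contain missing values")
  if (fps <= 0) stop("fps must be positive")
  structure(
    list(clip_id = clip_id, fps = fps, frames = nrow(x), points = ncol(x),
         x = x, y = y, condition = condition),
    class = "point_light_clip"
  )
}

#' @export
print.point_light_clip <- function(x, ...) {
  cat(sprintf("<point_light_clip> '%s': %d frames x %d points @ %g fps (%s, %.2f s)\n",
              x$clip_id, x$frames, x$points, x$fps, x$condition,
              x$frames / x$fps))
  invisible(x)
}

#' Long-format coordinate table of a clip
#'
#' @param clip A [point_light_clip()].
#' @return A data.frame with columns `frame`, `point`, `x_deg`, `y_deg`
#'   (frame-major, `frames * points` rows).
#' @export
clip_table <- function(clip) {
  stopifnot(inherits(clip, "point_light_clip"))
  data.frame(
    frame = rep(seq_len(clip$frames), times = clip$points),
    point = rep(seq_len(clip$points), each = clip$frames),
    x_deg = as.vector(clip$x),
    y_deg = as.vector(clip$y)
  )
}

# Canonical 15-point body layout (deg, figure-centred): head, neck, pelvis,
# left/right shoulder, elbow, wrist, hip, knee, ankle. Limb points move more
# than torso points; the scale factors below encode that.
.walker_layout <- function() {
  pts <- rbind(
    c( 0.00,  2.20), # head
    c( 0.00,  1.60), # neck
    c( 0.00, -0.10), # pelvis
    c(-0.55,  1.45), c( 0.55,  1.45), # shoulders
    c(-0.75,  0.75), c( 0.75,  0.75), # elbows
    c(-0.85,  0.05), c( 0.85,  0.05), # wrists
    c(-0.35, -0.20), c( 0.35, -0.20), # hips
    c(-0.40, -1.30), c( 0.40, -1.30), # knees
    c(-0.45, -2.40), c( 0.45, -2.40)  # ankles
  )
  limb <- c(0.2, 0.2, 0.3, 0.4, 0.4, 0.8, 0.8, 1.0, 1.0,
            0.5, 0.5, 0.9, 0.9, 1.0, 1.0)
  list(base = pts, limb = limb)
}

#' Generate a procedural point-light walker
#'
#' Deterministic sum-of-sinusoids limb model: each dot oscillates around a
#' body-layout base position with two harmonics of the fundamental gait
#' period, so every coordinate signal is exactly periodic with period
#' `gait_period_frames`. Opposite limbs move in anti-phase, giving the
#' signal structure (a dominant gait cycle) that the periodicity estimator
#' and the scrambling/rotation controls rely on.
#'
#' @param duration_s Clip duration in seconds (> 0).
#' @param fps Frames per second (> 0); 120 is the stimulus native rate.
#' @param gait_period_frames Fundamental gait period in frames (>= 4).
#' @param n_points Number of dots (>= 2); 15 covers the major joints.
#' @param seed RNG seed fixing amplitudes and phases.
#' @return A [point_light_clip()] with `condition = "biological"`.
#' @examples
#' w <- generate_walker(4, 120, 100, 15, seed = 1)
#' dominant_period(w)  # 833 ms
#' @export
generate_walker <- function(duration_s = 4, fps = 120, gait_period_frames = 100,
                            n_points = 15, seed = 1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fps <= 0) stop("fps must be positive")
  if (n_points < 2) stop("n_points must be at least 2")
  if (gait_period_frames < 4) stop("gait_period_frames must be at least 4")

  frames <- round(duration_s * fps)
  lay <- .walker_layout()
  n_canon <- nrow(lay$base)
  idx <- ((seq_len(n_points) - 1) %% n_canon) + 1
  base <- lay$base[idx, , drop = FALSE]
  limb <- lay$limb[idx]
  rng <- .local_rng(seed)
  # extra points beyond the canonical 15 get jittered copies of joints
  if (n_points > n_canon) {
    extra <- seq(n_canon + 1, n_points)
    base[extra, ] <- base[extra, ] + matrix(rng(length(extra) * 2, "unif",
                                                min = -0.2, max = 0.2), ncol = 2)
  }

  t_idx <- seq_len(frames) - 1
  x <- matrix(0, frames, n_points)
  y <- matrix(0, frames, n_points)
  # harmonic amplitudes/phases per point; anti-phase for left/right pairs
  for (j in seq_len(n_points)) {
    side_phase <- if (base[j, 1] < 0) 0 else pi
    a1x <- limb[j] * rng(1, "unif", min = 0.25, max = 0.45)
    a2x <- limb[j] * rng(1, "unif", min = 0.05, max = 0.15)
    a1y <- limb[j] * rng(1, "unif", min = 0.10, max = 0.25)
    a2y <- limb[j] * rng(1, "unif", min = 0.03, max = 0.10)
    p1 <- rng(1, "unif", min = -0.4, max = 0.4) + side_phase
    p2 <- rng(1, "unif", min = -0.4, max = 0.4) + side_phase
    w1 <- 2 * pi * t_idx / gait_period_frames
    x[, j] <- base[j, 1] + a1x * sin(w1 + p1) + a2x * sin(2 * w1 + p2)
    y[, j] <- base[j, 2] + a1y * cos(w1 + p1) + a2y * cos(2 * w1 + p2)
  }
  point_light_clip(
    clip_id = sprintf("walker_p%d_s%d", gait_period_frames, seed),
    fps = fps, x = x, y = y, condition = "biological"
  )
}

#' Dominant period of a clip via averaged autocorrelation
#'
#' Mean-centres each point's x and y signal, computes the normalized
#' autocorrelation of each signal at every integer lag (the correlation of
#' the signal with its lag-shifted self over the overlapping stretch),
#' averages over all points and both axes, and returns the lag with the
#' highest averaged autocorrelation inside the search window, expressed in
#' milliseconds (rounded to the nearest ms). For a periodic signal every
#' multiple of the period attains the maximum; ties (within 1e-9) break to
#' the shortest lag, i.e. the fundamental.
#'
#' @param clip A [point_light_clip()].
#' @param window_ms Search window in ms; the default `[250, 2000]` excludes
#'   lag 0 and sub-gait harmonics for human gait at normal speed.
#' @return Dominant period in integer milliseconds.
#' @export
dominant_period <- function(clip, window_ms = c(250, 2000)) {
  stopifnot(inherits(clip, "point_light_clip"))
  lag_min <- max(1L, ceiling(window_ms[1] * clip$fps / 1000))
  lag_max <- floor(window_ms[2] * clip$fps / 1000)
  n <- clip$frames
  if (n <= lag_max)
    stop("insufficient data: clip has ", n,
         " frames but the search window needs more than ", lag_max)
  z <- cbind(clip$x, clip$y)
  z <- sweep(z, 2, colMeans(z))
  denom <- colSums(z^2)
  keep <- denom > 0           # constant signals carry no period information
  if (!any(keep)) stop("insufficient data: all signals are constant")
  z <- z[, keep, drop = FALSE]
  denom <- denom[keep]
  z2 <- z^2
  lags <- lag_min:lag_max
  acf_mean <- vapply(lags, function(L) {
    head_ss <- colSums(z2[1:(n - L), , drop = FALSE])
    tail_ss <- colSums(z2[(1 + L):n, , drop = FALSE])
    num <- colSums(z[1:(n - L), , drop = FALSE] * z[(1 + L):n, , drop = FALSE])
    mean(num / sqrt(head_ss * tail_ss))
  }, numeric(1))
  best <- lags[which(acf_mean >= max(acf_mean) - 1e-9)[1]]
  as.integer(round(best / clip$fps * 1000))
}

#' Phase-scrambling parameters
#'
#' The per-point random time offsets are drawn uniformly on
#' `[-max_offset_ms, +max_offset_ms]` with `max_offset_ms` fixed at half the
#' dominant period (rounded), so an offset can move a dot anywhere within
#' its gait cycle.
#'
#' @param period_ms Dominant period of the source clip in ms (833 for the
#'   reference gait).
#' @param seed RNG seed for the offsets.
#' @return An object of class `scramble_params` with fields `period_ms`,
#'   `max_offset_ms`, `seed`.
#' @export
scramble_params <- function(period_ms = 833, seed = 1) {
  stopifnot(period_ms > 0)
  # conventional half-up rounding: 833 / 2 = 416.5 becomes 417
  structure(
    list(period_ms = period_ms, max_offset_ms = floor(period_ms / 2 + 0.5),
         seed = seed),
    class = "scramble_params"
  )
}

#' Phase-scramble a biological clip
#'
#' Shifts each point's trajectory in time by an independent uniform offset,
#' cyclically with wrap period equal to the dominant gait period. The shift
#' is a pure phase change, so each point's within-period local motion (the
#' multiset of frame-to-frame displacements) is preserved exactly while the
#' global body configuration is destroyed.
#'
#' @param clip A biological [point_light_clip()], exactly periodic with
#'   `params$period_ms` (as produced by [generate_walker()]).
#' @param params A [scramble_params()].
#' @return A [point_light_clip()] with `condition = "scrambled"` and the
#'   same frames, fps and point count as the input.
#' @export
phase_scramble <- function(clip, params) {
  stopifnot(inherits(clip, "point_light_clip"), inherits(params, "scramble_params"))
  if (clip$condition != "biological")
    stop("phase_scramble requires a biological clip, got '", clip$condition, "'")
  wrap <- round(params$period_ms * clip$fps / 1000)
  if (wrap < 1 || wrap > clip$frames)
    stop("wrap period (", wrap, " frames) must lie within the clip")
  rng <- .local_rng(params$seed)
  offset_ms <- rng(clip$points, "unif",
                   min = -params$max_offset_ms, max = params$max_offset_ms)
  offset_fr <- round(offset_ms * clip$fps / 1000)
  x <- clip$x; y <- clip$y
  t0 <- seq_len(clip$frames) - 1L
  for (j in seq_len(clip$points)) {
    src <- ((t0 + offset_fr[j]) %% wrap) + 1L  # phase within the gait cycle
    x[, j] <- clip$x[src, j]
    y[, j] <- clip$y[src, j]
  }
  point_light_clip(
    clip_id = paste0(clip$clip_id, "_scr", params$seed),
    fps = clip$fps, x = x, y = y, condition = "scrambled"
  )
}

#' Rotational (spinning first frame) control clip
#'
#' Takes frame 0 of a biological clip as a rigid 2-D point set with implied
#' depth zero and rotates it about the vertical axis through its centroid at
#' constant angular speed `2 * pi / hip_period_ms`, rendering the
#' orthographic x-projection per frame; y is unchanged. The first rendered
#' frame equals the biological clip's first frame, so the initial view is
#' comparable across conditions.
#'
#' @param clip A biological [point_light_clip()].
#' @param hip_period_ms Rotation period in ms (> 0), the dominant hip
#'   periodicity of the source motion.
#' @return A [point_light_clip()] with `condition = "rotational"`.
#' @export
rotational_control <- function(clip, hip_period_ms) {
  stopifnot(inherits(clip, "point_light_clip"))
  if (clip$condition != "biological")
    stop("rotational_control requires a biological clip, got '", clip$condition, "'")
  if (hip_period_ms <= 0) stop("hip_period_ms must be positive")
  x0 <- clip$x[1, ]; y0 <- clip$y[1, ]
  cx <- mean(x0)
  t_ms <- (seq_len(clip$frames) - 1) / clip$fps * 1000
  theta <- 2 * pi * t_ms / hip_period_ms
  # vertical-axis rotation of (dx, z = 0): projected x offset scales by cos
  x <- cx + outer(cos(theta), x0 - cx)
  y <- matrix(y0, clip$frames, clip$points, byrow = TRUE)
  point_light_clip(
    clip_id = paste0(clip$clip_id, "_rot"),
    fps = clip$fps, x = x, y = y, condition = "rotational"
  )
}

#' Compose a side-by-side presentation scene
#'
#' Places a biological and a non-biological clip side-by-side, each
#' horizontally centred in its half of the screen (offset
#' `width_deg / 4` from screen centre), with the biological clip on
#' `bio_side`.
#'
#' @param bio Biological [point_light_clip()].
#' @param control Non-biological clip with matching fps/frames/points.
#' @param bio_side `"left"` or `"right"`.
#' @param geometry A [screen_geometry()].
#' @param trial_id Identifier.
#' @param onset_ms Trial onset on the recording clock.
#' @return An object of class `scene_clip`; its `left_clip`/`right_clip`
#'   carry screen-centred coordinates (already offset).
#' @export
compose_scene <- function(bio, control, bio_side = c("left", "right"),
                          geometry = screen_geometry(), trial_id = "t1",
                          onset_ms = 0) {
  bio_side <- match.arg(bio_side)
  stopifnot(inherits(bio, "point_light_clip"), inherits(control, "point_light_clip"))
  if (bio$condition != "biological")
    stop("'bio' clip must have condition biological")
  if (control$condition == "biological")
    stop("'control' clip must be non-biological")
  if (bio$fps != control$fps || bio$frames != control$frames ||
      bio$points != control$points)
    stop("composition error: clips differ in fps, frame count or point count")
  offset_deg <- pixels_to_degrees(geometry$width_px, geometry) / 4
  shift <- function(clip, dx) {
    clip$x <- clip$x + dx
    clip
  }
  if (bio_side == "left") {
    left <- shift(bio, -offset_deg); right <- shift(control, offset_deg)
  } else {
    left <- shift(control, -offset_deg); right <- shift(bio, offset_deg)
  }
  structure(
    list(trial_id = trial_id, left_clip = left, right_clip = right,
         bio_side = bio_side, onset_ms = onset_ms,
         duration_ms = bio$frames / bio$fps * 1000,
         offset_deg = offset_deg, geometry = geometry),
    class = "scene_clip"
  )
}

#' Trial-set configuration
#'
#' @param n_trials Total number of trials (60 in the reference design).
#' @param n_blocks Number of blocks (6); `n_trials` must be divisible by it.
#' @param isi_range_ms Inter-stimulus interval range in ms, drawn uniformly.
#' @param control_mix Fraction of trials whose control is phase-scrambled
#'   (the rest use the rotational control).
#' @param seed RNG seed for side order, control draw, offsets and gaps.
#' @return An object of class `trial_set_config`.
#' @export
trial_set_config <- function(n_trials = 60, n_blocks = 6,
                             isi_range_ms = c(1500, 2000),
                             control_mix = 0.5, seed = 1) {
  if (n_trials %% n_blocks != 0)
    stop("configuration error: n_trials (", n_trials,
         ") is not divisible by n_blocks (", n_blocks, ")")
  stopifnot(control_mix >= 0, control_mix <= 1,
            length(isi_range_ms) == 2, isi_range_ms[1] <= isi_range_ms[2])
  structure(
    list(n_trials = n_trials, n_blocks = n_blocks,
         trials_per_block = n_trials %/% n_blocks,
         isi_range_ms = isi_range_ms, control_mix = control_mix, seed = seed),
    class = "trial_set_config"
  )
}

#' Build a counterbalanced side-by-side trial set
#'
#' From one or more source biological clips, builds `n_trials` scenes in
#' `n_blocks` blocks with the biological side exactly counterbalanced
#' (left/right counts differ by at most one; equal for even `n_trials`),
#' per-trial controls drawn per `control_mix`, and onsets spaced by the clip
#' duration plus a uniform inter-stimulus gap. Deterministic under
#' `config$seed`.
#'
#' @param config A [trial_set_config()].
#' @param source_clips A biological clip or list of them; trials cycle
#'   through the list.
#' @param geometry A [screen_geometry()].
#' @param period_ms Dominant period used for scrambling and rotation; when
#'   `NULL` it is estimated from the first source clip via
#'   [dominant_period()].
#' @param start_ms Onset of the first trial.
#' @return An object of class `trial_set`: a list with `scenes` (list of
#'   [compose_scene()] results), `config`, `geometry` and `period_ms`.
#' @export
make_trial_set <- function(config = trial_set_config(),
                           source_clips = generate_walker(),
                           geometry = screen_geometry(),
                           period_ms = NULL, start_ms = 1000) {
  stopifnot(inherits(config, "trial_set_config"))
  if (inherits(source_clips, "point_light_clip"))
    source_clips <- list(source_clips)
  if (length(source_clips) < 1) stop("at least one source clip is required")
  for (cl in source_clips)
    if (cl$condition != "biological") stop("source clips must be biological")
  if (is.null(period_ms)) period_ms <- dominant_period(source_clips[[1]])

  n <- config$n_trials
  rng <- .local_rng(config$seed)
  sides <- c(rep("left", n %/% 2), rep("right", n - n %/% 2))
  sides <- sides[rng(n, "perm")]
  scrambled <- rng(n, "unif") < config$control_mix
  gaps <- rng(n, "unif", min = config$isi_range_ms[1],
              max = config$isi_range_ms[2])

  scenes <- vector("list", n)
  onset <- start_ms
  for (i in seq_len(n)) {
    src <- source_clips[[((i - 1) %% length(source_clips)) + 1]]
    ctrl <- if (scrambled[i]) {
      phase_scramble(src, scramble_params(period_ms,
                                          seed = derive_seed(config$seed, i)))
    } else {
      rotational_control(src, period_ms)
    }
    scenes[[i]] <- compose_scene(src, ctrl, bio_side = sides[i],
                                 geometry = geometry,
                                 trial_id = sprintf("trial_%02d", i),
                                 onset_ms = onset)
    scenes[[i]]$block <- ((i - 1) %/% config$trials_per_block) + 1
    onset <- onset + scenes[[i]]$duration_ms + gaps[i]
  }
  structure(
    list(scenes = scenes, config = config, geometry = geometry,
         period_ms = period_ms),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  sides <- vapply(x$scenes, `[[`, character(1), "bio_side")
  cat(sprintf("<trial_set> %d trials in %d blocks (bio left/right: %d/%d), period %d ms\n",
              length(x$scenes), x$config$n_blocks,
              sum(sides == "left"), sum(sides == "right"), x$period_ms))
  invisible(x)
}

#' Trial manifest of a trial set
#'
#' @param trial_set A [make_trial_set()] result.
#' @return A data.frame with one row per trial: `trial_id`, `block`,
#'   `bio_side`, `control_condition`, `onset_ms`, `duration_ms`.
#' @export
trial_manifest <- function(trial_set) {
  stopifnot(inherits(trial_set, "trial_set"))
  do.call(rbind, lapply(trial_set$scenes, function(s) {
    ctrl <- if (s$bio_side == "left") s$right_clip else s$left_clip
    data.frame(trial_id = s$trial_id, block = s$block, bio_side = s$bio_side,
               control_condition = ctrl$condition, onset_ms = s$onset_ms,
               duration_ms = s$duration_ms)
  }))
}
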