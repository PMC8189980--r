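#' Dynamic ROI configuration
#'
#' Each stimulus side's region of interest is the union of circles of
#' `radius_deg` degrees of visual angle centred on that side's dots,
#' recomputed every stimulus frame. A fixation is assigned to an ROI when at
#' least `assignment_rule` of its tracked samples fall inside it.
#'
#' @param radius_deg Circle radius in degrees (3.7 by default).
#' @param assignment_rule Required in-ROI sample fraction, in `(0, 1]`.
#' @return An object of class `roi_config`.
#' @export
roi_config <- function(radius_deg = 3.7, assignment_rule = 0.5) {
  stopifnot(radius_deg > 0, assignment_rule > 0, assignment_rule <= 1)
  structure(list(radius_deg = radius_deg, assignment_rule = assignment_rule),
            class = "roi_config")
}

#' Classify gaze positions against a scene's dynamic ROIs
#'
#' For each query the stimulus frame active at `t_ms` is selected
#' (`floor((t - onset) * fps / 1000)`), and the position is inside an ROI iff
#' it lies within `radius_deg` (in pixels) of any dot of that side's clip in
#' that frame. A position inside both ROIs takes the side of the nearest
#' dot. Times outside the scene's presentation window return `"neither"`.
#'
#' @param scene A [compose_scene()] result.
#' @param t_ms,x_px,y_px Equal-length vectors of sample times and gaze
#'   positions (pixels, screen origin top-left).
#' @param geometry A [screen_geometry()]; defaults to the scene's.
#' @param roi A [roi_config()].
#' @return Character vector over `{"bio", "nonbio", "neither"}`.
#' @export
roi_membership <- function(scene, t_ms, x_px, y_px,
                           geometry = scene$geometry, roi = roi_config()) {
  stopifnot(inherits(scene, "scene_clip"))
  n <- length(t_ms)
  out <- rep("neither", n)
  bio <- if (scene$bio_side == "left") scene$left_clip else scene$right_clip
  ctl <- if (scene$bio_side == "left") scene$right_clip else scene$left_clip
  fr <- floor((t_ms - scene$onset_ms) * bio$fps / 1000) + 1
  ok <- !is.na(x_px) & t_ms >= scene$onset_ms &
    t_ms < scene$onset_ms + scene$duration_ms & fr >= 1 & fr <= bio$frames
  if (!any(ok)) return(out)
  ppd <- pixels_per_degree(geometry)
  r_px2 <- (roi$radius_deg * ppd)^2
  dot_px_x <- function(clip, f) geometry$width_px / 2 + clip$x[f, , drop = FALSE] * ppd
  dot_px_y <- function(clip, f) geometry$height_px / 2 - clip$y[f, , drop = FALSE] * ppd
  f <- fr[ok]
  min_d2 <- function(clip) {
    dx <- dot_px_x(clip, f) - x_px[ok]
    dy <- dot_px_y(clip, f) - y_px[ok]
    do.call(pmin, as.data.frame(dx^2 + dy^2))
  }
  d2b <- min_d2(bio)
  d2c <- min_d2(ctl)
  cls <- rep("neither", sum(ok))
  in_b <- d2b <= r_px2
  in_c <- d2c <= r_px2
  cls[in_b & !in_c] <- "bio"
  cls[in_c & !in_b] <- "nonbio"
  both <- in_b & in_c
  cls[both] <- ifelse(d2b[both] <= d2c[both], "bio", "nonbio")
  out[ok] <- cls
  out
}

#' Total valid time
#'
#' Percentage of samples within stimulus-presentation windows in which the
#' participant gazed at the screen: at least one eye tracked and the
#' cyclopean position inside the screen bounds. The complement of data
#' loss.
#'
#' @param recording A `gaze_recording`.
#' @param trial_set A [make_trial_set()] defining the presentation windows.
#' @param geometry A [screen_geometry()].
#' @return Percentage in `[0, 100]`, or `NA` if no samples fall in any
#'   window.
#' @export
total_valid_time <- function(recording, trial_set,
                             geometry = trial_set$geometry) {
  s <- recording$samples
  man <- trial_manifest(trial_set)
  in_win <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(man)))
    in_win <- in_win | (s$t_ms >= man$onset_ms[i] &
                          s$t_ms < man$onset_ms[i] + man$duration_ms[i])
  if (!any(in_win)) return(NA_real_)
  s <- s[in_win, , drop = FALSE]
  any_valid <- s$l_valid | s$r_valid
  cx <- rowMeans(cbind(s$lx_px, s$rx_px), na.rm = TRUE)
  cy <- rowMeans(cbind(s$ly_px, s$ry_px), na.rm = TRUE)
  on_screen <- !is.na(cx) & !is.na(cy) &
    cx >= 0 & cx <= geometry$width_px & cy >= 0 & cy <= geometry$height_px
  100 * mean(any_valid & on_screen)
}

# Per-sample ROI classification of tracked fixation samples.
# Returns data.frame(fix = fixation row index, t_ms, class).
.classify_fixation_samples <- function(fixations, recording, trial_set,
                                       roi = roi_config()) {
  empty <- data.frame(fix = integer(0), t_ms = numeric(0),
                      class = character(0))
  if (nrow(fixations) == 0) return(empty)
  s <- recording$samples
  ord <- order(fixations$start_ms)
  fixations <- fixations[ord, , drop = FALSE]
  tracked <- s$l_valid & s$r_valid
  # map each tracked sample to the (non-overlapping) fixation containing it
  k <- findInterval(s$t_ms, fixations$start_ms)
  in_fix <- k >= 1 & tracked
  in_fix[in_fix] <- s$t_ms[in_fix] < fixations$end_ms[k[in_fix]] &
    !is.na(fixations$trial_id[k[in_fix]])
  idx <- which(in_fix)
  if (!length(idx)) return(empty)
  fixk <- k[idx]
  tid <- fixations$trial_id[fixk]
  cx <- (s$lx_px[idx] + s$rx_px[idx]) / 2
  cy <- (s$ly_px[idx] + s$ry_px[idx]) / 2
  cls <- rep("neither", length(idx))
  for (sc in trial_set$scenes) {
    sel <- which(tid == sc$trial_id)
    if (!length(sel)) next
    cls[sel] <- roi_membership(sc, s$t_ms[idx[sel]], cx[sel], cy[sel],
                               geometry = trial_set$geometry, roi = roi)
  }
  data.frame(fix = ord[fixk], t_ms = s$t_ms[idx], class = cls)
}

#' Preference for biological motion
#'
#' Ratio of the total time spent looking at biological motion to the total
#' time spent looking at biological and non-biological motion together,
#' pooled over all trials: looking time accrues per tracked fixation
#' sample, classified against the dynamic ROIs at that sample's time and
#' position.
#'
#' @param fixations Output of [detect_fixations()] with trial assignment.
#' @param recording The `gaze_recording` the fixations came from.
#' @param trial_set The [make_trial_set()] presented.
#' @param roi A [roi_config()].
#' @return Percentage in `[0, 100]`, or `NA` if no on-ROI looking time.
#' @export
preference_biological <- function(fixations, recording, trial_set,
                                  roi = roi_config()) {
  cls <- .classify_fixation_samples(fixations, recording, trial_set, roi)
  .preference_from_cls(cls)
}

.preference_from_cls <- function(cls) {
  t_bio <- sum(cls$class == "bio")
  t_non <- sum(cls$class == "nonbio")
  if (t_bio + t_non == 0) return(NA_real_)
  100 * t_bio / (t_bio + t_non)
}

#' First-fixation metrics
#'
#' Per trial, the first fixation assigned to each ROI (per the
#' `assignment_rule` sample-fraction rule) defines that side's first-look
#' latency as fixation start minus trial onset. The share of trials whose
#' earliest ROI fixation is on the biological side gives
#' `first_fix_bio_pct`; each latency metric averages only the trials on
#' which that side was fixated at all.
#'
#' @inheritParams preference_biological
#' @return A list with `first_fix_bio_pct`, `latency_bio_ms`,
#'   `latency_nonbio_ms`, `n_trials_bio`, `n_trials_nonbio` (all `NA`/0 if
#'   no trial has an ROI fixation).
#' @export
first_fixation_metrics <- function(fixations, recording, trial_set,
                                   roi = roi_config()) {
  cls <- .classify_fixation_samples(fixations, recording, trial_set, roi)
  .first_fix_from_cls(fixations, cls, trial_set, roi)
}

.first_fix_from_cls <- function(fixations, cls, trial_set, roi) {
  empty <- list(first_fix_bio_pct = NA_real_, latency_bio_ms = NA_real_,
                latency_nonbio_ms = NA_real_, n_trials_bio = 0L,
                n_trials_nonbio = 0L)
  if (nrow(fixations) == 0 || nrow(cls) == 0) return(empty)
  # fixation-level ROI assignment: fraction of tracked samples in each ROI
  agg <- tapply(cls$class, cls$fix, function(v) {
    fb <- mean(v == "bio"); fn <- mean(v == "nonbio")
    if (fb >= roi$assignment_rule && fb >= fn) "bio"
    else if (fn >= roi$assignment_rule && fn > fb) "nonbio"
    else "none"
  })
  side <- rep("none", nrow(fixations))
  side[as.integer(names(agg))] <- as.character(agg)

  man <- trial_manifest(trial_set)
  onset <- stats::setNames(man$onset_ms, man$trial_id)
  first_side <- character(0)
  lat_bio <- numeric(0); lat_non <- numeric(0)
  for (tid in man$trial_id) {
    in_tr <- which(!is.na(fixations$trial_id) & fixations$trial_id == tid &
                     side != "none" & fixations$start_ms >= onset[[tid]])
    if (!length(in_tr)) next
    in_tr <- in_tr[order(fixations$start_ms[in_tr])]
    first_side[length(first_side) + 1] <- side[in_tr[1]]
    b <- in_tr[side[in_tr] == "bio"]
    if (length(b))
      lat_bio[length(lat_bio) + 1] <- fixations$start_ms[b[1]] - onset[[tid]]
    nb <- in_tr[side[in_tr] == "nonbio"]
    if (length(nb))
      lat_non[length(lat_non) + 1] <- fixations$start_ms[nb[1]] - onset[[tid]]
  }
  if (!length(first_side)) return(empty)
  list(
    first_fix_bio_pct = 100 * mean(first_side == "bio"),
    latency_bio_ms = if (length(lat_bio)) mean(lat_bio) else NA_real_,
    latency_nonbio_ms = if (length(lat_non)) mean(lat_non) else NA_real_,
    n_trials_bio = length(lat_bio),
    n_trials_nonbio = length(lat_non)
  )
}

#' All per-participant eye-movement metrics
#'
#' Runs fixation detection and computes the five metrics for one recording:
#' total valid time, preference for biological motion, first-fixation share
#' on biological motion, and the two first-fixation latencies.
#'
#' @param recording A `gaze_recording`.
#' @param trial_set The presented [make_trial_set()].
#' @param geometry A [screen_geometry()].
#' @param fix_params A [fixation_params()].
#' @param roi A [roi_config()].
#' @return A one-row data.frame with columns `participant_id`,
#'   `total_valid_pct`, `preference_bio_pct`, `first_fix_bio_pct`,
#'   `latency_bio_ms`, `latency_nonbio_ms`, `n_trials_bio_latency`,
#'   `n_trials_nonbio_latency`.
#' @export
participant_metrics <- function(recording, trial_set,
                                geometry = trial_set$geometry,
                                fix_params = fixation_params(),
                                roi = roi_config()) {
  fx <- detect_fixations(recording, geometry, fix_params, trial_set)
  cls <- .classify_fixation_samples(fx, recording, trial_set, roi)
  ff <- .first_fix_from_cls(fx, cls, trial_set, roi)
  data.frame(
    participant_id = recording$participant_id,
    total_valid_pct = total_valid_time(recording, trial_set, geometry),
    preference_bio_pct = .preference_from_cls(cls),
    first_fix_bio_pct = ff$first_fix_bio_pct,
    latency_bio_ms = ff$latency_bio_ms,
    latency_nonbio_ms = ff$latency_nonbio_ms,
    n_trials_bio_latency = ff$n_trials_bio,
    n_trials_nonbio_latency = ff$n_trials_nonbio
  )
}

#' Metrics table for a whole cohort
#'
#' @param cohort A [simulate_cohort()] result (or a list with `recordings`
#'   and `trial_set`).
#' @param fix_params A [fixation_params()].
#' @param roi A [roi_config()].
#' @return A data.frame with one [participant_metrics()] row per recording.
#' @export
cohort_metrics <- function(cohort, fix_params = fixation_params(),
                           roi = roi_config()) {
  rows <- lapply(cohort$recordings, participant_metrics,
                 trial_set = cohort$trial_set, fix_params = fix_params,
                 roi = roi)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
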