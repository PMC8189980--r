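#' Gaze-generator parameters for one group
#'
#' Parameters of the synthetic binocular gaze process. A participant's gaze
#' alternates fixations and saccades; during each trial the first on-ROI
#' fixation begins at onset plus a truncated-normal latency, and each
#' on-stimulus fixation is allocated to the biological side with probability
#' `p_bio`. Tracking loss arrives in geometric-length runs so the long-run
#' tracked fraction approximates `p_valid`. The `*_between_sd*` fields give
#' between-participant heterogeneity: each simulated participant draws an
#' individual `p_bio`, `p_valid` and latency mean around the group value.
#'
#' @param p_bio Target fraction of on-stimulus looking time on the
#'   biological side, in `[0, 1]`.
#' @param p_valid Target tracked-sample fraction, in `[0, 1]`.
#' @param first_fix_latency_mean_ms,first_fix_latency_sd_ms Mean and
#'   within-participant SD of the first on-ROI fixation latency (ms).
#' @param fixation_dur_mean_ms Mean fixation duration (ms); durations are
#'   gamma with shape 4.
#' @param saccade_dur_ms Saccade duration (ms); one 30 Hz sample by default.
#' @param dropout_run_geometric_p Geometric parameter for untracked run
#'   lengths (runs have mean `1 / p` samples).
#' @param binocular_noise_deg Per-eye, per-axis Gaussian positional noise
#'   (degrees of visual angle).
#' @param p_bio_between_sd,p_valid_between_sd,latency_between_sd_ms
#'   Between-participant SDs of the individual allocation fraction, tracked
#'   fraction and latency mean.
#' @return An object of class `gaze_model_params`.
#' @seealso [asd_model_params()], [td_model_params()] for the calibrated
#'   group presets.
#' @export
gaze_model_params <- function(p_bio = 0.5, p_valid = 1.0,
                              first_fix_latency_mean_ms = 550,
                              first_fix_latency_sd_ms = 150,
                              fixation_dur_mean_ms = 300,
                              saccade_dur_ms = 1000 / 30,
                              dropout_run_geometric_p = 1 / 3,
                              binocular_noise_deg = 0.3,
                              p_bio_between_sd = 0.085,
                              p_valid_between_sd = 0.08,
                              latency_between_sd_ms = 150) {
  stopifnot(p_bio >= 0, p_bio <= 1, p_valid >= 0, p_valid <= 1,
            first_fix_latency_mean_ms > 0, fixation_dur_mean_ms > 0,
            saccade_dur_ms > 0, dropout_run_geometric_p > 0,
            dropout_run_geometric_p <= 1, binocular_noise_deg >= 0)
  structure(
    list(p_bio = p_bio, p_valid = p_valid,
         first_fix_latency_mean_ms = first_fix_latency_mean_ms,
         first_fix_latency_sd_ms = first_fix_latency_sd_ms,
         fixation_dur_mean_ms = fixation_dur_mean_ms,
         saccade_dur_ms = saccade_dur_ms,
         dropout_run_geometric_p = dropout_run_geometric_p,
         binocular_noise_deg = binocular_noise_deg,
         p_bio_between_sd = p_bio_between_sd,
         p_valid_between_sd = p_valid_between_sd,
         latency_between_sd_ms = latency_between_sd_ms),
    class = "gaze_model_params"
  )
}

#' Calibrated group presets
#'
#' Generator presets carrying the reference group means: allocation fraction
#' 0.545 (ASD-like) vs. 0.619 (TD-like), tracked fraction 0.800 vs. 0.892,
#' and first-fixation latency mean 649.1 ms vs. 521.3 ms.
#'
#' @param ... Overrides passed to [gaze_model_params()].
#' @return A `gaze_model_params` object.
#' @export
asd_model_params <- function(...) {
  defaults <- list(p_bio = 0.545, p_valid = 0.800,
                   first_fix_latency_mean_ms = 649.1)
  do.call(gaze_model_params, utils::modifyList(defaults, list(...)))
}

#' @rdname asd_model_params
#' @export
td_model_params <- function(...) {
  defaults <- list(p_bio = 0.619, p_valid = 0.892,
                   first_fix_latency_mean_ms = 521.3)
  do.call(gaze_model_params, utils::modifyList(defaults, list(...)))
}

#' Participant profile
#'
#' @param participant_id Identifier.
#' @param group `"ASD-like"` or `"TD-like"`.
#' @param age Age in years.
#' @param gender `"male"` or `"female"`.
#' @param iq IQ composite score in `[60, 136]`, or `NA` (TD-like group).
#' @param symptom_scores Named numeric vector over the 29 subscales of
#'   [symptom_subscales()], or `NULL`.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, group = c("ASD-like", "TD-like"),
                                age, gender = c("male", "female"),
                                iq = NA_real_, symptom_scores = NULL) {
  group <- match.arg(group)
  gender <- match.arg(gender)
  if (!is.na(iq) && (iq < 60 || iq > 136))
    stop("iq must lie within [60, 136]")
  if (!is.null(symptom_scores)) {
    want <- symptom_subscales()$key
    if (!setequal(names(symptom_scores), want))
      stop("symptom_scores must cover exactly the 29 named subscales")
    symptom_scores <- symptom_scores[want]
  }
  structure(
    list(participant_id = participant_id, group = group, age = age,
         gender = gender, iq = iq, symptom_scores = symptom_scores),
    class = "participant_profile"
  )
}

#' The 29 symptom subscales
#'
#' Canonical list of the behaviour-rating subscales whose scores enter the
#' severity and correlation analyses. Scores are treated as opaque numbers.
#'
#' @return A data.frame with columns `key` (syntactic identifier), `scale`
#'   and `subscale`; 29 rows.
#' @export
symptom_subscales <- function() {
  tab <- rbind(
    c("ABI", "Core ASD symptom scale score"),
    c("ABI", "Challenging behavior"),
    c("ABI", "Mental health"),
    c("ABI", "Restrictive repetitive behaviors"),
    c("ABI", "Self-regulation"),
    c("ABI", "Social communication"),
    c("ADOS-2", "Restricted and repetitive behavior"),
    c("ADOS-2", "Social affect"),
    c("ADOS-2", "Total score"),
    c("ABC", "Hyperactivity non-compliance"),
    c("ABC", "Inappropriate speech"),
    c("ABC", "Irritability"),
    c("ABC", "Lethargy social withdrawal"),
    c("ABC", "Stereotypic behavior"),
    c("CASI-Anx", "Total score"),
    c("RBS-R", "Compulsive behavior"),
    c("RBS-R", "Ritualistic behavior"),
    c("RBS-R", "Restricted behavior"),
    c("RBS-R", "Sameness behavior"),
    c("RBS-R", "Self-injurious behavior"),
    c("RBS-R", "Stereotyped behavior"),
    c("RBS-R", "Total score"),
    c("SRS-2", "Social awareness"),
    c("SRS-2", "Social cognition"),
    c("SRS-2", "Social communication"),
    c("SRS-2", "Social motivation"),
    c("SRS-2", "Restricted interests and repetitive behavior"),
    c("SRS-2", "Social communication and interaction"),
    c("SRS-2", "Total score")
  )
  key <- paste(tolower(gsub("[^A-Za-z0-9]+", "_", tab[, 1])),
               tolower(gsub("[^A-Za-z0-9]+", "_", tab[, 2])), sep = ".")
  data.frame(key = key, scale = tab[, 1], subscale = tab[, 2])
}

.truncnorm1 <- function(rng, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(min(max(mean, lower), upper))
  for (i in 1:1000) {
    v <- rng(1, "norm", mean = mean, sd = sd)
    if (v >= lower && v <= upper) return(v)
  }
  min(max(mean, lower), upper)
}

# dot position (screen-centred deg) of a random dot on `side` of `scene`
# at recording time t_ms
.dot_target <- function(scene, t_ms, side, rng) {
  clip <- if ((side == "bio") == (scene$bio_side == "left"))
    scene$left_clip else scene$right_clip
  fr <- floor((t_ms - scene$onset_ms) * clip$fps / 1000) + 1
  fr <- min(max(fr, 1), clip$frames)
  j <- 1 + floor(rng(1, "unif") * clip$points)
  c(clip$x[fr, j], clip$y[fr, j])
}

#' Simulate a binocular gaze recording for one participant
#'
#' Generates a 30 Hz binocular sample stream over the trial set with an
#' alternating fixation/saccade process, per-fixation biological-side
#' allocation, geometric-run tracking dropout shared between the eyes, and
#' independent per-eye positional noise. Between trials and before the
#' first on-ROI fixation of each trial the participant fixates the screen
#' centre (the inter-stimulus attention-getter position). Alongside the
#' samples, the recording carries a ground-truth event log (true on-ROI
#' fixation intervals with sides, and the true first-fixation latency per
#' trial) used to validate the detector and metrics.
#'
#' @param profile A [participant_profile()].
#' @param trial_set A [make_trial_set()] result.
#' @param params A [gaze_model_params()].
#' @param geometry A [screen_geometry()].
#' @param seed RNG seed; identical seeds give identical recordings.
#' @return An object of class `gaze_recording`: list with `participant_id`,
#'   `sample_rate_hz`, `samples` (data.frame `t_ms, lx_px, ly_px, rx_px,
#'   ry_px, l_valid, r_valid`), and `truth`.
#' @export
simulate_participant <- function(profile, trial_set, params,
                                 geometry = trial_set$geometry, seed = 1) {
  stopifnot(inherits(trial_set, "trial_set"), inherits(params, "gaze_model_params"))
  if (length(trial_set$scenes) == 0)
    stop("configuration error: trial set is empty")
  rng <- .local_rng(seed)
  dt <- 1000 / 30

  # individual-level parameter draws (between-participant heterogeneity)
  p_bio_i <- .truncnorm1(rng, params$p_bio, params$p_bio_between_sd, 0.02, 0.98)
  # a perfect tracking rate admits no downward heterogeneity: keep it exact
  p_valid_i <- if (params$p_valid >= 1) 1 else
    .truncnorm1(rng, params$p_valid, params$p_valid_between_sd, 0.05, 0.995)
  lat_mean_i <- .truncnorm1(rng, params$first_fix_latency_mean_ms,
                            params$latency_between_sd_ms, 100, Inf)

  sacc <- params$saccade_dur_ms
  fix_shape <- 4
  fix_scale <- params$fixation_dur_mean_ms / fix_shape
  jitter_sd <- 0.3

  # --- build the piecewise segment timeline -------------------------------
  # columns: start, end, x0, y0, x1, y1 (deg; x0==x1 for fixations)
  seg_start <- seg_end <- seg_x0 <- seg_y0 <- seg_x1 <- seg_y1 <- numeric(0)
  truth_start <- truth_end <- numeric(0)
  truth_side <- truth_trial <- character(0)
  ff_trial <- character(0); ff_lat <- numeric(0); ff_side <- character(0)

  cur_t <- 0
  cur_pos <- c(rng(1, "norm", sd = jitter_sd), rng(1, "norm", sd = jitter_sd))
  add_seg <- function(s, e, p0, p1) {
    seg_start[length(seg_start) + 1] <<- s
    seg_end[length(seg_end) + 1] <<- e
    seg_x0[length(seg_x0) + 1] <<- p0[1]; seg_y0[length(seg_y0) + 1] <<- p0[2]
    seg_x1[length(seg_x1) + 1] <<- p1[1]; seg_y1[length(seg_y1) + 1] <<- p1[2]
  }
  move_to <- function(t_end, target) {
    # saccade from cur_pos to target starting at cur_t, then hold to t_end
    s_end <- min(cur_t + sacc, t_end)
    add_seg(cur_t, s_end, cur_pos, target)
    if (t_end > s_end) add_seg(s_end, t_end, target, target)
    cur_t <<- t_end
    cur_pos <<- target
  }

  scenes <- trial_set$scenes
  onsets <- vapply(scenes, `[[`, numeric(1), "onset_ms")
  ord <- order(onsets)
  for (i in ord) {
    sc <- scenes[[i]]
    t_on <- sc$onset_ms
    t_off <- t_on + sc$duration_ms
    lat <- .truncnorm1(rng, lat_mean_i, params$first_fix_latency_sd_ms, dt + 1, Inf)
    t_first <- t_on + lat
    if (t_first >= t_off) t_first <- t_off - 2 * dt  # degenerate long latency
    # centre fixation until the first stimulus-directed saccade
    if (t_first - sacc > cur_t) {
      ctr <- c(rng(1, "norm", sd = jitter_sd), rng(1, "norm", sd = jitter_sd))
      move_to(t_first - sacc, ctr)
    }
    first <- TRUE
    t_cur <- t_first
    while (t_cur < t_off - dt) {
      side <- if (rng(1, "unif") < p_bio_i) "bio" else "nonbio"
      tgt <- .dot_target(sc, t_cur, side, rng) +
        c(rng(1, "norm", sd = jitter_sd), rng(1, "norm", sd = jitter_sd))
      dur <- rng(1, "gamma", shape = fix_shape, scale = fix_scale)
      f_end <- min(t_cur + dur, t_off)
      # saccade into the fixation, then hold
      move_to(f_end, tgt)
      truth_start[length(truth_start) + 1] <- t_cur
      truth_end[length(truth_end) + 1] <- f_end
      truth_side[length(truth_side) + 1] <- side
      truth_trial[length(truth_trial) + 1] <- sc$trial_id
      if (first) {
        ff_trial[length(ff_trial) + 1] <- sc$trial_id
        ff_lat[length(ff_lat) + 1] <- lat
        ff_side[length(ff_side) + 1] <- side
        first <- FALSE
      }
      t_cur <- f_end + sacc
    }
  }
  # trailing centre fixation
  t_total <- max(seg_end) + 1500
  move_to(t_total, c(0, 0))

  # --- sample the timeline at 30 Hz ---------------------------------------
  t_ms <- seq(0, t_total, by = dt)
  k <- findInterval(t_ms, seg_start)
  k[k < 1] <- 1
  span <- pmax(seg_end[k] - seg_start[k], 1e-9)
  a <- pmin(pmax((t_ms - seg_start[k]) / span, 0), 1)
  gx <- seg_x0[k] + a * (seg_x1[k] - seg_x0[k])
  gy <- seg_y0[k] + a * (seg_y1[k] - seg_y0[k])

  n <- length(t_ms)
  noise <- params$binocular_noise_deg
  lx <- gx + rng(n, "norm", sd = noise); ly <- gy + rng(n, "norm", sd = noise)
  rx <- gx + rng(n, "norm", sd = noise); ry <- gy + rng(n, "norm", sd = noise)

  # --- geometric-run tracking dropout (shared between eyes) ---------------
  valid <- rep(TRUE, n)
  if (p_valid_i < 1) {
    p_u <- params$dropout_run_geometric_p
    m_u <- 1 / p_u
    m_t <- m_u * p_valid_i / (1 - p_valid_i)
    p_t <- 1 / max(m_t, 1)
    # draw alternating run lengths until the stream is covered
    need <- n
    runs_t <- 1 + rng(ceiling(need / (m_t + m_u)) * 2 + 20, "geom", prob = p_t)
    runs_u <- 1 + rng(length(runs_t), "geom", prob = p_u)
    lens <- as.vector(rbind(runs_t, runs_u))
    while (sum(lens) < n) {
      extra_t <- 1 + rng(20, "geom", prob = p_t)
      extra_u <- 1 + rng(20, "geom", prob = p_u)
      lens <- c(lens, as.vector(rbind(extra_t, extra_u)))
    }
    flags <- rep(rep(c(TRUE, FALSE), length.out = length(lens)), times = lens)
    valid <- flags[seq_len(n)]
  }
  px <- pixels_per_degree(geometry)
  to_px_x <- function(d) geometry$width_px / 2 + d * px
  to_px_y <- function(d) geometry$height_px / 2 - d * px
  samples <- data.frame(
    t_ms = t_ms,
    lx_px = ifelse(valid, to_px_x(lx), NA_real_),
    ly_px = ifelse(valid, to_px_y(ly), NA_real_),
    rx_px = ifelse(valid, to_px_x(rx), NA_real_),
    ry_px = ifelse(valid, to_px_y(ry), NA_real_),
    l_valid = valid, r_valid = valid
  )
  structure(
    list(participant_id = profile$participant_id, sample_rate_hz = 30,
         samples = samples,
         truth = list(
           fixations = data.frame(start_ms = truth_start, end_ms = truth_end,
                                  side = truth_side, trial_id = truth_trial),
           first_fix = data.frame(trial_id = ff_trial, latency_ms = ff_lat,
                                  side = ff_side),
           p_bio = p_bio_i, p_valid = p_valid_i,
           latency_mean_ms = lat_mean_i),
         seed = seed),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> '%s': %d samples @ %g Hz (%.1f%% tracked)\n",
              x$participant_id, nrow(x$samples), x$sample_rate_hz,
              100 * mean(x$samples$l_valid | x$samples$r_valid)))
  invisible(x)
}

#' Cohort configuration
#'
#' Group sizes and generator presets for a simulated two-group cohort:
#' 121 ASD-like and 40 TD-like participants by default, with covariate
#' distributions matched to the reference cohort (ASD-like: mean age 14.6 y,
#' 76% male, IQ composite mean 98.5, SD 20, range 60-136; TD-like: mean age
#' 16.4 y, 65% male) and 29 opaque symptom subscale scores per ASD-like
#' participant.
#'
#' @param n_asd,n_td Group sizes (non-negative).
#' @param asd_params,td_params [gaze_model_params()] presets per group.
#' @param trial_config A [trial_set_config()] shared by all participants.
#' @param seed Master seed; per-participant seeds derive from it via
#'   [derive_seed()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_asd = 121, n_td = 40,
                          asd_params = asd_model_params(),
                          td_params = td_model_params(),
                          trial_config = trial_set_config(), seed = 1) {
  stopifnot(n_asd >= 0, n_td >= 0,
            inherits(asd_params, "gaze_model_params"),
            inherits(td_params, "gaze_model_params"))
  structure(
    list(n_asd = n_asd, n_td = n_td, asd_params = asd_params,
         td_params = td_params, trial_config = trial_config, seed = seed),
    class = "cohort_config"
  )
}

#' Simulate a two-group cohort
#'
#' Samples participant profiles (age, gender, IQ and symptom scores for the
#' ASD-like group) and one gaze recording per participant over a shared
#' trial set. Per-participant seeds derive from the master seed by the
#' counter-based rule of [derive_seed()].
#'
#' @param config A [cohort_config()].
#' @param trial_set Optional pre-built [make_trial_set()]; when `NULL`, one
#'   is built from `config$trial_config`.
#' @param geometry A [screen_geometry()].
#' @return A list with `participants` (data.frame: `participant_id`,
#'   `group`, `age`, `gender`, `iq`), `symptom_scores` (data.frame, ASD-like
#'   rows x 29 subscale columns keyed per [symptom_subscales()]),
#'   `recordings` (named list of `gaze_recording`), and `trial_set`.
#' @export
simulate_cohort <- function(config = cohort_config(), trial_set = NULL,
                            geometry = screen_geometry()) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(trial_set)) {
    # the trial config's own seed governs the stimulus set, so the same
    # stimuli can be rebuilt independently of the cohort seed
    tc <- config$trial_config
    trial_set <- make_trial_set(tc, generate_walker(seed = tc$seed),
                                geometry = geometry)
  }
  rng <- .local_rng(derive_seed(config$seed, 999983))
  subs <- symptom_subscales()$key

  n_total <- config$n_asd + config$n_td
  ids <- sprintf("P%03d", seq_len(n_total))
  groups <- c(rep("ASD-like", config$n_asd), rep("TD-like", config$n_td))
  profiles <- vector("list", n_total)
  scores <- list()
  for (i in seq_len(n_total)) {
    asd <- groups[i] == "ASD-like"
    age <- if (asd) 6 + rng(1, "gamma", shape = 2.2, scale = 3.9)
           else 6 + rng(1, "gamma", shape = 1.35, scale = 7.7)
    gender <- if (rng(1, "unif") < (if (asd) 0.76 else 0.65)) "male" else "female"
    iq <- if (asd) round(.truncnorm1(rng, 98.5, 20, 60, 136)) else NA_real_
    sy <- NULL
    if (asd) {
      sy <- round(rng(length(subs), "norm", mean = 55, sd = 10), 1)
      names(sy) <- subs
      scores[[ids[i]]] <- sy
    }
    profiles[[i]] <- participant_profile(ids[i], groups[i], age = age,
                                         gender = gender, iq = iq,
                                         symptom_scores = sy)
  }
  recordings <- vector("list", n_total)
  names(recordings) <- ids
  for (i in seq_len(n_total)) {
    params <- if (groups[i] == "ASD-like") config$asd_params else config$td_params
    recordings[[i]] <- simulate_participant(profiles[[i]], trial_set, params,
                                            geometry = geometry,
                                            seed = derive_seed(config$seed, i))
  }
  participants <- data.frame(
    participant_id = ids, group = groups,
    age = vapply(profiles, `[[`, numeric(1), "age"),
    gender = vapply(profiles, `[[`, character(1), "gender"),
    iq = vapply(profiles, `[[`, numeric(1), "iq")
  )
  symptom_scores <- if (length(scores)) {
    df <- as.data.frame(do.call(rbind, scores))
    cbind(data.frame(participant_id = names(scores)), df)
  } else {
    df <- as.data.frame(matrix(numeric(0), 0, length(subs),
                               dimnames = list(NULL, subs)))
    cbind(data.frame(participant_id = character(0)), df)
  }
  rownames(symptom_scores) <- NULL
  list(participants = participants, symptom_scores = symptom_scores,
       recordings = recordings, trial_set = trial_set)
}
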