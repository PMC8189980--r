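# a hand-built scene: two 2-dot clips at given x-offsets, constant dots
manual_scene <- function(lx, rx, bio_side = "left", onset = 0,
                         duration_frames = 480, g = screen_geometry()) {
  mk <- function(xc, cond) point_light_clip(
    paste0("c", xc), 120, matrix(xc, duration_frames, 2),
    matrix(0, duration_frames, 2), cond)
  structure(
    list(trial_id = "m1", block = 1,
         left_clip = mk(lx, if (bio_side == "left") "biological" else "rotational"),
         right_clip = mk(rx, if (bio_side == "right") "biological" else "rotational"),
         bio_side = bio_side, onset_ms = onset,
         duration_ms = duration_frames / 120 * 1000,
         offset_deg = (rx - lx) / 2, geometry = g),
    class = "scene_clip")
}

manual_trial_set <- function(scene, g = screen_geometry()) {
  structure(list(scenes = list(scene), geometry = g,
                 config = trial_set_config(n_trials = 1, n_blocks = 1),
                 period_ms = 833),
            class = "trial_set")
}

test_that("ROI membership agrees with a brute-force distance scan", {
  ts <- small_trial_set(n_trials = 2, seed = 7)
  sc <- ts$scenes[[1]]
  g <- ts$geometry
  ppd <- pixels_per_degree(g)
  t_probe <- sc$onset_ms + 757  # arbitrary time inside the window
  f <- floor(757 * 120 / 1000) + 1
  dots_px <- function(clip) cbind(g$width_px / 2 + clip$x[f, ] * ppd,
                                  g$height_px / 2 - clip$y[f, ] * ppd)
  bio <- if (sc$bio_side == "left") sc$left_clip else sc$right_clip
  ctl <- if (sc$bio_side == "left") sc$right_clip else sc$left_clip
  db <- dots_px(bio); dc <- dots_px(ctl)
  # random probes across the screen plus probes near dots
  set.seed(41)
  probes <- rbind(cbind(runif(200, 0, g$width_px), runif(200, 0, g$height_px)),
                  db + 0.2 * ppd, dc - 0.2 * ppd)
  oracle <- apply(probes, 1, function(p) {
    d2b <- min((db[, 1] - p[1])^2 + (db[, 2] - p[2])^2)
    d2c <- min((dc[, 1] - p[1])^2 + (dc[, 2] - p[2])^2)
    r2 <- (3.7 * ppd)^2
    if (d2b > r2 && d2c > r2) "neither"
    else if (d2b <= r2 && (d2c > r2 || d2b <= d2c)) "bio"
    else "nonbio"
  })
  got <- roi_membership(sc, rep(t_probe, nrow(probes)), probes[, 1],
                        probes[, 2], g)
  expect_equal(got, unname(oracle))
  # exactly on a biological dot
  expect_equal(roi_membership(sc, t_probe, db[1, 1], db[1, 2], g), "bio")
  # outside the presentation window
  expect_equal(roi_membership(sc, sc$onset_ms - 1, db[1, 1], db[1, 2], g),
               "neither")
})

test_that("3.6 degrees is inside the circle, 3.8 is outside, ties go to the nearest dot", {
  g <- screen_geometry()
  ppd <- pixels_per_degree(g)
  sc <- manual_scene(-12, 12)
  bx <- g$width_px / 2 - 12 * ppd  # biological dot x in px
  cy <- g$height_px / 2
  expect_equal(roi_membership(sc, 100, bx + 3.6 * ppd, cy, g), "bio")
  expect_equal(roi_membership(sc, 100, bx + 3.8 * ppd, cy, g), "neither")
  # overlapping ROIs: nearest dot wins
  sc2 <- manual_scene(-1, 1)
  mid <- g$width_px / 2
  expect_equal(roi_membership(sc2, 100, mid - 0.1 * ppd, cy, g), "bio")
  expect_equal(roi_membership(sc2, 100, mid + 0.1 * ppd, cy, g), "nonbio")
  expect_equal(roi_membership(sc2, 100, mid, cy, g), "bio")  # exact tie
})

test_that("total valid time counts tracked on-screen samples in trial windows", {
  g <- screen_geometry()
  dt <- 1000 / 30
  n <- 120
  sc <- manual_scene(-12, 12, duration_frames = 480)
  ts <- manual_trial_set(sc)
  # lossless on-screen recording inside the window
  rec <- manual_recording((0:(n - 1)) * dt, rep(900, n), rep(500, n))
  expect_equal(total_valid_time(rec, ts, g), 100)
  # alternating valid/invalid
  rec2 <- manual_recording((0:(n - 1)) * dt, rep(900, n), rep(500, n),
                           valid = rep(c(TRUE, FALSE), n / 2))
  expect_equal(total_valid_time(rec2, ts, g), 50)
})

test_that("one-sided looking yields 100% preference", {
  g <- screen_geometry()
  ppd <- pixels_per_degree(g)
  dt <- 1000 / 30
  sc <- manual_scene(-12, 12)
  ts <- manual_trial_set(sc)
  bx <- g$width_px / 2 - 12 * ppd
  n <- 60
  rec <- manual_recording((0:(n - 1)) * dt, rep(bx, n), rep(g$height_px / 2, n))
  fx <- data.frame(start_ms = 0, end_ms = n * dt, x_px = bx,
                   y_px = g$height_px / 2, n_tracked = n, trial_id = "m1")
  expect_equal(preference_biological(fx, rec, ts), 100)
  # no on-ROI time: undefined flag
  rec0 <- manual_recording((0:9) * dt, rep(g$width_px / 2, 10),
                           rep(g$height_px / 2, 10))
  fx0 <- data.frame(start_ms = 0, end_ms = 10 * dt, x_px = 0, y_px = 0,
                    n_tracked = 10, trial_id = "m1")
  expect_true(is.na(preference_biological(fx0, rec0, ts)))
})

test_that("first-fixation metrics follow the two-trial hand fixture", {
  ts <- small_trial_set(n_trials = 2, seed = 9)
  g <- ts$geometry
  ppd <- pixels_per_degree(g)
  man <- trial_manifest(ts)
  dt <- 1000 / 30
  dot_px <- function(scene, side, t_ms) {
    clip <- if ((side == "bio") == (scene$bio_side == "left"))
      scene$left_clip else scene$right_clip
    f <- floor((t_ms - scene$onset_ms) * 120 / 1000) + 1
    c(g$width_px / 2 + clip$x[f, 1] * ppd, g$height_px / 2 - clip$y[f, 1] * ppd)
  }
  # trial 1: fixation on bio starting 500 ms after onset
  # trial 2: fixation only on nonbio starting 700 ms after onset
  s1 <- ts$scenes[[1]]; s2 <- ts$scenes[[2]]
  p1 <- dot_px(s1, "bio", s1$onset_ms + 500)
  p2 <- dot_px(s2, "nonbio", s2$onset_ms + 700)
  t1 <- s1$onset_ms + 500 + (0:14) * dt
  t2 <- s2$onset_ms + 700 + (0:14) * dt
  rec <- manual_recording(c(t1, t2), c(rep(p1[1], 15), rep(p2[1], 15)),
                          c(rep(p1[2], 15), rep(p2[2], 15)))
  fx <- data.frame(start_ms = c(t1[1], t2[1]),
                   end_ms = c(t1[15] + dt, t2[15] + dt),
                   x_px = c(p1[1], p2[1]), y_px = c(p1[2], p2[2]),
                   n_tracked = 15, trial_id = man$trial_id)
  ff <- first_fixation_metrics(fx, rec, ts)
  expect_equal(ff$first_fix_bio_pct, 50)
  expect_equal(ff$latency_bio_ms, 500)
  expect_equal(ff$latency_nonbio_ms, 700)
  expect_equal(ff$n_trials_bio, 1)
  expect_equal(ff$n_trials_nonbio, 1)
})

test_that("all four metrics are invariant under a left-right mirror", {
  ts <- small_trial_set(n_trials = 6, seed = 15)
  g <- ts$geometry
  prof <- participant_profile("P1", "ASD-like", age = 11, gender = "male",
                              iq = 100)
  rec <- simulate_participant(prof, ts, asd_model_params(), seed = 19)
  mirror_ts <- ts
  mirror_ts$scenes <- lapply(ts$scenes, function(s) {
    ml <- s$right_clip; mr <- s$left_clip
    ml$x <- -ml$x; mr$x <- -mr$x
    s$left_clip <- ml; s$right_clip <- mr
    s$bio_side <- if (s$bio_side == "left") "right" else "left"
    s
  })
  mirror_rec <- rec
  mirror_rec$samples$lx_px <- g$width_px - rec$samples$lx_px
  mirror_rec$samples$rx_px <- g$width_px - rec$samples$rx_px
  m1 <- participant_metrics(rec, ts)
  m2 <- participant_metrics(mirror_rec, mirror_ts)
  for (col in c("total_valid_pct", "preference_bio_pct", "first_fix_bio_pct",
                "latency_bio_ms", "latency_nonbio_ms"))
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-6)
})

test_that("metrics survive a degree/pixel round trip", {
  ts <- small_trial_set(n_trials = 4, seed = 16)
  g <- ts$geometry
  prof <- participant_profile("P1", "TD-like", age = 11, gender = "male")
  rec <- simulate_participant(prof, ts, td_model_params(), seed = 23)
  rt <- rec
  for (col in c("lx_px", "ly_px", "rx_px", "ry_px"))
    rt$samples[[col]] <- degrees_to_pixels(
      pixels_to_degrees(rec$samples[[col]], g), g)
  m1 <- participant_metrics(rec, ts)
  m2 <- participant_metrics(rt, ts)
  for (col in names(m1)[-1])
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-6)
})

test_that("measured first-look latency tracks the generator truth", {
  ts <- small_trial_set(n_trials = 10, seed = 25)
  prof <- participant_profile("P1", "TD-like", age = 11, gender = "male")
  # near-exclusive biological looking makes the biological first-fix
  # latency coincide with the trial's true first-fixation latency
  params <- td_model_params(p_bio = 0.98, p_bio_between_sd = 0,
                            latency_between_sd_ms = 0)
  rec <- simulate_participant(prof, ts, params, seed = 27)
  m <- participant_metrics(rec, ts)
  truth_mean <- mean(rec$truth$first_fix$latency_ms)
  expect_lt(abs(m$latency_bio_ms - truth_mean), 2.5 * 1000 / 30)
})
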