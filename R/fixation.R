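#' Fixation-detection parameters
#'
#' The two count rules (minimum tracked samples in a fixation, maximum
#' consecutive untracked samples bridged inside one) both default to three.
#' The velocity cutoff is adaptive per individual and per eye: iterated
#' mean + `threshold_k` * SD of sub-cutoff speeds.
#'
#' @param min_tracked_samples Minimum tracked samples per fixation (>= 1).
#' @param max_consecutive_untracked Maximum internal untracked run (>= 0).
#' @param threshold_k Multiplier for the adaptive velocity cutoff.
#' @param convergence_tol Relative cutoff change at which iteration stops.
#' @return An object of class `fixation_params`.
#' @export
fixation_params <- function(min_tracked_samples = 3,
                            max_consecutive_untracked = 3,
                            threshold_k = 3, convergence_tol = 1e-3) {
  stopifnot(min_tracked_samples >= 1, max_consecutive_untracked >= 0,
            threshold_k > 0, convergence_tol > 0)
  structure(
    list(min_tracked_samples = min_tracked_samples,
         max_consecutive_untracked = max_consecutive_untracked,
         threshold_k = threshold_k, convergence_tol = convergence_tol),
    class = "fixation_params"
  )
}

#' Per-eye angular speed series
#'
#' Speed between consecutive samples in degrees per second, per eye.
#' Element `i` is the speed over the interval from sample `i - 1` to sample
#' `i`; element 1 and any pair spanning an untracked sample are `NA`
#' (velocity is never interpolated across gaps).
#'
#' @param recording A `gaze_recording` (or any list with a `samples`
#'   data.frame in the documented column layout).
#' @param geometry A [screen_geometry()].
#' @return A list with numeric vectors `left` and `right`, each as long as
#'   the sample stream.
#' @export
sample_velocities <- function(recording, geometry = screen_geometry()) {
  s <- recording$samples
  n <- nrow(s)
  if (n < 2) stop("insufficient data: need at least 2 samples")
  ppd <- pixels_per_degree(geometry)
  dt_s <- diff(s$t_ms) / 1000
  speed <- function(x, y, valid) {
    d <- sqrt(diff(x)^2 + diff(y)^2) / ppd / dt_s
    d[!(valid[-n] & valid[-1])] <- NA_real_
    c(NA_real_, d)
  }
  list(left = speed(s$lx_px, s$ly_px, s$l_valid),
       right = speed(s$rx_px, s$ry_px, s$r_valid))
}

#' Adaptive velocity cutoff
#'
#' Iterates `cutoff <- mean + k * SD` of the speeds below the current
#' cutoff, starting from all defined speeds, until the relative change
#' falls below `convergence_tol`. Undefined (`NA`) entries are excluded and
#' never affect the result. Fixational (slow) samples dominate a gaze
#' stream, so the iteration settles between the fixation and saccade speed
#' modes.
#'
#' @param speeds Numeric vector of angular speeds (deg/s), `NA` = undefined.
#' @param threshold_k SD multiplier.
#' @param convergence_tol Relative change stopping rule.
#' @return The converged cutoff in deg/s.
#' @export
estimate_threshold <- function(speeds, threshold_k = 3, convergence_tol = 1e-3) {
  v <- speeds[!is.na(speeds)]
  if (length(v) < 1) stop("insufficient data: all speeds undefined")
  cutoff <- Inf
  for (iter in 1:200) {
    sel <- v[v <= cutoff]
    if (length(sel) < 1) break
    s <- stats::sd(sel)
    if (is.na(s)) s <- 0
    new_cutoff <- mean(sel) + threshold_k * s
    if (is.finite(cutoff) &&
        abs(new_cutoff - cutoff) <= convergence_tol * cutoff) {
      cutoff <- new_cutoff
      break
    }
    cutoff <- new_cutoff
  }
  cutoff
}

#' Detect fixations from a binocular recording
#'
#' A sample is fixational iff both eyes' local speeds are defined and below
#' their per-eye adaptive cutoffs (binocular AND). A sample's local speed is
#' the speed over the interval arriving at it (backward difference), so the
#' landing sample of a saccade is never counted as fixational and gaze
#' shifts reliably split runs; where the backward difference is undefined
#' (the previous sample was untracked) the forward difference stands in, so
#' samples just after a tracked gap can rejoin a run. Maximal fixational
#' runs are kept, tolerating internal untracked runs of at most
#' `max_consecutive_untracked` samples; runs with fewer than
#' `min_tracked_samples` tracked samples are discarded. The centroid is the
#' mean of the tracked cyclopean (two-eye average) positions; untracked
#' samples bridge a fixation but contribute no position and no looking time.
#'
#' @param recording A `gaze_recording`.
#' @param geometry A [screen_geometry()].
#' @param params A [fixation_params()].
#' @param trial_set Optional [make_trial_set()]; when given, each fixation
#'   is assigned to the trial window it overlaps most (`NA` if none).
#' @return A data.frame with one row per fixation: `start_ms`, `end_ms`,
#'   `x_px`, `y_px`, `n_tracked`, `trial_id`.
#' @export
detect_fixations <- function(recording, geometry = screen_geometry(),
                             params = fixation_params(), trial_set = NULL) {
  s <- recording$samples
  n <- nrow(s)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      n_tracked = integer(0), trial_id = character(0))
  if (n == 0) return(empty)
  tracked <- s$l_valid & s$r_valid
  if (!any(tracked) || n < 2) return(empty)

  vel <- sample_velocities(recording, geometry)
  thr_l <- estimate_threshold(vel$left, params$threshold_k, params$convergence_tol)
  thr_r <- estimate_threshold(vel$right, params$threshold_k, params$convergence_tol)

  # backward-difference speed; across untracked gaps (backward undefined)
  # fall back to the forward difference so post-gap samples can rejoin a run
  local_speed <- function(v) {
    fwd <- c(v[-1], NA_real_)
    ifelse(is.na(v), fwd, v)
  }
  ls_l <- local_speed(vel$left)
  ls_r <- local_speed(vel$right)
  fixational <- tracked & !is.na(ls_l) & !is.na(ls_r) &
    ls_l <= thr_l & ls_r <= thr_r

  # states: 2 = fixational, 1 = untracked (bridgeable), 0 = tracked non-fix
  state <- ifelse(fixational, 2L, ifelse(tracked, 0L, 1L))
  r <- rle(state)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L

  fix_start <- integer(0); fix_end <- integer(0)
  i <- 1L
  n_runs <- length(r$values)
  while (i <= n_runs) {
    if (r$values[i] == 2L) {
      a <- run_start[i]; b <- run_end[i]
      j <- i + 1L
      # extend across short untracked runs followed by more fixational samples
      while (j + 1L <= n_runs && r$values[j] == 1L &&
             r$lengths[j] <= params$max_consecutive_untracked &&
             r$values[j + 1L] == 2L) {
        b <- run_end[j + 1L]
        j <- j + 2L
      }
      fix_start <- c(fix_start, a); fix_end <- c(fix_end, b)
      i <- j
    } else i <- i + 1L
  }
  if (length(fix_start) == 0) return(empty)

  dt <- if (n >= 2) stats::median(diff(s$t_ms)) else 1000 / 30
  cx <- (s$lx_px + s$rx_px) / 2
  cy <- (s$ly_px + s$ry_px) / 2
  # prefix sums over tracked samples give centroids in O(1) per fixation
  csn <- cumsum(tracked)
  csx <- cumsum(ifelse(tracked, cx, 0))
  csy <- cumsum(ifelse(tracked, cy, 0))
  at <- function(cs, i) ifelse(i >= 1, cs[pmax(i, 1)], 0)
  n_tr <- csn[fix_end] - at(csn, fix_start - 1L)
  out <- data.frame(
    start_ms = s$t_ms[fix_start],
    end_ms = s$t_ms[fix_end] + dt,
    x_px = (csx[fix_end] - at(csx, fix_start - 1L)) / n_tr,
    y_px = (csy[fix_end] - at(csy, fix_start - 1L)) / n_tr,
    n_tracked = as.integer(n_tr)
  )
  out <- out[out$n_tracked >= params$min_tracked_samples, , drop = FALSE]
  rownames(out) <- NULL

  out$trial_id <- rep(NA_character_, nrow(out))
  if (!is.null(trial_set) && nrow(out) > 0) {
    man <- trial_manifest(trial_set)
    ov <- outer(seq_len(nrow(out)), seq_len(nrow(man)), function(i, j) {
      pmax(0, pmin(out$end_ms[i], man$onset_ms[j] + man$duration_ms[j]) -
              pmax(out$start_ms[i], man$onset_ms[j]))
    })
    best <- max.col(ov, ties.method = "first")
    hit <- ov[cbind(seq_len(nrow(out)), best)] > 0
    out$trial_id[hit] <- man$trial_id[best[hit]]
  }
  out
}
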