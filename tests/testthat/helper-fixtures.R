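# Shared fixtures, built in code at test time.

ref_walker <- function(seed = 1) generate_walker(4, 120, 100, 15, seed = seed)

small_trial_set <- function(n_trials = 10, seed = 3, ...) {
  make_trial_set(trial_set_config(n_trials = n_trials, n_blocks = 2,
                                  seed = seed, ...),
                 ref_walker(), screen_geometry())
}

# a hand-built recording: positions in px, explicit validity
manual_recording <- function(t_ms, x_px, y_px, valid = rep(TRUE, length(t_ms)),
                             id = "M1") {
  structure(
    list(participant_id = id, sample_rate_hz = 30,
         samples = data.frame(
           t_ms = t_ms,
           lx_px = ifelse(valid, x_px, NA_real_),
           ly_px = ifelse(valid, y_px, NA_real_),
           rx_px = ifelse(valid, x_px, NA_real_),
           ry_px = ifelse(valid, y_px, NA_real_),
           l_valid = valid, r_valid = valid),
         truth = NULL),
    class = "gaze_recording")
}

# recall of detected fixations against the generator truth log,
# restricted to true fixations of at least min_samples sample intervals
truth_recall <- function(recording, fixations, min_samples = 4) {
  tr <- recording$truth$fixations
  dt <- 1000 / 30
  long <- tr[tr$end_ms - tr$start_ms >= min_samples * dt, , drop = FALSE]
  if (nrow(long) == 0) return(NA_real_)
  hits <- vapply(seq_len(nrow(long)), function(i) {
    any(pmin(fixations$end_ms, long$end_ms[i]) -
          pmax(fixations$start_ms, long$start_ms[i]) > 0)
  }, logical(1))
  mean(hits)
}

# exact two-sided signed-rank p by enumeration of all sign assignments
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
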