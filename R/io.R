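#' @importFrom jsonlite toJSON fromJSON write_json read_json
NULL

.gaze_cols <- c("participant_id", "trial_id", "t_ms", "lx_px", "ly_px",
                "rx_px", "ry_px", "l_valid", "r_valid")

# small polynomial rolling hash for config fingerprints in output metadata
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.tool_meta <- function(seed, config = NULL) {
  list(tool = "plightgaze",
       version = as.character(utils::packageVersion("plightgaze")),
       seed = seed, config_hash = .config_hash(config))
}

#' Write gaze recordings to a delimited file
#'
#' Long-format CSV with the exact column set `participant_id, trial_id,
#' t_ms, lx_px, ly_px, rx_px, ry_px, l_valid, r_valid`; samples outside all
#' trial windows carry an empty `trial_id`. A JSON sidecar (`<path>.meta.json`)
#' records the tool version and seed.
#'
#' @param recordings A `gaze_recording` or list of them.
#' @param path Output CSV path.
#' @param trial_set A [make_trial_set()] used to label samples with trials.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(recordings, path, trial_set) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  man <- trial_manifest(trial_set)
  rows <- lapply(recordings, function(r) {
    s <- r$samples
    tid <- rep("", nrow(s))
    for (i in seq_len(nrow(man))) {
      in_w <- s$t_ms >= man$onset_ms[i] &
        s$t_ms < man$onset_ms[i] + man$duration_ms[i]
      tid[in_w] <- man$trial_id[i]
    }
    cbind(data.frame(participant_id = r$participant_id, trial_id = tid), s)
  })
  out <- do.call(rbind, rows)[, .gaze_cols]
  # 17 significant digits make the numeric round trip exact, so detection
  # on a re-read file reproduces in-memory results bit for bit
  for (col in c("t_ms", "lx_px", "ly_px", "rx_px", "ry_px")) {
    v <- sprintf("%.17g", out[[col]])
    v[is.na(out[[col]])] <- "NA"
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  seeds <- vapply(recordings, function(r) as.numeric(r$seed %||% NA), numeric(1))
  jsonlite::write_json(.tool_meta(seeds, trial_set$config),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gaze recordings from a delimited file
#'
#' Strict reader: the header must match the documented column set exactly
#' (same names, same order), and timestamps must be strictly increasing
#' within each participant; violations raise an error naming the first
#' offending row.
#'
#' @param path CSV path written by [write_gaze()].
#' @return A named list of `gaze_recording` objects (without truth logs).
#' @export
read_gaze <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(header, .gaze_cols))
    stop("parse error: expected columns [", paste(.gaze_cols, collapse = ", "),
         "] but found [", paste(header, collapse = ", "), "]")
  d <- utils::read.csv(path, colClasses = c("character", "character",
                                            rep("numeric", 5),
                                            rep("logical", 2)))
  out <- list()
  for (pid in unique(d$participant_id)) {
    s <- d[d$participant_id == pid, ]
    bad <- which(diff(s$t_ms) <= 0)
    if (length(bad))
      stop("validation error: non-increasing timestamp for participant ",
           pid, " at row ", which(d$participant_id == pid)[bad[1] + 1],
           " of ", path)
    out[[pid]] <- structure(
      list(participant_id = pid, sample_rate_hz = 30,
           samples = s[, setdiff(names(s), c("participant_id", "trial_id"))],
           truth = NULL),
      class = "gaze_recording")
  }
  out
}

#' Write / read a participant metrics table
#'
#' One row per participant; the metric columns are named exactly
#' `total_valid_pct, preference_bio_pct, first_fix_bio_pct, latency_bio_ms,
#' latency_nonbio_ms`.
#'
#' @param metrics A [cohort_metrics()] table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "total_valid_pct", "preference_bio_pct",
            "first_fix_bio_pct", "latency_bio_ms", "latency_nonbio_ms")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("parse error: metrics file lacks columns: ",
         paste(miss, collapse = ", "))
  d
}

#' Write a trial manifest as JSON
#'
#' @param trial_set A [make_trial_set()].
#' @param path JSON path.
#' @export
write_manifest <- function(trial_set, path) {
  jsonlite::write_json(
    list(meta = .tool_meta(trial_set$config$seed, trial_set$config),
         trials = trial_manifest(trial_set)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)$trials
}

#' Write the statistical report as JSON
#'
#' @param report A [run_full_battery()] result.
#' @param path JSON path.
#' @param seed Seed recorded in the metadata block.
#' @export
write_report <- function(report, path, seed = NA) {
  payload <- unclass(report)
  payload$meta <- .tool_meta(seed, report$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' End-to-end run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param cohort A [cohort_config()].
#' @param fix_params A [fixation_params()].
#' @param roi A [roi_config()].
#' @param stats A [stats_config()].
#' @param geometry A [screen_geometry()].
#' @param seed Master seed; overrides `cohort$seed`.
#' @param write_gaze_files Whether to write the (large) per-sample gaze CSV.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, cohort = cohort_config(),
                       fix_params = fixation_params(), roi = roi_config(),
                       stats = stats_config(), geometry = screen_geometry(),
                       seed = cohort$seed, write_gaze_files = FALSE) {
  structure(
    list(out_dir = out_dir, cohort = cohort, fix_params = fix_params,
         roi = roi, stats = stats, geometry = geometry, seed = seed,
         write_gaze_files = write_gaze_files),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Simulate a cohort, detect fixations, compute the per-participant metrics
#' and run the statistical battery, writing every artifact under
#' `config$out_dir`: `trials.json`, `participants.csv`,
#' `symptom_scores.csv`, `metrics.csv`, `report.json` (and `gaze.csv` when
#' requested). Bit-identical outputs under a fixed seed.
#'
#' @param config A [run_config()].
#' @return The report path, invisibly; the report itself as attribute
#'   `"report"`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  cc <- config$cohort
  cc$seed <- config$seed
  cohort <- stage("simulate", simulate_cohort(cc, geometry = config$geometry))
  stage("manifest", write_manifest(cohort$trial_set,
                                   file.path(config$out_dir, "trials.json")))
  utils::write.csv(cohort$participants,
                   file.path(config$out_dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$symptom_scores,
                   file.path(config$out_dir, "symptom_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  if (config$write_gaze_files)
    stage("gaze", write_gaze(cohort$recordings,
                             file.path(config$out_dir, "gaze.csv"),
                             cohort$trial_set))
  metrics <- stage("metrics", cohort_metrics(cohort, config$fix_params,
                                             config$roi))
  write_metrics(metrics, file.path(config$out_dir, "metrics.csv"))
  report <- stage("stats", run_full_battery(metrics, cohort$participants,
                                            cohort$symptom_scores,
                                            config$stats))
  path <- file.path(config$out_dir, "report.json")
  write_report(report, path, seed = config$seed)
  out <- invisible(path)
  attr(out, "report") <- report
  out
}
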