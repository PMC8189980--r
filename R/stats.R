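#' Configuration of the statistical battery
#'
#' @param covariates Covariates entering the group ANCOVAs.
#' @param fdr_level False-discovery-rate level for the Benjamini-Hochberg
#'   adjustment of the primary group tests.
#' @param n_primary_tests Number of primary group comparisons adjusted
#'   together (one per eye-movement metric).
#' @param chance_level_pct Chance level for the preference and
#'   first-fixation tests (equal looking at both stimuli).
#' @param iq_strata Named list of closed IQ intervals.
#' @param severity_levels Ordered severity labels for the tertile split.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(covariates = c("age", "gender"), fdr_level = 0.05,
                         n_primary_tests = 5, chance_level_pct = 50,
                         iq_strata = list(low = c(60, 84),
                                          normal = c(85, 115),
                                          high = c(116, 136)),
                         severity_levels = c("mild", "moderate", "severe")) {
  stopifnot(fdr_level > 0, fdr_level < 1)
  b <- do.call(rbind, iq_strata)
  if (any(b[, 1] > b[, 2]) || is.unsorted(as.vector(t(b))))
    stop("iq_strata bounds must be ordered and non-overlapping")
  structure(
    list(covariates = covariates, fdr_level = fdr_level,
         n_primary_tests = n_primary_tests,
         chance_level_pct = chance_level_pct, iq_strata = iq_strata,
         severity_levels = severity_levels),
    class = "stats_config"
  )
}

.stat_result <- function(test_name, estimate = NA_real_, statistic = NA_real_,
                         p_raw = NA_real_, n_used = NA_integer_, ...) {
  structure(c(list(test_name = test_name, estimate = estimate,
                   statistic = statistic, p_raw = p_raw,
                   n_used = as.integer(n_used)), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: estimate %.4g, statistic %.4g, p %.3g (n = %d)\n",
              x$test_name, x$estimate, x$statistic, x$p_raw, x$n_used))
  invisible(x)
}

#' Group ANCOVA on one eye-movement metric
#'
#' Least-squares linear model `metric ~ group + age + gender` (no
#' interactions). The group F statistic comes from the partial
#' sum-of-squares of the group term (full model vs. model without group);
#' partial eta-squared is `SS_group / (SS_group + SS_residual)`. Cohen's d
#' is computed from the raw group means and the pooled SD, unadjusted for
#' covariates, with sign second-factor-level minus first.
#'
#' @param metrics_table A data.frame with columns `group`, `age`, `gender`
#'   and the metric; rows with missing values are excluded and counted.
#' @param metric_name Name of the metric column.
#' @param config A [stats_config()].
#' @return A `stat_result` with fields `effect_cohens_d`,
#'   `effect_partial_eta_sq`, `n_excluded`.
#' @export
ancova_group_effect <- function(metrics_table, metric_name,
                                config = stats_config()) {
  need <- c("group", config$covariates, metric_name)
  missing_cols <- setdiff(need, names(metrics_table))
  if (length(missing_cols))
    stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "))
  d <- metrics_table[, need]
  names(d)[ncol(d)] <- ".y"
  cc <- stats::complete.cases(d)
  n_excluded <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  d$group <- factor(d$group)
  if (nlevels(d$group) != 2 || any(table(d$group) < 2))
    stop("need two groups with at least 2 observations each")
  if (stats::var(d$.y) == 0)
    stop("degenerate model: metric '", metric_name, "' is constant")

  rhs <- paste(config$covariates, collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(".y ~ group +", rhs)), data = d)
  reduced <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  ss_res <- sum(stats::residuals(full)^2)
  ss_group <- sum(stats::residuals(reduced)^2) - ss_res
  df_group <- reduced$df.residual - full$df.residual
  f_stat <- (ss_group / df_group) / (ss_res / full$df.residual)
  p <- stats::pf(f_stat, df_group, full$df.residual, lower.tail = FALSE)

  m <- tapply(d$.y, d$group, mean)
  v <- tapply(d$.y, d$group, stats::var)
  nn <- tapply(d$.y, d$group, length)
  sp <- sqrt(((nn[1] - 1) * v[1] + (nn[2] - 1) * v[2]) / (sum(nn) - 2))
  cohens_d <- unname((m[2] - m[1]) / sp)

  .stat_result(paste0("ancova_group:", metric_name),
               estimate = unname(m[2] - m[1]), statistic = f_stat,
               p_raw = p, n_used = nrow(d),
               effect_cohens_d = cohens_d,
               effect_partial_eta_sq = ss_group / (ss_group + ss_res),
               group_means = as.list(m), n_excluded = n_excluded,
               df = c(df_group, full$df.residual))
}

#' Wilcoxon signed-rank test against a chance level
#'
#' Signed-rank test on `values - chance_level_pct` with zero differences
#' dropped and mid-ranks for ties; two-sided p via the normal approximation
#' with continuity and tie corrections.
#'
#' @param values Numeric vector (e.g. preference percentages).
#' @param chance_level_pct Chance level to test against.
#' @return A `stat_result`; if every value equals chance the result is
#'   flagged degenerate with `p = 1`.
#' @export
wilcoxon_vs_chance <- function(values, chance_level_pct = 50) {
  d <- values[!is.na(values)] - chance_level_pct
  n_all <- length(d)
  if (n_all < 6) stop("need at least 6 non-missing values")
  dz <- d[d != 0]
  if (!length(dz))
    return(.stat_result("wilcoxon_vs_chance", estimate = 0, statistic = NA,
                        p_raw = 1, n_used = n_all, degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(dz, exact = FALSE, correct = TRUE))
  .stat_result("wilcoxon_vs_chance",
               estimate = stats::median(d) + 0,  # median shift from chance
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               n_used = length(dz), degenerate = FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on within-pair differences (e.g. first-fixation
#' latencies on biological vs. non-biological motion), conventions as in
#' [wilcoxon_vs_chance()].
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A `stat_result`.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  cc <- !is.na(a) & !is.na(b)
  d <- a[cc] - b[cc]
  if (length(d) < 6) stop("need at least 6 complete pairs")
  dz <- d[d != 0]
  if (!length(dz))
    return(.stat_result("wilcoxon_paired", estimate = 0, statistic = NA,
                        p_raw = 1, n_used = length(d), degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(dz, exact = FALSE, correct = TRUE))
  .stat_result("wilcoxon_paired", estimate = stats::median(d),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               n_used = length(dz), degenerate = FALSE)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and each covariate, residualizes the ranks of
#' `x` and `y` on the covariate ranks by least squares (with intercept),
#' and correlates the residuals. The p-value uses a t reference
#' distribution on `n - 2 - k` degrees of freedom, `k` the number of
#' covariates. With no covariates this reduces to the ordinary Spearman
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data.frame of covariates; factors/characters
#'   are converted to numeric codes before ranking.
#' @return A `stat_result` with `estimate` the partial rank correlation.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(x))
  covariates <- as.data.frame(covariates)
  num <- lapply(covariates, function(v) {
    if (is.numeric(v)) v else as.numeric(factor(v))
  })
  cc <- stats::complete.cases(data.frame(x = x, y = y, covariates))
  k <- length(num)
  n <- sum(cc)
  if (n < k + 3) stop("need at least ", k + 3, " complete cases")
  rx <- rank(x[cc]); ry <- rank(y[cc])
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(.stat_result("spearman_partial", estimate = NA, p_raw = NA,
                        n_used = n, degenerate = TRUE))
  if (k > 0) {
    Z <- cbind(1, vapply(num, function(v) rank(v[cc]), numeric(n)))
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
    if (stats::var(rx) == 0 || stats::var(ry) == 0)
      return(.stat_result("spearman_partial", estimate = NA, p_raw = NA,
                          n_used = n, degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  .stat_result("spearman_partial", estimate = r, statistic = tt, p_raw = p,
               n_used = n, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param fdr_level FDR level used downstream for significance calls (does
#'   not change the adjusted values).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values, fdr_level = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Severity tertiles
#'
#' Ranks scores (stably: ties broken by input order) and splits them into
#' three similarly-sized, non-overlapping groups. With `n = 3q + r` the
#' group sizes are `q` plus the remainder allocated to the later (more
#' severe) groups, e.g. sizes (40, 40, 41) at n = 121.
#'
#' @param scores Numeric severity scores; `NA` scores get `NA` labels.
#' @param levels Ordered labels for the three groups.
#' @return A factor of the same length as `scores`.
#' @export
severity_tertiles <- function(scores,
                              levels = c("mild", "moderate", "severe")) {
  ok <- which(!is.na(scores))
  n <- length(ok)
  if (n < 3) stop("need at least 3 non-missing scores")
  q <- n %/% 3; r <- n %% 3
  sizes <- q + c(0, if (r == 2) 1 else 0, if (r >= 1) 1 else 0)
  ord <- ok[order(scores[ok], ok)]  # stable: ties break by input position
  lab <- rep(NA_character_, length(scores))
  lab[ord] <- rep(levels, times = sizes)
  factor(lab, levels = levels)
}

#' IQ strata
#'
#' Closed-interval binning of IQ composite scores into low (60-84),
#' average/normal (85-115) and high (116-136) strata.
#'
#' @param iq_values Numeric vector within `[60, 136]`.
#' @param config A [stats_config()] carrying the interval bounds.
#' @return A factor with levels `low`, `normal`, `high`.
#' @export
iq_strata <- function(iq_values, config = stats_config()) {
  if (!length(iq_values))
    return(factor(character(0), levels = names(config$iq_strata)))
  b <- config$iq_strata
  lo <- b[[1]][1]; hi <- b[[length(b)]][2]
  bad <- which(!is.na(iq_values) & (iq_values < lo | iq_values > hi))
  if (length(bad))
    stop("IQ value out of range [", lo, ", ", hi, "]: ", iq_values[bad[1]])
  lab <- rep(NA_character_, length(iq_values))
  for (nm in names(b))
    lab[!is.na(iq_values) & iq_values >= b[[nm]][1] &
          iq_values <= b[[nm]][2]] <- nm
  factor(lab, levels = names(b))
}

#' Retention percentage from enrollment counts
#'
#' @param analyzed,enrolled Participant counts.
#' @return Percentage retained, rounded to one decimal.
#' @export
retention_pct <- function(analyzed, enrolled) {
  stopifnot(enrolled > 0, analyzed >= 0, analyzed <= enrolled)
  round(100 * analyzed / enrolled, 1)
}

#' Reference cohort enrollment bookkeeping
#'
#' Enrollment and analyzed counts of the reference cohort the synthetic
#' defaults emulate: 136 enrolled / 121 analyzed ASD-like, 41 / 40 TD-like
#' (exclusions due to technical or calibration failures).
#'
#' @return A list with `asd_enrolled`, `asd_analyzed`, `td_enrolled`,
#'   `td_analyzed`.
#' @export
reference_enrollment <- function() {
  list(asd_enrolled = 136, asd_analyzed = 121,
       td_enrolled = 41, td_analyzed = 40)
}

#' Parse printed p-value strings
#'
#' Printed p-values such as `"0.02"` or `"<1e-4"` become numeric upper
#' bounds (the `<` prefix is stripped).
#'
#' @param p_chr Character vector.
#' @return Numeric vector.
#' @export
parse_printed_p <- function(p_chr) {
  as.numeric(gsub("^\\s*<\\s*", "", p_chr))
}

#' Count significant cells among printed p-values
#'
#' Applies the significance rule used for printed grids: a cell is
#' significant when its printed p-value (or upper bound) does not exceed
#' `alpha`. Printed values are rounded to two decimals, so a printed 0.05
#' reflects an underlying p below the threshold and counts as significant.
#'
#' @param p_chr Character vector of printed p-values.
#' @param alpha Significance threshold.
#' @return Integer count.
#' @export
count_significant_cells <- function(p_chr, alpha = 0.05) {
  sum(parse_printed_p(p_chr) <= alpha, na.rm = TRUE)
}

#' Significant-cell fraction as a printed percentage
#'
#' @param n_sig,n_total Cell counts.
#' @return Percentage rounded to one decimal (e.g. 5 of 145 gives 3.4).
#' @export
significant_fraction <- function(n_sig, n_total) {
  round(100 * n_sig / n_total, 1)
}

#' Bundled reference severity grid
#'
#' Published mean preference-for-biological-motion values and chance-level
#' test p-values of the reference cohort, for each of the 29 symptom
#' subscales at three severity levels (87 cells). Used to validate the
#' grid bookkeeping (cell counts and the significance rule).
#'
#' @return A data.frame with columns `scale`, `subscale`, `level`, `n`,
#'   `mean_pref`, `p_printed`.
#' @export
published_severity_grid <- function() {
  path <- system.file("extdata", "severity_grid_published.tsv",
                      package = "plightgaze", mustWork = TRUE)
  utils::read.delim(path, colClasses = c(rep("character", 3), "integer",
                                         "numeric", "character"))
}

#' Run the full statistical battery
#'
#' Joins the metrics, participant and symptom tables and produces a single
#' structured report: the five group ANCOVAs with BH adjustment over their
#' p-values, chance-level tests per group, paired latency tests per group,
#' the severity grid (29 symptoms x 3 tertiles of the ASD-like group, each
#' cell a chance-level test of preference), IQ strata sizes with
#' per-stratum group ANCOVAs, and the 5 x 29 partial-correlation grid with
#' age, gender and IQ as covariates.
#'
#' @param metrics_table Output of [cohort_metrics()].
#' @param participant_table Cohort `participants` data.frame.
#' @param symptom_scores Cohort `symptom_scores` data.frame (ASD-like rows).
#' @param config A [stats_config()].
#' @return An object of class `plight_report` (a nested list; see
#'   [write_report()]).
#' @export
run_full_battery <- function(metrics_table, participant_table,
                             symptom_scores, config = stats_config()) {
  tab <- merge(participant_table, metrics_table, by = "participant_id")
  n_unjoined <- nrow(metrics_table) - nrow(tab)
  if (n_unjoined > 0)
    warning(n_unjoined, " metric rows failed to join the participant table")
  metric_cols <- c("total_valid_pct", "preference_bio_pct",
                   "first_fix_bio_pct", "latency_bio_ms", "latency_nonbio_ms")

  res_to_list <- function(r) unclass(r)

  # primary group effects + BH over the five tests
  ge <- lapply(metric_cols, function(mc) ancova_group_effect(tab, mc, config))
  p_adj <- bh_adjust(vapply(ge, `[[`, numeric(1), "p_raw"), config$fdr_level)
  group_effects <- stats::setNames(lapply(seq_along(ge), function(i) {
    out <- res_to_list(ge[[i]]); out$p_adjusted <- p_adj[i]; out
  }), metric_cols)

  # chance-level and paired tests per group
  chance_tests <- list(); paired_latency <- list()
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    chance_tests[[g]] <- list(
      preference_bio_pct = res_to_list(
        wilcoxon_vs_chance(sub$preference_bio_pct, config$chance_level_pct)),
      first_fix_bio_pct = res_to_list(
        wilcoxon_vs_chance(sub$first_fix_bio_pct, config$chance_level_pct)))
    paired_latency[[g]] <- res_to_list(
      wilcoxon_paired(sub$latency_bio_ms, sub$latency_nonbio_ms))
  }

  asd <- tab[grepl("^ASD", tab$group), ]
  sy <- merge(asd[, c("participant_id", "age", "gender", "iq", metric_cols)],
              symptom_scores, by = "participant_id")
  subs <- symptom_subscales()

  # severity grid: 29 symptoms x 3 tertile levels
  severity_grid <- do.call(rbind, lapply(seq_len(nrow(subs)), function(i) {
    key <- subs$key[i]
    sc <- sy[[key]]
    pref <- sy$preference_bio_pct
    keep <- !is.na(sc) & !is.na(pref)
    lev <- severity_tertiles(ifelse(keep, sc, NA), config$severity_levels)
    do.call(rbind, lapply(config$severity_levels, function(lv) {
      v <- pref[!is.na(lev) & lev == lv]
      p <- if (length(v) >= 6)
        wilcoxon_vs_chance(v, config$chance_level_pct)$p_raw else NA_real_
      data.frame(scale = subs$scale[i], subscale = subs$subscale[i],
                 level = lv, n = length(v),
                 mean_pref = if (length(v)) mean(v) else NA_real_,
                 p_raw = p)
    }))
  }))

  # IQ strata: sizes and per-stratum group ANCOVAs against the TD group
  strata <- iq_strata(asd$iq, config)
  iq_section <- list(sizes = as.list(table(strata)))
  td <- tab[!grepl("^ASD", tab$group), ]
  for (lv in levels(strata)) {
    sub <- rbind(asd[!is.na(strata) & strata == lv, names(tab)], td)
    iq_section[[lv]] <- tryCatch(
      stats::setNames(lapply(metric_cols, function(mc)
        res_to_list(ancova_group_effect(sub, mc, config))), metric_cols),
      error = function(e) list(error = conditionMessage(e)))
  }

  # correlation grid: 5 metrics x 29 symptoms, partial Spearman
  covars <- sy[, c("age", "gender", "iq")]
  correlation_grid <- do.call(rbind, lapply(metric_cols, function(mc) {
    do.call(rbind, lapply(seq_len(nrow(subs)), function(i) {
      r <- spearman_partial(sy[[mc]], sy[[subs$key[i]]], covars)
      data.frame(metric = mc, scale = subs$scale[i],
                 subscale = subs$subscale[i], estimate = r$estimate,
                 p_raw = r$p_raw, n = r$n_used)
    }))
  }))

  structure(
    list(group_effects = group_effects, chance_tests = chance_tests,
         paired_latency = paired_latency, severity_grid = severity_grid,
         iq_strata = iq_section, correlation_grid = correlation_grid,
         config = unclass(config), n_unjoined = n_unjoined),
    class = "plight_report"
  )
}

#' @export
print.plight_report <- function(x, ...) {
  cat("<plight_report>\n")
  cat(sprintf("  group effects: %d metrics (BH-adjusted)\n",
              length(x$group_effects)))
  for (nm in names(x$group_effects)) {
    g <- x$group_effects[[nm]]
    cat(sprintf("    %-20s d = %6.2f  eta_p^2 = %5.3f  p_adj = %.3g\n",
                nm, g$effect_cohens_d, g$effect_partial_eta_sq, g$p_adjusted))
  }
  cat(sprintf("  severity grid: %d cells; correlation grid: %d cells\n",
              nrow(x$severity_grid), nrow(x$correlation_grid)))
  invisible(x)
}
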