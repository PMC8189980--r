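test_that("group ANCOVA matches an explicit normal-equations oracle", {
  set.seed(12)
  d <- data.frame(
    group = rep(c("A", "B"), each = 6),
    age = round(runif(12, 6, 40), 1),
    gender = sample(c("male", "female"), 12, replace = TRUE),
    y = round(rnorm(12, 55, 8), 2)
  )
  r <- ancova_group_effect(d, "y")
  # oracle: solve the normal equations by hand for full and reduced models
  g01 <- as.numeric(d$group == "B")
  s01 <- as.numeric(factor(d$gender)) - 1
  Xf <- cbind(1, g01, d$age, s01)
  Xr <- cbind(1, d$age, s01)
  bf <- solve(t(Xf) %*% Xf, t(Xf) %*% d$y)
  br <- solve(t(Xr) %*% Xr, t(Xr) %*% d$y)
  ssf <- sum((d$y - Xf %*% bf)^2)
  ssr <- sum((d$y - Xr %*% br)^2)
  f_oracle <- (ssr - ssf) / (ssf / (12 - 4))
  expect_equal(r$statistic, f_oracle, tolerance = 1e-8)
  expect_equal(r$effect_partial_eta_sq, (ssr - ssf) / (ssr - ssf + ssf),
               tolerance = 1e-8)
  expect_equal(r$p_raw, pf(f_oracle, 1, 8, lower.tail = FALSE),
               tolerance = 1e-8)
  # two-level factor identity: F equals the squared group-coefficient t
  fit <- lm(y ~ group + age + gender, data = d)
  t_g <- summary(fit)$coefficients["groupB", "t value"]
  expect_equal(r$statistic, t_g^2, tolerance = 1e-8)
  # Cohen's d from raw means and pooled SD
  m <- tapply(d$y, d$group, mean); v <- tapply(d$y, d$group, var)
  expect_equal(r$effect_cohens_d,
               unname((m[2] - m[1]) / sqrt((5 * v[1] + 5 * v[2]) / 10)),
               tolerance = 1e-10)
})

test_that("ANCOVA null and degenerate cases behave", {
  d <- data.frame(group = rep(c("A", "B"), each = 10),
                  age = rep(seq(8, 17), 2),
                  gender = rep(c("male", "female"), 10),
                  y = rep(c(1, 2, 3, 4, 5), 4))
  # identical groups: no group effect
  r <- ancova_group_effect(d, "y")
  expect_lt(r$statistic, 1e-10)
  expect_equal(r$effect_cohens_d, 0)
  # constant metric
  d$y <- 5
  expect_error(ancova_group_effect(d, "y"), "degenerate")
  # missing covariates excluded with count
  d2 <- data.frame(group = rep(c("A", "B"), each = 10),
                   age = c(NA, seq(8, 16), seq(8, 17)),
                   gender = rep(c("male", "female"), 10),
                   y = rnorm(20, 50, 5))
  expect_equal(ancova_group_effect(d2, "y")$n_excluded, 1)
})

test_that("signed-rank tests follow their conventions and edge cases", {
  # values exactly symmetric about chance: p near 1
  v <- 50 + c(-5, -4, -3, -2, -1, 1, 2, 3, 4, 5)
  expect_gt(wilcoxon_vs_chance(v)$p_raw, 0.9)
  # all above chance at n = 40: maximal positive-rank sum, strong rejection
  set.seed(3)
  v2 <- 50 + abs(rnorm(40, 5, 2))
  r2 <- wilcoxon_vs_chance(v2)
  expect_equal(r2$statistic, 40 * 41 / 2)
  expect_lt(r2$p_raw, 1e-3)
  # degenerate: everything at chance
  r3 <- wilcoxon_vs_chance(rep(50, 10))
  expect_true(r3$degenerate)
  expect_equal(r3$p_raw, 1)
  expect_error(wilcoxon_vs_chance(c(51, 52, 53)), "at least 6")
  # paired: identical vectors flag degenerate
  a <- c(600, 610, 620, 630, 640, 650)
  rp <- wilcoxon_paired(a, a)
  expect_true(rp$degenerate)
  expect_equal(rp$p_raw, 1)
  expect_error(wilcoxon_paired(a, a[-1]), "equal length")
})

test_that("the normal approximation tracks the exact enumeration for n <= 12", {
  set.seed(7)
  checked <- 0
  for (i in 1:60) {
    n <- sample(8:12, 1)
    d <- round(rnorm(n, 0.3, 1), 2); d <- d[d != 0]
    if (length(d) < 6) next
    pe <- exact_signed_rank_p(d)
    if (pe < 0.05 || pe > 0.95) next  # the approximation targets moderate p
    pa <- wilcoxon_vs_chance(d + 50, 50)$p_raw
    expect_lt(abs(pa - pe) / pe, 0.10)
    checked <- checked + 1
  }
  expect_gte(checked, 30)
})

test_that("paired signed-rank has power under shift and is calibrated under null", {
  # +50 ms shift at n = 40: near-certain rejection
  set.seed(99)
  rejections <- vapply(1:100, function(i) {
    a <- rnorm(40, 600, 100)
    b <- a - 50 + rnorm(40, 0, 50)
    wilcoxon_paired(a, b)$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
  # null calibration: p values uniform on (0, 1)
  set.seed(100)
  ps <- vapply(1:200, function(i)
    wilcoxon_paired(rnorm(40), rnorm(40))$p_raw, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
})

test_that("partial Spearman reduces, detects, and deconfounds correctly", {
  set.seed(5)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  # no covariates: ordinary Spearman
  r0 <- spearman_partial(x, y)
  expect_equal(r0$estimate,
               unname(suppressWarnings(
                 stats::cor.test(x, y, method = "spearman"))$estimate),
               tolerance = 1e-10)
  # monotone relation: correlation approaches 1
  x2 <- rnorm(200); y2 <- exp(x2)
  z2 <- data.frame(a = rnorm(200), b = rnorm(200))
  expect_gt(spearman_partial(x2, y2, z2)$estimate, 0.95)
  # pure confounding: marginal correlation vanishes after adjustment
  z <- rnorm(500)
  xc <- z + rnorm(500); yc <- z + rnorm(500)
  marginal <- spearman_partial(xc, yc)$estimate
  partial <- spearman_partial(xc, yc, data.frame(z = z))$estimate
  expect_gt(marginal, 0.3)
  expect_lt(abs(partial), 0.1)
  expect_true(spearman_partial(rep(1, 20), rnorm(20))$degenerate)
})

test_that("partial Spearman equals the precision-matrix oracle", {
  set.seed(8)
  n <- 80
  covs <- data.frame(age = runif(n, 6, 50),
                     gender = sample(c("male", "female"), n, TRUE),
                     iq = round(rnorm(n, 100, 15)))
  x <- rnorm(n) + 0.02 * covs$age
  y <- rnorm(n) + 0.01 * covs$iq
  r <- spearman_partial(x, y, covs)
  # oracle: partial correlation from the inverse rank-correlation matrix
  M <- cbind(rank(x), rank(y), rank(covs$age),
             rank(as.numeric(factor(covs$gender))), rank(covs$iq))
  P <- solve(stats::cor(M))
  r_oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(r$estimate, r_oracle, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg step-up matches the hand calculation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(21)
  p <- runif(20)
  a <- bh_adjust(p)
  expect_true(all(a >= p) && all(a <= 1))
  # order-preserving up to the final reordering
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), a[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("severity tertiles split 121 scores into 40/40/41 with stable ties", {
  set.seed(9)
  s <- rnorm(121)
  lab <- severity_tertiles(s)
  expect_equal(as.vector(table(lab)), c(40, 40, 41))
  # severity increases with score
  expect_true(max(s[lab == "mild"]) <= min(s[lab == "severe"]))
  # three distinct scores: one per group in score order
  expect_equal(as.character(severity_tertiles(c(3, 1, 2))),
               c("severe", "mild", "moderate"))
  # all tied: the documented input-order tie-break fixes the split
  lab2 <- severity_tertiles(rep(7, 121))
  expect_equal(as.vector(table(lab2)), c(40, 40, 41))
  expect_equal(as.character(lab2[1:3]), rep("mild", 3))
  expect_error(severity_tertiles(c(1, 2)), "at least 3")
})

test_that("IQ strata use closed-interval bounds", {
  lab <- iq_strata(c(60, 84, 85, 115, 116, 136))
  expect_equal(as.character(lab),
               c("low", "low", "normal", "normal", "high", "high"))
  expect_equal(length(iq_strata(numeric(0))), 0)
  expect_error(iq_strata(c(100, 140)), "out of range")
  expect_error(iq_strata(59), "out of range")
})

test_that("retention and grid bookkeeping helpers round as printed", {
  expect_equal(retention_pct(121, 136), 89.0)
  expect_equal(retention_pct(40, 41), 97.6)
  expect_equal(parse_printed_p(c("0.05", "<1e-4")), c(0.05, 1e-4))
  expect_equal(count_significant_cells(c("0.05", "<1e-4", "0.06", "0.12")), 2)
  expect_equal(significant_fraction(5, 145), 3.4)
})

test_that("the full battery produces complete grids on a small cohort", {
  cfg <- cohort_config(
    n_asd = 21, n_td = 8,
    asd_params = asd_model_params(), td_params = td_model_params(),
    trial_config = trial_set_config(n_trials = 10, n_blocks = 2, seed = 1),
    seed = 33)
  ch <- simulate_cohort(cfg)
  m <- cohort_metrics(ch)
  rep <- run_full_battery(m, ch$participants, ch$symptom_scores)
  expect_s3_class(rep, "plight_report")
  expect_named(rep, c("group_effects", "chance_tests", "paired_latency",
                      "severity_grid", "iq_strata", "correlation_grid",
                      "config", "n_unjoined"), ignore.order = TRUE)
  expect_equal(nrow(rep$correlation_grid), 5 * 29)
  expect_equal(nrow(rep$severity_grid), 29 * 3)
  expect_true(all(rep$severity_grid$n %in% c(7, 7, 7)))
  # BH is applied to exactly the five primary tests
  expect_equal(length(rep$group_effects), 5)
  p_raw <- vapply(rep$group_effects, `[[`, numeric(1), "p_raw")
  p_adj <- vapply(rep$group_effects, `[[`, numeric(1), "p_adjusted")
  expect_equal(unname(p_adj), bh_adjust(unname(p_raw)))
  expect_true(all(vapply(rep$chance_tests, length, integer(1)) == 2))
})

test_that("partial-correlation grid is calibrated under the null", {
  # zero metric-symptom coupling: significant fraction ~ alpha
  set.seed(55)
  fracs <- vapply(1:100, function(i) {
    n <- 121
    covs <- data.frame(age = runif(n, 6, 54),
                       gender = sample(c("male", "female"), n, TRUE),
                       iq = rnorm(n, 98.5, 20))
    x <- rnorm(n)
    ps <- vapply(1:29, function(j)
      spearman_partial(x, rnorm(n), covs)$p_raw, numeric(1))
    mean(ps < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})
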