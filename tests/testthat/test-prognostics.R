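test_that("AUC handles separation, the 4-point worked set, and complements", {
  expect_equal(
    roc_auc(feature = c(1, 2, 3, 10, 11, 12), event = c(0, 0, 0, 1, 1, 1), n_boot = 0)$auc,
    1
  )
  # events {2, 4}, non-events {1, 3}: 3 of 4 pairs concordant
  w <- roc_auc(feature = c(2, 4, 1, 3), event = c(1, 1, 0, 0), n_boot = 0)
  expect_equal(w$auc, 0.75)

  for (seed in 1:5) {
    set.seed(seed)
    f <- rnorm(40)
    ev <- rbinom(40, 1, 0.4)
    if (sum(ev) %in% c(0, 40)) next
    a1 <- roc_auc(feature = f, event = ev, n_boot = 0)$auc
    a2 <- roc_auc(feature = -f, event = ev, n_boot = 0)$auc
    expect_equal(a1 + a2, 1)
  }
  expect_error(
    roc_auc(feature = 1:5, event = rep(1, 5), n_boot = 0),
    class = "histofract_eval_error"
  )
})

test_that("AUC bootstrap gives an interval bracketing the point estimate", {
  set.seed(3)
  f <- c(rnorm(30), rnorm(20, 1.2))
  ev <- rep(c(0, 1), c(30, 20))
  a <- roc_auc(feature = f, event = ev, n_boot = 300, seed = 5)
  expect_true(a$ci_lo <= a$auc && a$auc <= a$ci_hi)
  expect_true(is.finite(a$auc_corrected))
  expect_equal(a$direction, "high_risk")
})

test_that("the hand-rolled log-rank statistic agrees with survival::survdiff", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 50
    tm <- round(rexp(n, 0.05)) + 1 # ties on purpose
    ev <- rbinom(n, 1, 0.5)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(ev) == 0) next
    ours <- logrank_stat(tm, ev, g)$chisq
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)$chisq
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("the cutpoint scan finds block separations and matches a brute-force scan", {
  # all events above all non-events
  f <- c(1:10, 101:110)
  tm <- c(rexp(10, 0.01) + 50, rexp(10, 0.2))
  ev <- c(rep(0, 10), rep(1, 10))
  cp <- optimal_cutpoint(feature = f, time = tm, event = ev)
  expect_true(cp$cutpoint > 10 && cp$cutpoint < 101)

  expect_error(
    optimal_cutpoint(feature = rep(1, 30), time = rexp(30), event = rbinom(30, 1, 0.5)),
    class = "histofract_eval_error"
  )

  set.seed(8)
  n <- 40
  f <- rnorm(n); tm <- rexp(n, 0.05); ev <- rbinom(n, 1, 0.4)
  cp <- optimal_cutpoint(feature = f, time = tm, event = ev)
  # independent exhaustive scan with survdiff
  vals <- sort(unique(f))
  cuts <- (head(vals, -1) + tail(vals, -1)) / 2
  min_n <- ceiling(0.1 * n)
  best <- -Inf; best_cut <- NA
  for (cu in cuts) {
    hi <- f > cu
    if (sum(hi) < min_n || sum(!hi) < min_n) next
    st <- survival::survdiff(survival::Surv(tm, ev) ~ hi)$chisq
    if (st > best) { best <- st; best_cut <- cu }
  }
  expect_equal(cp$statistic, best, tolerance = 1e-10)
  expect_equal(cp$cutpoint, best_cut)
})

test_that("the cutpoint split is invariant under strictly monotone transforms", {
  set.seed(11)
  n <- 50
  f <- rnorm(n); tm <- rexp(n, 0.05); ev <- rbinom(n, 1, 0.4)
  cp1 <- optimal_cutpoint(feature = f, time = tm, event = ev)
  cp2 <- optimal_cutpoint(feature = exp(f), time = tm, event = ev)
  expect_equal(f > cp1$cutpoint, exp(f) > cp2$cutpoint)
  expect_equal(cp1$statistic, cp2$statistic, tolerance = 1e-10)
})

test_that("cutpoint optimization inflates the uncorrected type-I error; the corrected p does not", {
  rejections <- sapply(1:60, function(s) {
    co <- gen_cohort(cohort_spec(seed = s, group_log_hr = 0))
    optimal_cutpoint(co, "mean_intensity", "time_months", "event")$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.05) # optimism bias of outcome-based categorization

  co <- gen_cohort(cohort_spec(seed = 1, group_log_hr = 0))
  cp <- optimal_cutpoint(co, "mean_intensity", "time_months", "event",
    n_perm = 99, seed = 4
  )
  expect_gt(cp$p_corrected, cp$p_value) # correction removes optimism
})

test_that("Cox univariate recovers null and planted hazard ratios", {
  hrs <- sapply(1:60, function(s) {
    co <- gen_cohort(cohort_spec(seed = s, group_log_hr = 0))
    cox_univariate(
      group = co$risk_group == "high", time = co$time_months,
      event = co$event, n_boot = 0
    )$hr
  })
  expect_lt(abs(log(median(hrs))), log(1.25))

  hits <- sapply(1:40, function(s) {
    set.seed(s)
    g <- rep(c(TRUE, FALSE), each = 100)
    te <- rexp(200, 0.01 * exp(log(3) * g))
    tc <- runif(200, 0, 150)
    r <- cox_univariate(
      group = g, time = pmin(te, tc), event = as.integer(te <= tc),
      n_boot = 0
    )
    r$ci_lo <= 3 && 3 <= r$ci_hi
  })
  expect_gte(mean(hits), 0.85)
})

test_that("label-swapped Cox fits give exactly reciprocal hazard ratios", {
  co <- gen_cohort(cohort_spec(seed = 6))
  g <- co$risk_group == "high"
  h1 <- cox_univariate(group = g, time = co$time_months, event = co$event, n_boot = 0)$hr
  h2 <- cox_univariate(group = !g, time = co$time_months, event = co$event, n_boot = 0)$hr
  expect_equal(h1 * h2, 1, tolerance = 1e-9)
})

test_that("complete separation is flagged as monotone likelihood, not an error", {
  g <- rep(c(TRUE, FALSE), each = 15)
  tm <- c(1:15, 100 + 1:15)
  ev <- c(rep(1, 15), rep(0, 15))
  r <- cox_univariate(group = g, time = tm, event = ev, n_boot = 0)
  expect_true(r$monotone_flag)
})

test_that("Schoenfeld p-values are calibrated under PH and detect hazard reversal", {
  ps <- sapply(1:120, function(s) {
    set.seed(s)
    n <- 100
    g <- rbinom(n, 1, 0.5)
    te <- rexp(n, 0.02 * exp(0.5 * g))
    tc <- runif(n, 0, 100)
    fit <- survival::coxph(survival::Surv(pmin(te, tc), as.integer(te <= tc)) ~ g)
    schoenfeld_ph_test(fit)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  pow <- sapply(1:30, function(s) {
    set.seed(s)
    n <- 200
    g <- rep(c(0, 1), each = n / 2)
    # group 1: high early hazard that collapses after month 25 (reversal);
    # group 0: constant hazard
    te <- sapply(seq_len(n), function(k) {
      if (g[k] == 0) return(rexp(1, 0.02))
      t1 <- rexp(1, 0.08)
      if (t1 <= 25) t1 else 25 + rexp(1, 0.005)
    })
    tc <- runif(n, 40, 120)
    fit <- survival::coxph(survival::Surv(pmin(te, tc), as.integer(te <= tc)) ~ g)
    schoenfeld_ph_test(fit)$p_value < 0.05
  })
  expect_gte(mean(pow), 0.8)

  one <- suppressWarnings(
    survival::coxph(survival::Surv(c(1, 2, 3), c(1, 0, 0)) ~ c(0, 1, 1))
  )
  expect_error(schoenfeld_ph_test(one), class = "histofract_eval_error")
})

test_that("multivariate selection keeps a truly prognostic feature and drops noise", {
  kept <- sapply(1:25, function(s) {
    set.seed(s)
    n <- 200
    x <- matrix(rnorm(n * 6), n, 6)
    colnames(x) <- paste0("f", 1:6)
    te <- rexp(n, 0.02 * exp(0.8 * x[, 1]))
    tc <- runif(n, 0, 100)
    df <- data.frame(time_months = pmin(te, tc), event = as.integer(te <= tc), x)
    m <- cox_multivariate(df, paste0("f", 1:6))
    "f1" %in% m$selected
  })
  expect_gte(mean(kept), 0.8)

  empty <- sapply(1:20, function(s) {
    set.seed(s + 500)
    n <- 80
    x <- matrix(rnorm(n * 4), n, 4)
    colnames(x) <- paste0("f", 1:4)
    te <- rexp(n, 0.02)
    tc <- runif(n, 0, 100)
    df <- data.frame(time_months = pmin(te, tc), event = as.integer(te <= tc), x)
    length(cox_multivariate(df, paste0("f", 1:4))$selected) == 0
  })
  expect_gt(mean(empty), 0.5)
})

test_that("duplicated candidates are reduced to one with a collinearity flag", {
  set.seed(2)
  n <- 120
  f1 <- rnorm(n)
  te <- rexp(n, 0.02 * exp(0.9 * f1))
  tc <- runif(n, 0, 120)
  df <- data.frame(
    time_months = pmin(te, tc), event = as.integer(te <= tc),
    a = f1, b = f1
  )
  m <- cox_multivariate(df, c("a", "b"))
  expect_length(m$selected, 1)
  expect_length(m$collinear, 1)
})

test_that("Kaplan-Meier steps equal hand-computed product-limit values", {
  # group A: times 1, 2, 3 with events 1, 0, 1; group B: 2, 4, 5 with 1, 1, 0
  km <- km_summary(
    group = rep(c("A", "B"), each = 3),
    time = c(1, 2, 3, 2, 4, 5),
    event = c(1, 0, 1, 1, 1, 0)
  )
  a <- dplyr::filter(km$curves, group == "A")
  b <- dplyr::filter(km$curves, group == "B")
  expect_equal(a$surv[a$time == 1], 2 / 3)
  expect_equal(a$surv[a$time == 3], 0)
  expect_equal(b$surv[b$time == 2], 2 / 3)
  expect_equal(b$surv[b$time == 4], 1 / 3)
  expect_equal(b$surv[b$time == 5], 1 / 3) # censored, no drop
  expect_true(km$logrank_p >= 0 && km$logrank_p <= 1)
})

test_that("event-free cohorts give flat curves at 1 and empty groups error", {
  km <- km_summary(
    group = rep(c("A", "B"), each = 5),
    time = rexp(10, 0.1) + 1, event = rep(0, 10)
  )
  expect_true(all(km$curves$surv == 1))
  expect_error(
    km_summary(group = rep("A", 5), time = rexp(5), event = rep(1, 5)),
    class = "histofract_eval_error"
  )
})

test_that("Spearman matrices are symmetric with unit diagonal and match hand values", {
  df <- data.frame(
    x = c(1, 2, 3, 4, 5),
    y = c(2, 1, 4, 3, 5), # sum d^2 = 4 -> rho = 0.8
    z = 5:1,
    const = rep(7, 5)
  )
  sm <- spearman_matrix(df)
  expect_equal(sm$rho["x", "x"], 1)
  expect_equal(sm$rho["x", "y"], 0.8)
  expect_equal(sm$rho["x", "z"], -1)
  expect_equal(sm$rho, t(sm$rho))
  expect_true("const" %in% sm$constant)
  expect_true(all(is.na(sm$rho["const", c("x", "y", "z")])))
  expect_error(spearman_matrix(df[1:2, ]), class = "histofract_eval_error")
})

test_that("the prognostic report flags a strongly planted feature in both ROC and Cox", {
  spec <- cohort_spec(
    seed = 21, group_log_hr = log(8),
    features = tibble::tibble(
      feature = "marker", mean_high = 2, sd_high = 0.5,
      mean_low = 0, sd_low = 0.5
    )
  )
  co <- gen_cohort(spec)
  co$noise <- rnorm(nrow(co)) # independent of outcome
  rep <- prognostic_report(co, c("marker", "noise"),
    n_boot = 200, n_perm = 100, seed = 2
  )
  tr <- tidy(rep)
  marker <- tr[tr$feature == "marker", ]
  noise <- tr[tr$feature == "noise", ]
  expect_lt(marker$auc_p, 0.05)
  expect_lt(marker$hr_p, 0.05)
  expect_equal(marker$direction, "high_risk")
  expect_gt(noise$auc_p, 0.05)
  # uncorrected and corrected cutpoint p are reported side by side
  expect_true(all(c("cutpoint_p", "cutpoint_p_corrected") %in% names(tr)))
  expect_s3_class(glance(rep), "tbl_df")
})
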