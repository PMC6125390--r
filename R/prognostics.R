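#' ROC AUC by the Mann-Whitney statistic, with bootstrap validation
#'
#' AUC is the probability that a randomly chosen event case has a higher
#' feature value than a randomly chosen non-event case, ties counted 1/2
#' (midranks). The p-value comes from the tie-corrected normal approximation
#' to the Mann-Whitney null. Nonparametric case-resampling bootstrap
#' provides a percentile confidence interval and a bias-corrected
#' (optimism-corrected) point estimate `2 * auc - mean(boot)`.
#'
#' AUC < 0.5 means higher feature values associate with the event-free
#' (low-risk) class.
#'
#' @param data Optional data frame containing the columns named by
#'   `feature` and `event`; alternatively pass vectors directly.
#' @param feature Numeric feature values, or column name in `data`.
#' @param event 0/1 or logical event indicator, or column name in `data`.
#' @param n_boot Bootstrap resamples (0 skips the bootstrap).
#' @param seed Seed for the bootstrap; required when `n_boot > 0`.
#' @param conf Confidence level for the bootstrap interval.
#' @return One-row tibble: `auc`, `auc_corrected`, `ci_lo`, `ci_hi`,
#'   `p_value`, `direction`, `n`, `n_events`, `n_boot`.
#' @export
roc_auc <- function(data = NULL, feature, event, n_boot = 1000L, seed = NULL,
                    conf = 0.95) {
  if (!is.null(data)) {
    feature <- data[[feature]]
    event <- data[[event]]
  }
  event <- as.logical(event)
  if (anyNA(feature) || anyNA(event)) {
    abort("missing values are not allowed", class = "histofract_eval_error")
  }
  n1 <- sum(event)
  n0 <- sum(!event)
  if (n1 == 0L || n0 == 0L) {
    abort("both outcome classes must be present", class = "histofract_eval_error")
  }
  auc_point <- mw_auc(feature, event)
  n <- n1 + n0
  ties <- table(feature)
  sigma_u <- sqrt(n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  u <- auc_point * n1 * n0
  z <- if (sigma_u > 0) (u - n1 * n0 / 2) / sigma_u else 0
  p <- 2 * pnorm(-abs(z))

  ci <- c(NA_real_, NA_real_)
  auc_corr <- NA_real_
  if (n_boot > 0L) {
    if (is.null(seed)) abort("seed is required for the bootstrap", class = "histofract_eval_error")
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ev <- event[idx]
      if (all(ev) || !any(ev)) return(NA_real_)
      mw_auc(feature[idx], ev)
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
    auc_corr <- 2 * auc_point - mean(boot)
  }
  tibble(
    auc = auc_point, auc_corrected = auc_corr,
    ci_lo = ci[1], ci_hi = ci[2], p_value = p,
    direction = ifelse(auc_point < 0.5, "low_risk", "high_risk"),
    n = n, n_events = n1, n_boot = as.integer(n_boot)
  )
}

mw_auc <- function(feature, event) {
  r <- rank(feature)
  n1 <- sum(event)
  n0 <- sum(!event)
  (sum(r[event]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sample log-rank statistic
#'
#' Plain-R implementation of the two-group log-rank chi-squared statistic
#' (hypergeometric variance, ties handled jointly), used inside the
#' cutpoint scan where many thousands of splits and permutations are
#' evaluated. Agrees with [survival::survdiff()].
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicator.
#' @param group Logical or 0/1 group indicator.
#' @return List with `chisq`, `p_value`.
#' @export
logrank_stat <- function(time, event, group) {
  group <- as.logical(group)
  event <- as.integer(event)
  o <- order(time)
  time <- time[o]; event <- event[o]; group <- group[o]
  n <- length(time)
  ev_times <- unique(time[event == 1L])
  u <- 0; v <- 0
  for (t in ev_times) {
    at <- time >= t
    n_at <- sum(at)
    n1_at <- sum(at & group)
    d <- sum(event == 1L & time == t)
    d1 <- sum(event == 1L & time == t & group)
    u <- u + d1 - d * n1_at / n_at
    if (n_at > 1) {
      v <- v + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1)
    }
  }
  chisq <- if (v > 0) u^2 / v else 0
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Outcome-based optimal cutpoint
#'
#' Exhaustive scan over every midpoint between consecutive sorted distinct
#' feature values that leaves at least `min_group_frac` of the cohort on
#' each side; returns the cutpoint maximizing the two-group log-rank
#' statistic, ties broken toward the more balanced split. Because the
#' cutpoint is chosen to maximize outcome separation, the uncorrected
#' log-rank p-value is optimistic; a resampling-corrected p (permutation of
#' the feature against the outcome pairs, re-running the full scan) is
#' reported alongside when `n_perm > 0`.
#'
#' @param data Optional data frame with the named columns.
#' @param feature Numeric feature (>= 10 distinct values), or column name.
#' @param time Follow-up times, or column name.
#' @param event 0/1 event indicator, or column name.
#' @param min_group_frac Minimum fraction of patients on each side (default 0.10).
#' @param n_perm Permutation resamples for the corrected p (0 skips).
#' @param seed Seed for the permutations.
#' @return One-row tibble: `cutpoint`, `statistic`, `p_value`,
#'   `p_corrected`, `n_low`, `n_high`.
#' @export
optimal_cutpoint <- function(data = NULL, feature, time, event,
                             min_group_frac = 0.10, n_perm = 0L, seed = NULL) {
  if (!is.null(data)) {
    feature <- data[[feature]]; time <- data[[time]]; event <- data[[event]]
  }
  vals <- sort(unique(feature))
  if (length(vals) < 10L) {
    abort("need at least 10 distinct feature values for a cutpoint scan",
      class = "histofract_eval_error"
    )
  }
  n <- length(feature)
  min_n <- ceiling(min_group_frac * n)
  cuts <- (head(vals, -1) + tail(vals, -1)) / 2

  scan <- function(f) {
    stats_vec <- rep(-Inf, length(cuts))
    bal <- rep(Inf, length(cuts))
    for (i in seq_along(cuts)) {
      hi <- f > cuts[i]
      n_hi <- sum(hi)
      if (n_hi < min_n || n - n_hi < min_n) next
      stats_vec[i] <- logrank_stat(time, event, hi)$chisq
      bal[i] <- abs(n - 2 * n_hi)
    }
    list(stat = stats_vec, bal = bal)
  }

  obs <- scan(feature)
  if (!any(is.finite(obs$stat))) {
    abort("no admissible split under the minimum group size", class = "histofract_eval_error")
  }
  best_stat <- max(obs$stat)
  cand <- which(obs$stat >= best_stat - 1e-12)
  best <- cand[which.min(obs$bal[cand])]
  cut <- cuts[best]
  n_high <- sum(feature > cut)
  p_unc <- pchisq(best_stat, df = 1, lower.tail = FALSE)

  p_corr <- NA_real_
  if (n_perm > 0L) {
    if (is.null(seed)) abort("seed is required for permutation correction", class = "histofract_eval_error")
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      mx <- max(scan(sample(feature))$stat)
      if (is.finite(mx) && mx >= best_stat) exceed <- exceed + 1L
    }
    p_corr <- (1 + exceed) / (n_perm + 1)
  }
  tibble(
    cutpoint = cut, statistic = best_stat, p_value = p_unc,
    p_corrected = p_corr, n_low = n - n_high, n_high = n_high
  )
}

#' Univariate Cox proportional-hazards fit on a binary risk group
#'
#' Partial-likelihood fit with Efron tie handling via
#' [survival::coxph()]. The bootstrap (nonparametric case resampling,
#' stratified by group) yields a bias-corrected percentile confidence
#' interval for the hazard ratio. Monotone-likelihood (complete separation)
#' is flagged rather than treated as an error.
#'
#' @param data Optional data frame with the named columns.
#' @param group Logical/0-1 high-risk indicator, or column name.
#' @param time Follow-up times, or column name.
#' @param event 0/1 event indicator, or column name.
#' @param n_boot Bootstrap resamples (0 skips).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `hr`, `ci_lo`, `ci_hi`, `p_value`, `coef`, `se`,
#'   `monotone_flag`, `n_boot`.
#' @export
cox_univariate <- function(data = NULL, group, time, event, n_boot = 1000L,
                           seed = NULL) {
  if (!is.null(data)) {
    group <- data[[group]]; time <- data[[time]]; event <- data[[event]]
  }
  group <- as.logical(group)
  if (sum(event) < 1L) abort("no events: hazard ratio undefined", class = "histofract_eval_error")
  fit_one <- function(g, t, e) {
    w <- FALSE
    fit <- withCallingHandlers(
      coxph(Surv(t, e) ~ g, ties = "efron"),
      warning = function(cnd) {
        if (grepl("infinite|converge", conditionMessage(cnd))) w <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    list(coef = unname(coef(fit)[1]), se = sqrt(fit$var[1, 1]), flag = w)
  }
  base <- fit_one(group, time, event)
  if (!is.finite(base$coef)) {
    abort("Cox fit did not converge", class = "histofract_fit_error")
  }
  monotone <- base$flag || abs(base$coef) > 10
  p <- 2 * pnorm(-abs(base$coef / base$se))

  ci <- exp(base$coef + c(-1, 1) * 1.96 * base$se)
  if (n_boot > 0L) {
    if (is.null(seed)) abort("seed is required for the bootstrap", class = "histofract_eval_error")
    set.seed(seed)
    i1 <- which(group); i0 <- which(!group)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- c(
        sample(i1, length(i1), replace = TRUE),
        sample(i0, length(i0), replace = TRUE)
      )
      if (sum(event[idx]) == 0L) return(NA_real_)
      tryCatch(fit_one(group[idx], time[idx], event[idx])$coef,
        error = function(e) NA_real_
      )
    }, numeric(1))
    boot <- boot[is.finite(boot) & abs(boot) < 15]
    if (length(boot) >= 10L) {
      bias <- mean(boot) - base$coef
      ci <- exp(unname(quantile(boot - bias, c(0.025, 0.975))))
    }
  }
  tibble(
    hr = exp(base$coef), ci_lo = ci[1], ci_hi = ci[2], p_value = p,
    coef = base$coef, se = base$se, monotone_flag = monotone,
    n_boot = as.integer(n_boot)
  )
}

#' Schoenfeld proportional-hazards check
#'
#' Correlation test of the scaled Schoenfeld residuals against event time
#' ([survival::cox.zph()] with identity time transform); one p-value per
#' covariate. Requires at least 5 events.
#'
#' @param fit A fitted [survival::coxph()] model.
#' @return Tibble: `term`, `chisq`, `df`, `p_value`.
#' @export
schoenfeld_ph_test <- function(fit) {
  if (is.null(fit$nevent) || fit$nevent < 5L) {
    abort("need at least 5 events for the Schoenfeld PH check", class = "histofract_eval_error")
  }
  z <- cox.zph(fit, transform = "identity")
  tb <- z$table
  tb <- tb[rownames(tb) != "GLOBAL", , drop = FALSE]
  tibble(
    term = rownames(tb), chisq = tb[, "chisq"], df = tb[, "df"],
    p_value = tb[, "p"]
  )
}

#' Multivariate Cox model with forward-entry / backward-stay selection
#'
#' Candidates are screened by univariate Cox Wald p < `enter_p` (default
#' 0.20); the surviving set enters a full model from which the covariate
#' with the worst Wald p is removed until all remaining satisfy
#' p < `stay_p` (default 0.05). Exactly collinear candidates (aliased
#' coefficients) are dropped and flagged.
#'
#' @param data Data frame with `time`, `event` and candidate columns.
#' @param candidates Character vector of candidate feature columns.
#' @param time,event Column names for follow-up time and event indicator.
#' @param enter_p,stay_p Selection thresholds.
#' @return An `hf_cox_model`: list with the final `fit` (or NULL for an
#'   empty model), `selected`, `univariate` screen, `dropped`, and
#'   `collinear` flags. Supports [tidy()] and [glance()].
#' @export
cox_multivariate <- function(data, candidates, time = "time_months",
                             event = "event", enter_p = 0.20, stay_p = 0.05) {
  if (length(candidates) < 2L) abort("need at least 2 candidate features", class = "histofract_eval_error")
  if (sum(data[[event]]) < 5L) abort("need at least 5 events", class = "histofract_eval_error")
  srv <- Surv(data[[time]], data[[event]])
  uni <- purrr::map_dfr(candidates, function(cn) {
    fit <- suppressWarnings(coxph(srv ~ data[[cn]], ties = "efron"))
    z <- coef(fit)[1] / sqrt(fit$var[1, 1])
    tibble(term = cn, coef = unname(coef(fit)[1]), p_value = 2 * pnorm(-abs(z)))
  })
  keep <- uni$term[uni$p_value < enter_p & is.finite(uni$p_value)]
  dropped <- character(0)
  collinear <- character(0)
  fit <- NULL
  while (length(keep) > 0L) {
    fml <- stats::reformulate(keep, response = "srv")
    fit <- suppressWarnings(coxph(fml, data = data, ties = "efron"))
    cf <- coef(fit)
    if (anyNA(cf)) {
      bad <- names(cf)[is.na(cf)]
      collinear <- c(collinear, bad)
      keep <- setdiff(keep, bad)
      next
    }
    se <- sqrt(diag(fit$var))
    pvals <- 2 * pnorm(-abs(cf / se))
    if (max(pvals) < stay_p) break
    worst <- names(pvals)[which.max(pvals)]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
    fit <- NULL
  }
  structure(
    list(
      fit = fit, selected = keep, univariate = uni,
      dropped = dropped, collinear = collinear,
      n = nrow(data), n_events = sum(data[[event]])
    ),
    class = "hf_cox_model"
  )
}

#' @exportS3Method generics::tidy
tidy.hf_cox_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(
      term = character(), coef = numeric(), hr = numeric(),
      ci_lo = numeric(), ci_hi = numeric(), p_value = numeric()
    ))
  }
  cf <- coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  tibble(
    term = names(cf), coef = unname(cf), hr = exp(unname(cf)),
    ci_lo = exp(unname(cf) - 1.96 * se), ci_hi = exp(unname(cf) + 1.96 * se),
    p_value = 2 * pnorm(-abs(unname(cf) / se))
  )
}

#' @exportS3Method generics::glance
glance.hf_cox_model <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events, n_selected = length(x$selected),
    n_candidates = nrow(x$univariate),
    concordance = if (is.null(x$fit)) NA_real_ else unname(x$fit$concordance["concordance"])
  )
}

#' Kaplan-Meier summary for two or more risk groups
#'
#' Product-limit estimates per group with censoring marks, plus the
#' two-sided log-rank test across groups.
#'
#' @param data Optional data frame with the named columns.
#' @param group Group labels, or column name.
#' @param time,event Follow-up time and event indicator, or column names.
#' @return An `hf_km`: list with `curves` (tibble of step coordinates:
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`) and
#'   `logrank_p`. Supports [tidy()] and [autoplot()].
#' @export
km_summary <- function(data = NULL, group, time, event) {
  if (!is.null(data)) {
    group <- data[[group]]; time <- data[[time]]; event <- data[[event]]
  }
  if (any(table(group) == 0L) || length(unique(group)) < 2L) {
    abort("need at least two non-empty groups", class = "histofract_eval_error")
  }
  df <- data.frame(time = time, event = as.integer(event), group = factor(group))
  sf <- survfit(Surv(time, event) ~ group, data = df)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble(
    group = sub("^group=", "", strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv
  )
  if (sum(df$event) == 0L) {
    p <- NA_real_ # no events anywhere: the log-rank test is undefined
  } else {
    sd_fit <- survdiff(Surv(time, event) ~ group, data = df)
    p <- pchisq(sd_fit$chisq, df = length(sd_fit$n) - 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, logrank_p = p), class = "hf_km")
}

#' @exportS3Method generics::tidy
tidy.hf_km <- function(x, ...) x$curves

#' @exportS3Method ggplot2::autoplot
autoplot.hf_km <- function(object, ...) {
  cens <- dplyr::filter(object$curves, .data$n_censor > 0)
  ggplot2::ggplot(object$curves, ggplot2::aes(
    x = .data$time, y = .data$surv,
    colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "months", y = "metastasis-free fraction",
      subtitle = sprintf("log-rank p = %.3g", object$logrank_p)
    )
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations (average ranks for ties) with p-values;
#' constant columns yield `NA` and are flagged.
#'
#' @param data Data frame; `cols` selects the numeric columns (default all
#'   numeric columns).
#' @param cols Optional character vector of column names.
#' @return An `hf_spearman`: list with `rho` and `p` matrices and a
#'   `constant` character vector of flagged columns. [tidy()] gives the
#'   long form.
#' @export
spearman_matrix <- function(data, cols = NULL) {
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (nrow(data) < 3L) abort("need at least 3 records", class = "histofract_eval_error")
  x <- as.matrix(data[cols])
  constant <- cols[apply(x, 2, function(v) length(unique(v)) < 2L)]
  k <- length(cols)
  rho <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  pm <- rho
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    pm[i, i] <- 0
    for (j in seq_len(k)) {
      if (j <= i) next
      if (cols[i] %in% constant || cols[j] %in% constant) next
      ct <- suppressWarnings(cor.test(x[, i], x[, j], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pm[i, j] <- pm[j, i] <- ct$p.value
    }
  }
  diag(rho)[cols %in% constant] <- NA_real_
  structure(list(rho = rho, p = pm, constant = constant), class = "hf_spearman")
}

#' @exportS3Method generics::tidy
tidy.hf_spearman <- function(x, ...) {
  cols <- colnames(x$rho)
  out <- expand.grid(term1 = cols, term2 = cols, stringsAsFactors = FALSE)
  out$rho <- as.numeric(x$rho)
  out$p_value <- as.numeric(x$p)
  as_tibble(out)
}

#' Per-feature prognostic report
#'
#' For every feature column: continuous-value ROC AUC with bootstrap CI,
#' outcome-based optimal cutpoint with uncorrected and resampling-corrected
#' log-rank p side by side, and a univariate Cox fit on the dichotomized
#' risk groups with bootstrap-corrected CI. Also runs the
#' forward-entry/backward-stay multivariate Cox selection on the
#' dichotomized features and the Spearman correlation matrix of the
#' continuous features.
#'
#' @param data Data frame with `patient_id`, time, event and feature columns.
#' @param features Character vector of feature column names.
#' @param time,event Column names.
#' @param n_boot Bootstrap resamples for AUC and Cox CIs.
#' @param n_perm Permutation resamples for the cutpoint-corrected p.
#' @param seed Seed recorded in the report and used for all resampling.
#' @return An `hf_report`: list with `features` (one row per feature),
#'   `multivariate` (`hf_cox_model`), `spearman`, `seed`. [tidy()] returns
#'   the per-feature table.
#' @export
prognostic_report <- function(data, features, time = "time_months",
                              event = "event", n_boot = 1000L, n_perm = 200L,
                              seed = 1L) {
  groups <- list()
  rows <- purrr::map_dfr(features, function(fn) {
    a <- roc_auc(data, fn, event, n_boot = n_boot, seed = seed)
    cut <- tryCatch(
      optimal_cutpoint(data, fn, time, event, n_perm = n_perm, seed = seed),
      error = function(e) tibble(
        cutpoint = NA_real_, statistic = NA_real_, p_value = NA_real_,
        p_corrected = NA_real_, n_low = NA_integer_, n_high = NA_integer_
      )
    )
    if (is.finite(cut$cutpoint)) {
      grp <- data[[fn]] > cut$cutpoint
      groups[[fn]] <<- as.integer(grp)
      cox <- cox_univariate(
        group = grp, time = data[[time]], event = data[[event]],
        n_boot = n_boot, seed = seed
      )
    } else {
      cox <- tibble(
        hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        p_value = NA_real_, monotone_flag = NA
      )
    }
    tibble(
      feature = fn,
      auc = a$auc, auc_corrected = a$auc_corrected,
      auc_lo = a$ci_lo, auc_hi = a$ci_hi, auc_p = a$p_value,
      cutpoint = cut$cutpoint,
      cutpoint_p = cut$p_value, cutpoint_p_corrected = cut$p_corrected,
      hr = cox$hr, hr_lo = cox$ci_lo, hr_hi = cox$ci_hi, hr_p = cox$p_value,
      monotone_flag = cox$monotone_flag,
      direction = ifelse(a$auc < 0.5, "low_risk", "high_risk")
    )
  })
  multi <- NULL
  if (length(groups) >= 2L) {
    gdf <- as.data.frame(groups)
    names(gdf) <- paste0(names(groups), "_high")
    mdata <- cbind(data[c(time, event)], gdf)
    multi <- tryCatch(
      cox_multivariate(mdata, names(gdf), time = time, event = event),
      error = function(e) NULL
    )
  }
  structure(
    list(
      features = rows, multivariate = multi,
      spearman = spearman_matrix(data, features),
      seed = seed, n_boot = n_boot, n_perm = n_perm
    ),
    class = "hf_report"
  )
}

#' @exportS3Method generics::tidy
tidy.hf_report <- function(x, ...) x$features

#' @exportS3Method generics::glance
glance.hf_report <- function(x, ...) {
  tibble(
    n_features = nrow(x$features),
    n_significant_auc = sum(x$features$auc_p < 0.05, na.rm = TRUE),
    n_selected_multivariate = if (is.null(x$multivariate)) 0L else length(x$multivariate$selected),
    seed = x$seed, n_boot = x$n_boot
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.hf_report <- function(object, ...) {
  df <- dplyr::arrange(object$features, .data$auc)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$auc_lo, xmax = .data$auc_hi),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "AUC (bootstrap 95% CI)", y = NULL)
}
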