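#' Moment-order grid for multifractal analysis
#'
#' The 200-point half-open grid of moment orders Q: `-10.0, -9.9, ..., +9.9`
#' in 0.1 increments. Contains Q = 0 and Q = 1 exactly.
#'
#' @return Numeric vector of length 200.
#' @export
q_grid <- function() {
  (-100:99) / 10
}

#' Normalized box measures at one scale
#'
#' Probability vector `mu_i = m_i / sum(m_j)` over the occupied boxes at the
#' requested scale of a `scale_series`.
#'
#' @param series A `scale_series`.
#' @param scale One of `series$scale`.
#' @return Numeric probability vector summing to 1.
#' @export
normalized_masses <- function(series, scale) {
  i <- match(scale, series$scale)
  if (is.na(i)) abort("scale not present in series", class = "histofract_config_error")
  m <- series$masses[[i]]
  tot <- sum(m)
  if (tot <= 0) abort("zero total mass at this scale", class = "histofract_degenerate_error")
  m / tot
}

logsumexp_rows <- function(a) {
  mx <- apply(a, 1, max)
  mx + log(rowSums(exp(a - mx)))
}

ols_slope_r2 <- function(x, y_mat) {
  # per-column slope and r^2 of y ~ x
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  yc <- sweep(y_mat, 2, colMeans(y_mat))
  slope <- colSums(xc * yc) / ssx
  ssy <- colSums(yc^2)
  r2 <- ifelse(ssy > 0, (colSums(xc * yc))^2 / (ssx * ssy), 1)
  list(slope = slope, r2 = r2)
}

#' Estimate a multifractal spectrum by the direct Chhabra-Jensen method
#'
#' For each moment order Q the Q-normalized box measures
#' `mu_i(Q, eps) = mu_i^Q / sum_j mu_j^Q` are formed over the occupied boxes
#' (empty boxes carry no measure, which keeps negative Q well defined), and
#' three OLS regressions over the scale grid give the Holder exponent
#' `alpha(Q)` (slope of `sum mu(Q) log mu` vs `log eps`), the singularity
#' spectrum `f(Q)` (slope of `sum mu(Q) log mu(Q)` vs `log eps`) and the
#' mass exponent `tau(Q)` (slope of `log sum mu^Q` vs `log eps`). The
#' generalized dimension is `D_Q = tau(Q) / (Q - 1)` for `Q != 1`, with the
#' entropy limit `D_1 = alpha(1)`. All internal sums use log-sum-exp, so
#' extreme Q do not overflow.
#'
#' @param series A `scale_series` with at least 3 scales.
#' @param q Moment orders; defaults to the 200-point [q_grid()].
#' @return An `hf_spectrum` tibble: `q`, `tau`, `d_q`, `alpha`, `f_alpha`,
#'   `fit_r2` (r-squared of the tau regression; of the alpha regression at
#'   Q = 1).
#' @export
estimate_spectrum <- function(series, q = q_grid()) {
  if (nrow(series) < 3L) {
    abort("need at least 3 scales for spectrum estimation", class = "histofract_degenerate_error")
  }
  log_eps <- log(series$scale)
  nq <- length(q)
  ns <- nrow(series)
  s_alpha <- matrix(NA_real_, ns, nq)
  s_f <- matrix(NA_real_, ns, nq)
  s_tau <- matrix(NA_real_, ns, nq)
  for (s in seq_len(ns)) {
    p <- normalized_masses(series, series$scale[s])
    l <- log(p)
    a <- outer(q, l) # nq x n_boxes
    lse <- logsumexp_rows(a)
    w <- exp(a - lse)
    s_alpha[s, ] <- as.numeric(w %*% l)
    s_f[s, ] <- rowSums(w * (a - lse))
    s_tau[s, ] <- lse
  }
  alpha_fit <- ols_slope_r2(log_eps, s_alpha)
  f_fit <- ols_slope_r2(log_eps, s_f)
  tau_fit <- ols_slope_r2(log_eps, s_tau)
  tau <- tau_fit$slope
  d_q <- ifelse(abs(q - 1) < 1e-9, alpha_fit$slope, tau / (q - 1))
  fit_r2 <- ifelse(abs(q - 1) < 1e-9, alpha_fit$r2, tau_fit$r2)
  structure(
    tibble(
      q = q, tau = tau, d_q = d_q,
      alpha = alpha_fit$slope, f_alpha = f_fit$slope, fit_r2 = fit_r2
    ),
    class = c("hf_spectrum", class(tibble()))
  )
}

#' Scalar features derived from a multifractal spectrum
#'
#' Reduces a spectrum over the 200-point Q grid to the 13 per-modality
#' multifractal features: the three base values at Q = 0 (`d_q0`,
#' `alpha_q0`, `f_alpha_q0`) plus ten derived features: the maximum of
#' `D_Q` over the grid, the extrema of `f(alpha)` and the `alpha` values at
#' which they occur, OLS slopes of `D_Q(Q)`, `alpha(Q)` and `f(alpha)(Q)`
#' against Q over the full grid, the restricted `D_Q(Q)` slope over
#' `Q` in `[-1, 3]` (endpoints inclusive), and `f(alpha)` summed over the
#' 99 grid points with Q > 0.
#'
#' @param spectrum An `hf_spectrum` from [estimate_spectrum()].
#' @param modality Optional label ("binary"/"grayscale") carried through.
#' @return One-row tibble with 13 feature columns plus `modality`.
#' @export
derived_features <- function(spectrum, modality = NA_character_) {
  bad <- !is.finite(spectrum$d_q) | !is.finite(spectrum$alpha) | !is.finite(spectrum$f_alpha)
  if (any(bad)) {
    abort(
      paste0(
        "non-finite spectrum values at Q = ",
        paste(utils::head(spectrum$q[bad], 5), collapse = ", ")
      ),
      class = "histofract_propagation_error"
    )
  }
  q <- spectrum$q
  i0 <- which(abs(q) < 1e-9)
  slope_of <- function(y, keep = rep(TRUE, length(q))) {
    ols_slope_r2(q[keep], matrix(y[keep], ncol = 1))$slope
  }
  i_fmin <- which.min(spectrum$f_alpha)
  i_fmax <- which.max(spectrum$f_alpha)
  tibble(
    modality = modality,
    d_q0 = spectrum$d_q[i0],
    alpha_q0 = spectrum$alpha[i0],
    f_alpha_q0 = spectrum$f_alpha[i0],
    d_q_max = max(spectrum$d_q),
    f_alpha_min = spectrum$f_alpha[i_fmin],
    f_alpha_max = spectrum$f_alpha[i_fmax],
    alpha_at_f_min = spectrum$alpha[i_fmin],
    alpha_at_f_max = spectrum$alpha[i_fmax],
    slope_dq = slope_of(spectrum$d_q),
    slope_alpha = slope_of(spectrum$alpha),
    slope_falpha = slope_of(spectrum$f_alpha),
    slope_dq_q13 = slope_of(spectrum$d_q, q >= -1 - 1e-9 & q <= 3 + 1e-9),
    f_alpha_sum_qpos = sum(spectrum$f_alpha[q > 1e-9])
  )
}

#' Multifractal feature sets for one image
#'
#' Estimates the spectrum for both modalities and reduces each to its 13
#' scalar features. Binary modality: box masses are foreground pixel counts
#' of the thresholded mask. Grayscale modality: box masses are summed
#' inverted intensity (`255 - I`), so dark (stained) pixels carry mass.
#'
#' @inheritParams monofractal_features
#' @param q Moment orders; defaults to [q_grid()].
#' @return Tibble with one row per modality and 13 feature columns.
#' @export
multifractal_features <- function(gray, bin = binarize(gray),
                                  scales = make_scales(dim(gray)),
                                  q = q_grid()) {
  bin_series <- box_counts_binary(bin, scales)
  inv <- 255 - matrix(as.numeric(gray), nrow(gray), ncol(gray))
  gray_series <- box_mass_series(inv, scales)
  dplyr::bind_rows(
    derived_features(estimate_spectrum(bin_series, q), modality = "binary"),
    derived_features(estimate_spectrum(gray_series, q), modality = "grayscale")
  )
}

#' @exportS3Method generics::tidy
tidy.hf_spectrum <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method ggplot2::autoplot
autoplot.hf_spectrum <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    dplyr::transmute(df,
      q = .data$q, `D_Q` = .data$d_q, `alpha(Q)` = .data$alpha,
      `f(alpha)(Q)` = .data$f_alpha
    ),
    -"q",
    names_to = "curve", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "moment order Q", y = NULL)
}
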