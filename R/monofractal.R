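#' Fit a fractal dimension from a scale series
#'
#' Ordinary least-squares slope of `log N(eps)` against `log(1/eps)`
#' (natural logs; the base is irrelevant to the slope), with the fit's
#' coefficient of determination.
#'
#' @param series A `scale_series` from [box_counts_binary()],
#'   [dbc_counts_gray()] or [box_mass_series()].
#' @return One-row tibble: `fd`, `r_squared`.
#' @export
fit_dimension <- function(series) {
  ok <- series$count > 0
  if (sum(ok) < 3L) {
    abort("need at least 3 scales with positive counts", class = "histofract_degenerate_error")
  }
  x <- log(1 / series$scale[ok])
  y <- log(series$count[ok])
  xc <- x - mean(x)
  yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  ssy <- sum(yc^2)
  r2 <- if (ssy == 0) 1 else sum(xc * yc)^2 / (sum(xc^2) * ssy)
  tibble(fd = slope, r_squared = r2)
}

#' Lacunarity of a scale series
#'
#' Scale-averaged squared coefficient of variation of per-box mass
#' (moments taken over all grid boxes, empty boxes included):
#' `Lambda = mean over scales of (sd(eps) / mean(eps))^2`. Zero only for
#' translation-uniform mass.
#'
#' @inheritParams fit_dimension
#' @return Scalar `Lambda >= 0`.
#' @export
lacunarity <- function(series) {
  if (any(series$mean_mass <= 0)) {
    abort("zero mean box mass at some scale: lacunarity undefined", class = "histofract_degenerate_error")
  }
  mean((series$sd_mass / series$mean_mass)^2)
}

#' Monofractal feature set for one image
#'
#' Computes the three monofractal features (fractal dimension, outline
#' fractal dimension, lacunarity) for both modalities:
#' \describe{
#'   \item{binary}{regular box counting on the thresholded mask, its outline,
#'     and lacunarity from the mask's box masses; `fd` in `[0, 2]`.}
#'   \item{grayscale}{differential box counting on the full grayscale image
#'     (`fd` in `[2, 3]` for non-degenerate surfaces) and on the image with
#'     non-outline pixels set to 0 for the outline variant; lacunarity from
#'     the DBC box contributions.}
#' }
#'
#' @param gray A [gray_image()].
#' @param bin A [bin_image()]; defaults to [binarize()] of `gray`.
#' @param outline An `outline_image`; defaults to [extract_outline()] of `bin`.
#' @param scales Box edge lengths; defaults to [make_scales()].
#' @return Tibble with one row per modality: `modality`, `fd`, `fd_outline`,
#'   `lacunarity`, `r2_fd`, `r2_fd_outline`.
#' @export
monofractal_features <- function(gray, bin = binarize(gray),
                                 outline = extract_outline(bin),
                                 scales = make_scales(dim(gray))) {
  bin_series <- box_counts_binary(bin, scales)
  out_series <- box_counts_binary(outline, scales)
  bfd <- fit_dimension(bin_series)
  ofd <- fit_dimension(out_series)

  gray_series <- dbc_counts_gray(gray, scales)
  masked <- unclass(gray)
  masked[!outline] <- 0L
  gray_out_series <- dbc_counts_gray(masked, scales)
  gfd <- fit_dimension(gray_series)
  gofd <- fit_dimension(gray_out_series)

  tibble(
    modality = c("binary", "grayscale"),
    fd = c(bfd$fd, gfd$fd),
    fd_outline = c(ofd$fd, gofd$fd),
    lacunarity = c(lacunarity(bin_series), lacunarity(gray_series)),
    r2_fd = c(bfd$r_squared, gfd$r_squared),
    r2_fd_outline = c(ofd$r_squared, gofd$r_squared)
  )
}
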