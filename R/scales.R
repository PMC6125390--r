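#' Box-size grid for box counting
#'
#' Powers of `base` (default 2) from `base` up to 45% of the smaller image
#' dimension. All grids are anchored at the top-left origin and partial boxes
#' at the right/bottom edges are included, so the cap keeps at least two
#' boxes per axis at the coarsest scale.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param base Geometric spacing of box sizes. The default 2 is used
#'   throughout the pipeline; base 3 is convenient for base-3 constructs
#'   such as the Sierpinski carpet.
#' @return Increasing integer vector of box edge lengths (>= 3 scales).
#' @export
make_scales <- function(shape, base = 2L) {
  cap <- floor(0.45 * min(shape))
  k <- floor(log(cap) / log(base))
  if (!is.finite(k) || k < 1) {
    abort("image too small for a box-counting scale series", class = "histofract_config_error")
  }
  scales <- as.integer(base^seq_len(k))
  if (length(scales) < 3L) {
    abort(
      sprintf(
        "image of %d x %d supports only %d box scales; at least 3 are needed",
        shape[1], shape[2], length(scales)
      ),
      class = "histofract_config_error"
    )
  }
  scales
}

# Block-wise reduction of a matrix over an origin-anchored eps x eps grid.
# Partial edge blocks are padded with the operation's identity, so they are
# included in the reduction. Vectorized: eps strided slices per axis.
block_reduce <- function(m, eps, op = c("sum", "max", "min")) {
  op <- match.arg(op)
  pad <- switch(op, sum = 0, max = -Inf, min = Inf)
  f <- switch(op, sum = `+`, max = pmax, min = pmin)
  reduce_rows <- function(x) {
    nr <- nrow(x)
    nb <- ceiling(nr / eps)
    nr2 <- nb * eps
    if (nr2 > nr) x <- rbind(x, matrix(pad, nr2 - nr, ncol(x)))
    out <- x[seq(1L, nr2, by = eps), , drop = FALSE]
    if (eps > 1) {
      for (k in 2:eps) out <- f(out, x[seq(k, nr2, by = eps), , drop = FALSE])
    }
    out
  }
  t(reduce_rows(t(reduce_rows(m))))
}

new_scale_series <- function(df, modality) {
  structure(df, class = c("scale_series", class(tibble())), modality = modality)
}

#' Regular box counting on a binary mask
#'
#' Tiles the mask with a non-overlapping, origin-anchored grid of
#' `eps x eps` boxes for every scale (partial boxes at the right/bottom
#' edges included) and records the number of non-empty boxes `N(eps)`,
#' the per-box foreground mass, and the mean and (population) standard
#' deviation of per-box mass over ALL boxes, empty ones included.
#'
#' @param bin A [bin_image()], `outline_image`, or logical matrix.
#' @param scales Box edge lengths; defaults to [make_scales()] of the shape.
#' @return A `scale_series` tibble with columns `scale`, `n_boxes` (total
#'   grid boxes), `count` (non-empty boxes), `mean_mass`, `sd_mass`, and a
#'   list-column `masses` holding the occupied boxes' masses.
#' @export
box_counts_binary <- function(bin, scales = make_scales(dim(bin))) {
  m <- matrix(as.numeric(bin), nrow(bin), ncol(bin))
  if (sum(m) == 0) {
    abort("empty mask: box-counting dimension is undefined", class = "histofract_degenerate_error")
  }
  rows <- purrr::map(scales, function(eps) {
    s <- block_reduce(m, eps, "sum")
    all_mass <- as.numeric(s)
    occ <- all_mass[all_mass > 0]
    tibble(
      scale = as.integer(eps),
      n_boxes = length(all_mass),
      count = length(occ),
      mean_mass = mean(all_mass),
      sd_mass = sqrt(max(0, mean(all_mass^2) - mean(all_mass)^2)),
      masses = list(occ)
    )
  })
  new_scale_series(dplyr::bind_rows(rows), modality = "binary")
}

#' Differential box counting on a grayscale image
#'
#' Sarkar-Chaudhuri scheme: intensity is treated as surface height. For box
#' size `eps`, the intensity axis is divided into cells of height
#' `h = eps * 256 / min(rows, cols)`; each `eps x eps` box contributes
#' `n = floor((max - min) / h) + 1` intensity cells, where max/min are the
#' box's extreme intensities. `N(eps)` is the sum of contributions, and the
#' per-box contribution serves as the box mass for lacunarity.
#'
#' @param img A [gray_image()] or integer matrix.
#' @param scales Box edge lengths; defaults to [make_scales()].
#' @return A `scale_series` tibble (see [box_counts_binary()]); here every
#'   box is occupied, so `count = sum of contributions` and `n_boxes` is the
#'   number of grid boxes.
#' @export
dbc_counts_gray <- function(img, scales = make_scales(dim(img))) {
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  side <- min(dim(m))
  rows <- purrr::map(scales, function(eps) {
    h <- eps * 256 / side
    bmax <- block_reduce(m, eps, "max")
    bmin <- block_reduce(m, eps, "min")
    n <- floor((as.numeric(bmax) - as.numeric(bmin)) / h) + 1
    tibble(
      scale = as.integer(eps),
      n_boxes = length(n),
      count = sum(n),
      mean_mass = mean(n),
      sd_mass = sqrt(max(0, mean(n^2) - mean(n)^2)),
      masses = list(n)
    )
  })
  new_scale_series(dplyr::bind_rows(rows), modality = "grayscale")
}

#' Box-mass series of a non-negative mass raster
#'
#' Generalization of [box_counts_binary()] to an arbitrary non-negative
#' measure on the pixel grid (e.g. inverted intensity `255 - I` so that
#' stain carries mass, or a multiplicative-cascade measure). Used by the
#' multifractal estimator.
#'
#' @param mass Non-negative numeric matrix.
#' @param scales Box edge lengths.
#' @return A `scale_series` tibble.
#' @export
box_mass_series <- function(mass, scales = make_scales(dim(mass))) {
  mass <- as.matrix(mass)
  if (any(mass < 0)) abort("mass raster must be non-negative", class = "histofract_format_error")
  if (sum(mass) == 0) {
    abort("zero total mass: measure is degenerate", class = "histofract_degenerate_error")
  }
  rows <- purrr::map(scales, function(eps) {
    s <- block_reduce(mass, eps, "sum")
    all_mass <- as.numeric(s)
    occ <- all_mass[all_mass > 0]
    tibble(
      scale = as.integer(eps),
      n_boxes = length(all_mass),
      count = length(occ),
      mean_mass = mean(all_mass),
      sd_mass = sqrt(max(0, mean(all_mass^2) - mean(all_mass)^2)),
      masses = list(occ)
    )
  })
  new_scale_series(dplyr::bind_rows(rows), modality = "mass")
}
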