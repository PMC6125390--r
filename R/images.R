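#' Image containers
#'
#' Light S3 wrappers around plain matrices. A `gray_image` is an integer
#' matrix of 8-bit intensities (0 = black/fully stained, 255 = white) with a
#' physical `pixel_size` attribute in micrometres per pixel edge. A
#' `bin_image` is a logical matrix where `TRUE` marks stained foreground,
#' which by the dark-stain convention corresponds to LOW grayscale intensity.
#' An `outline_image` is a logical matrix of contour pixels.
#'
#' @param pixels Integer matrix with values in `[0, 255]`, at least 8 rows
#'   and 8 columns.
#' @param pixel_size Physical edge length of one pixel in micrometres.
#'   The default 0.145 corresponds to the 145 nm pixels of a 40x
#'   high-resolution slide scan.
#' @return `gray_image()` returns the matrix with class `gray_image`;
#'   `bin_image()` the logical matrix with class `bin_image`.
#' @export
gray_image <- function(pixels, pixel_size = 0.145) {
  pixels <- as_raster_int(pixels)
  if (any(pixels < 0L | pixels > 255L)) {
    abort("gray_image intensities must lie in [0, 255]", class = "histofract_format_error")
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    abort("gray_image must be at least 8 x 8 pixels", class = "histofract_format_error")
  }
  structure(pixels, pixel_size = pixel_size, class = c("gray_image", class(pixels)))
}

#' @rdname gray_image
#' @param mask Logical matrix, `TRUE` = stained foreground.
#' @export
bin_image <- function(mask, pixel_size = 0.145) {
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(mask, pixel_size = pixel_size, class = c("bin_image", class(mask)))
}

as_raster_int <- function(pixels) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  if (is.double(pixels)) {
    if (any(abs(pixels - round(pixels)) > 1e-8)) {
      abort("intensities must be whole graylevels", class = "histofract_format_error")
    }
    storage.mode(pixels) <- "integer"
  }
  pixels
}

#' Pixel size accessor
#' @param x A `gray_image` or `bin_image`.
#' @return Micrometres per pixel edge (scalar).
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) 0.145 else ps
}

round_half_up <- function(x) floor(x + 0.5)

#' Read an image as an 8-bit single-channel grayscale raster
#'
#' Reads a PNG or TIFF image and reduces it to one 8-bit channel following
#' the ImageJ "8-bit" contract: a 3-channel (RGB) input is reduced by the
#' unweighted channel mean, rounded half-up and clamped to `[0, 255]`; a
#' single-channel 8-bit input passes through unchanged.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams gray_image
#' @return A [gray_image()].
#' @export
load_gray <- function(path, pixel_size = 0.145) {
  if (!file.exists(path)) {
    abort(paste0("cannot read image: ", path), class = "histofract_input_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      abort(paste0("unsupported image format: ", path), class = "histofract_format_error")
    ),
    error = function(e) {
      abort(paste0("cannot decode image: ", path), class = "histofract_input_error")
    }
  )
  vals <- arr * 255
  if (length(dim(vals)) == 2L) {
    gray <- round_half_up(vals)
  } else if (length(dim(vals)) == 3L && dim(vals)[3] == 3L) {
    gray <- round_half_up((vals[, , 1] + vals[, , 2] + vals[, , 3]) / 3)
  } else {
    abort(
      paste0("expected 1 or 3 channels in ", path, ", found ", dim(vals)[3]),
      class = "histofract_format_error"
    )
  }
  gray <- pmin(pmax(gray, 0), 255)
  gray_image(gray, pixel_size = pixel_size)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is serialized as 255, background as 0.
#'
#' @param mask A `bin_image` or logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' IsoData (iterative intermeans) threshold
#'
#' Computes the automatic threshold used by the ImageJ "Make Binary"
#' contract: starting from the image mean, iterate
#' `T <- floor((mean(I <= T) + mean(I > T)) / 2)` on the 256-bin histogram
#' until a fixed point is reached.
#'
#' @param img A `gray_image` or integer matrix.
#' @return Integer threshold in `[0, 254]`, or `NA` for a constant image.
#' @export
isodata_threshold <- function(img) {
  v <- as.integer(img)
  h <- tabulate(v + 1L, nbins = 256L)
  lev <- 0:255
  if (sum(h > 0) < 2L) return(NA_integer_)
  t_cur <- floor(sum(h * lev) / sum(h))
  if (t_cur >= 255L) t_cur <- 254L
  repeat {
    below <- h[lev <= t_cur]
    above <- h[lev > t_cur]
    mu0 <- sum(below * lev[lev <= t_cur]) / sum(below)
    mu1 <- sum(above * lev[lev > t_cur]) / sum(above)
    if (!is.finite(mu0)) mu0 <- mu1
    if (!is.finite(mu1)) mu1 <- mu0
    t_new <- floor((mu0 + mu1) / 2)
    if (t_new >= 255L) t_new <- 254L
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  as.integer(t_cur)
}

#' Binarize a grayscale image by automatic thresholding
#'
#' Thresholds with [isodata_threshold()] and applies the dark-stain
#' convention: foreground = pixels with intensity `<= T` (immunostain absorbs
#' light, so stained structures are dark). A constant image yields an empty
#' (all-background) mask.
#'
#' @param img A [gray_image()].
#' @return A [bin_image()] of the same shape.
#' @export
binarize <- function(img) {
  t_iso <- isodata_threshold(img)
  if (is.na(t_iso)) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
  } else {
    mask <- unclass(img) <= t_iso
  }
  bin_image(mask, pixel_size = pixel_size(img))
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Extract the outline (contour) of a binary mask
#'
#' A foreground pixel belongs to the outline when at least one of its
#' 4-neighbours is background; the image border counts as background. The
#' result is a subset of the parent foreground and forms closed 8-connected
#' contours.
#'
#' @param bin A [bin_image()].
#' @return A logical `outline_image` of the same shape.
#' @export
extract_outline <- function(bin) {
  m <- unclass(bin)
  storage.mode(m) <- "logical"
  bg <- !m
  near_bg <- shift_mat(bg, 1, 0, TRUE) | shift_mat(bg, -1, 0, TRUE) |
    shift_mat(bg, 0, 1, TRUE) | shift_mat(bg, 0, -1, TRUE)
  out <- m & near_bg
  structure(out, pixel_size = pixel_size(bin), class = c("outline_image", "bin_image", class(out)))
}
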