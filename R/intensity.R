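#' Mean pixel intensity
#'
#' Arithmetic mean of all grayscale pixel intensities over the entire image
#' (stained and unstained regions alike), in graylevel units `[0, 255]`.
#' Lower values indicate darker, i.e. more heavily stained, images.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @return Scalar mean graylevel.
#' @export
mean_intensity <- function(img) {
  mean(as.numeric(img))
}

#' Total stained area
#'
#' Counts every foreground pixel of a thresholded mask (no minimum particle
#' size filter) and converts to physical area using the pixel size.
#'
#' @param bin A [bin_image()].
#' @return One-row tibble with `total_area_px` and `total_area_um2`.
#' @export
total_area <- function(bin) {
  px <- sum(as.logical(bin))
  tibble(
    total_area_px = px,
    total_area_um2 = px * pixel_size(bin)^2
  )
}

#' Staining-intensity feature set
#'
#' The two intensity features of the pipeline: mean pixel intensity of the
#' grayscale image and total stained area of its thresholded mask.
#'
#' @param img A [gray_image()].
#' @param bin A [bin_image()]; defaults to [binarize()] of `img`.
#' @return One-row tibble: `mean_intensity`, `total_area_px`, `total_area_um2`.
#' @export
intensity_features <- function(img, bin = binarize(img)) {
  dplyr::bind_cols(tibble(mean_intensity = mean_intensity(img)), total_area(bin))
}
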