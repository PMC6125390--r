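#' Full feature vector for one image
#'
#' Runs preprocessing (thresholding, outline extraction) and computes the
#' complete 34-feature record: 2 staining-intensity features, 6 monofractal
#' features (binary and grayscale fd, outline fd, lacunarity) and 26
#' multifractal features (13 per modality, prefixed `bin_mf_` /
#' `gray_mf_`). Fit r-squared diagnostics and the physical stained area are
#' appended as non-feature columns.
#'
#' @param gray A [gray_image()].
#' @param q Moment orders for the multifractal spectra.
#' @return One-row tibble.
#' @export
extract_features <- function(gray, q = q_grid()) {
  bin <- binarize(gray)
  if (!any(bin)) {
    abort("thresholding produced an empty mask", class = "histofract_degenerate_error")
  }
  outline <- extract_outline(bin)
  scales <- make_scales(dim(gray))
  intens <- intensity_features(gray, bin)
  mono <- monofractal_features(gray, bin, outline, scales)
  mono_wide <- tibble(
    bin_fd = mono$fd[1], bin_fd_outline = mono$fd_outline[1],
    bin_lac = mono$lacunarity[1],
    gray_fd = mono$fd[2], gray_fd_outline = mono$fd_outline[2],
    gray_lac = mono$lacunarity[2]
  )
  mf <- multifractal_features(gray, bin, scales, q)
  feat_cols <- setdiff(names(mf), "modality")
  mf_bin <- setNames(mf[mf$modality == "binary", feat_cols], paste0("bin_mf_", feat_cols))
  mf_gray <- setNames(mf[mf$modality == "grayscale", feat_cols], paste0("gray_mf_", feat_cols))
  diag_cols <- tibble(
    total_area_um2 = intens$total_area_um2,
    r2_bin_fd = mono$r2_fd[1], r2_bin_fd_outline = mono$r2_fd_outline[1],
    r2_gray_fd = mono$r2_fd[2], r2_gray_fd_outline = mono$r2_fd_outline[2]
  )
  dplyr::bind_cols(
    intens[c("mean_intensity", "total_area_px")],
    mono_wide, mf_bin, mf_gray, diag_cols
  )
}

#' Names of the 34 feature columns produced by [extract_features()]
#' @return Character vector of length 34.
#' @export
feature_columns <- function() {
  mf <- c(
    "d_q0", "alpha_q0", "f_alpha_q0", "d_q_max", "f_alpha_min", "f_alpha_max",
    "alpha_at_f_min", "alpha_at_f_max", "slope_dq", "slope_alpha",
    "slope_falpha", "slope_dq_q13", "f_alpha_sum_qpos"
  )
  c(
    "mean_intensity", "total_area_px",
    "bin_fd", "bin_fd_outline", "bin_lac",
    "gray_fd", "gray_fd_outline", "gray_lac",
    paste0("bin_mf_", mf), paste0("gray_mf_", mf)
  )
}

#' Batch feature extraction over a directory or file list
#'
#' Loads each image, extracts the full feature record, and logs one JSON
#' record per event. Per-image failures (unreadable files, images below the
#' minimum size for a 3-point scale series, empty masks) are logged and
#' skipped; the run continues.
#'
#' @param input Directory containing PNG/TIFF images, or a character vector
#'   of file paths.
#' @param out_dir Optional output directory; if given, writes
#'   `features.csv` and `manifest.jsonl`.
#' @param pixel_size Micrometres per pixel.
#' @return Tibble with an `image` id column plus the feature columns.
#' @export
run_extract <- function(input, out_dir = NULL, pixel_size = 0.145) {
  paths <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE, full.names = TRUE)
  } else {
    input
  }
  if (length(paths) == 0L) {
    abort("no input images found", class = "histofract_input_error")
  }
  log_lines <- character(0)
  log_event <- function(...) {
    log_lines <<- c(log_lines, jsonlite::toJSON(list(...), auto_unbox = TRUE))
  }
  rows <- purrr::map(sort(paths), function(p) {
    id <- tools::file_path_sans_ext(basename(p))
    res <- tryCatch(
      {
        img <- load_gray(p, pixel_size = pixel_size)
        feats <- extract_features(img)
        log_event(
          event = "extracted", image = id,
          r2_bin_fd = feats$r2_bin_fd, r2_gray_fd = feats$r2_gray_fd
        )
        dplyr::bind_cols(tibble(image = id), feats)
      },
      error = function(e) {
        log_event(event = "skipped", image = id, reason = conditionMessage(e))
        NULL
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    abort("no image could be processed", class = "histofract_input_error")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "features.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "manifest.jsonl"))
  }
  out
}

#' Prognostic evaluation of an extracted feature table against a cohort
#'
#' Joins the per-image feature table to the cohort outcome table 1:1 on
#' `patient_id` and runs the full prognostic report (ROC, cutpoint, Cox,
#' multivariate selection, Spearman). Orphan ids on either side are an
#' error.
#'
#' @param features Tibble/data frame (or CSV path) with `patient_id` and
#'   feature columns.
#' @param cohort Tibble/data frame (or CSV path) with `patient_id`,
#'   `time_months`, `event` and optional covariates.
#' @param feature_cols Feature columns to evaluate; default: all numeric
#'   feature columns shared with [feature_columns()], else all numeric
#'   non-outcome columns of `features`.
#' @param n_boot,n_perm,seed Resampling controls (see
#'   [prognostic_report()]).
#' @param out_dir Optional directory; writes `report.csv`,
#'   `multivariate.json` and `spearman.csv`.
#' @return An `hf_report`.
#' @export
run_prognosis <- function(features, cohort, feature_cols = NULL,
                          n_boot = 1000L, n_perm = 200L, seed = 1L,
                          out_dir = NULL) {
  if (is.character(features) && length(features) == 1L) features <- read.csv(features)
  if (is.character(cohort) && length(cohort) == 1L) cohort <- read.csv(cohort)
  features <- as_tibble(features)
  cohort <- as_tibble(cohort)
  if (!"patient_id" %in% names(features) || !"patient_id" %in% names(cohort)) {
    abort("both tables need a patient_id column", class = "histofract_input_error")
  }
  orphans <- c(
    setdiff(features$patient_id, cohort$patient_id),
    setdiff(cohort$patient_id, features$patient_id)
  )
  if (length(orphans) > 0L) {
    abort(
      paste0("feature/cohort tables do not join 1:1; orphan ids: ",
        paste(orphans, collapse = ", ")
      ),
      class = "histofract_input_error"
    )
  }
  data <- dplyr::inner_join(cohort, features, by = "patient_id")
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_columns(), names(features))
    if (length(feature_cols) == 0L) {
      feature_cols <- setdiff(
        names(features)[vapply(features, is.numeric, logical(1))],
        c("time_months", "event")
      )
    }
  }
  rep <- prognostic_report(
    data, feature_cols,
    n_boot = n_boot, n_perm = n_perm, seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep$features, file.path(out_dir, "report.csv"), row.names = FALSE)
    multi <- if (is.null(rep$multivariate)) list() else list(
      selected = rep$multivariate$selected,
      coefficients = tidy(rep$multivariate),
      seed = seed
    )
    jsonlite::write_json(multi, file.path(out_dir, "multivariate.json"),
      auto_unbox = TRUE, digits = NA
    )
    write.csv(rep$spearman$rho, file.path(out_dir, "spearman.csv"))
  }
  rep
}
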