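#' Locate the iris in one eye region
#'
#' Runs the per-eye chain: Gaussian smoothing, grayscale conversion, Otsu
#' binarization, HSV dark masking, mask combination, seed search, connected
#' component extraction, limbus sampling, and the least-squares circle fit.
#'
#' @param eye An `eye_region` from [extract_eye_regions()].
#' @param seg_cfg A [segmentation_config()].
#' @param row_fraction Passed to [sample_limbus()].
#' @param keep_masks Keep intermediate images in the result (for debugging).
#' @return A list: `fit` ([fit_circle()] result, crop-local),
#'   `center_source` (pupil center in source-image coordinates), `samples`,
#'   `diagnostics` (Otsu threshold, HSV V bound, combination variant used,
#'   seed, component size), and optionally `masks`.
#' @export
locate_iris <- function(eye, seg_cfg = segmentation_config(),
                        row_fraction = 1, keep_masks = FALSE) {
  smoothed <- with_stage("segmentation", smooth(eye$image, seg_cfg))
  gray <- to_gray(smoothed)
  t <- otsu_threshold(gray)
  otsu <- binarize(gray, t)
  hsv <- hsv_dark_mask(smoothed, gray, seg_cfg)
  combined <- with_stage("segmentation", combine_masks(otsu, hsv, seg_cfg))
  seed <- with_stage("iris-location", find_seed(combined))
  comp <- with_stage("iris-location", iris_component(combined, seed))
  samples <- with_stage("iris-location", sample_limbus(comp, row_fraction))
  fit <- with_stage("circle-fit", fit_circle(samples))
  out <- list(
    fit = fit,
    center_source = unname(fit$center) + unname(eye$offset) - 1,
    samples = samples,
    diagnostics = list(
      otsu_threshold = t,
      hsv_v_upper = attr(hsv, "v_upper"),
      combine_used = attr(combined, "combine_used"),
      seed = seed,
      component_size = comp$size,
      n_samples = fit$n_samples,
      offset = eye$offset
    )
  )
  if (keep_masks) {
    out$masks <- list(gray = gray, otsu = otsu, hsv = hsv, combined = combined)
  }
  out
}

#' Screen a single frontal image for strabismus
#'
#' Full pipeline: landmark ingestion (file or detection backend), eye-region
#' extraction, iris segmentation and circle fit for both eyes, canthus
#' distances and the positional similarity statistic S.
#'
#' @param image RGB array or path to a PNG/JPEG file.
#' @param landmarks A [landmark_set()], a path to a `.pts`/JSON landmark file,
#'   or `NULL` to invoke the detection backend (see [detect_landmarks()]).
#' @param cfg A [pipeline_config()].
#' @param seg_cfg A [segmentation_config()].
#' @param keep_masks Keep intermediate masks in the diagnostics.
#' @return A `screening_result` (see [positional_similarity()]) whose
#'   `diagnostics` element carries the per-eye intermediate quantities.
#' @export
screen_image <- function(image, landmarks = NULL,
                         cfg = pipeline_config(),
                         seg_cfg = segmentation_config(),
                         keep_masks = FALSE) {
  if (is.character(image)) image <- with_stage("input", read_image(image))
  stopifnot_rgb(image)
  lms <- if (is.null(landmarks)) {
    with_stage("landmark-detection",
               detect_landmarks(image, pipeline_config(
                 expansion_px = cfg$expansion_px,
                 resize_factor = cfg$resize_factor,
                 landmark_backend = "pretrained",
                 classification_threshold = cfg$classification_threshold,
                 random_seed = cfg$random_seed)))
  } else if (is.character(landmarks)) {
    with_stage("landmark-input", load_landmarks(landmarks))
  } else {
    landmarks
  }
  regions <- with_stage("eye-extraction", extract_eye_regions(image, lms, cfg))

  measure <- function(eye) {
    loc <- locate_iris(eye, seg_cfg, keep_masks = keep_masks)
    med <- unname(eye$medial_canthus) + unname(eye$offset) - 1
    lat <- unname(eye$lateral_canthus) + unname(eye$offset) - 1
    m <- with_stage("similarity",
                    eye_measurement(eye$side, loc$center_source, lat, med))
    list(measurement = m, location = loc)
  }
  r <- measure(regions$right)
  l <- measure(regions$left)
  res <- with_stage("similarity",
                    positional_similarity(r$measurement, l$measurement,
                                          cfg$classification_threshold))
  res$diagnostics <- list(right = r$location, left = l$location)
  res$config <- list(pipeline = unclass(cfg), segmentation = unclass(seg_cfg))
  res
}

#' Screen two cohorts of images and compare them
#'
#' Every image in each directory is screened (landmarks are read from a
#' sibling file with the same basename and extension `.pts` or `.json`), and
#' the two groups of S values are compared with the one-sided Mann-Whitney
#' test of [mann_whitney_one_sided()].
#'
#' @param normal_dir,strab_dir Directories of PNG/JPEG images, each with
#'   per-image landmark files.
#' @param alpha Significance level (default 0.001).
#' @param cfg,seg_cfg Pipeline and segmentation configurations.
#' @return A list: `per_image` (data frame with path, group, S, label),
#'   `stats` (a `cohort_stats`).
#' @export
screen_cohort <- function(normal_dir, strab_dir, alpha = 0.001,
                          cfg = pipeline_config(),
                          seg_cfg = segmentation_config()) {
  screen_dir <- function(dir, group) {
    imgs <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                       full.names = TRUE)
    if (length(imgs) == 0L) {
      strab_error(sprintf("no images found in %s group directory: %s", group, dir),
                  "io_error")
    }
    rows <- lapply(imgs, function(p) {
      lm_path <- find_landmark_file(p)
      res <- screen_image(p, landmarks = lm_path, cfg = cfg, seg_cfg = seg_cfg)
      data.frame(path = p, group = group, S = res$S, label = res$label,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  per_image <- rbind(screen_dir(normal_dir, "normal"),
                     screen_dir(strab_dir, "strabismus"))
  stats <- mann_whitney_one_sided(per_image$S[per_image$group == "normal"],
                                  per_image$S[per_image$group == "strabismus"],
                                  alpha = alpha)
  list(per_image = per_image, stats = stats)
}

#' @noRd
find_landmark_file <- function(image_path) {
  base <- tools::file_path_sans_ext(image_path)
  for (ext in c(".pts", ".json")) {
    cand <- paste0(base, ext)
    if (file.exists(cand)) return(cand)
  }
  NULL  # fall back to the detection backend
}
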