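#' Pipeline configuration
#'
#' Bundles the tunable parameters of the screening pipeline.
#'
#' @param expansion_px Non-negative integer; the eye-region rectangle derived
#'   from the landmarks is expanded by this many pixels on every side before
#'   cropping (default 10), so that slightly misplaced landmarks still yield a
#'   complete eye region.
#' @param resize_factor Factor in (0, 1] by which the input image is downscaled
#'   before being passed to a face/landmark detection backend (default 1/2);
#'   detected coordinates are rescaled back, and all downstream processing runs
#'   at the original resolution.
#' @param landmark_backend Either `"file"` (landmarks are supplied as a `.pts`
#'   or JSON file / `landmark_set`) or `"pretrained"` (a registered detection
#'   backend is invoked, see [detect_landmarks()]).
#' @param classification_threshold Positive similarity cutoff (>= 1): images
#'   with S above it are labelled `suspect-strabismus` (default 1.2, between
#'   the ranges observed for normal and strabismic eyes).
#' @param random_seed Integer seed used by any stochastic helper.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(expansion_px = 10L,
                            resize_factor = 1 / 2,
                            landmark_backend = c("file", "pretrained"),
                            classification_threshold = 1.2,
                            random_seed = 1L) {
  landmark_backend <- match.arg(landmark_backend)
  if (expansion_px < 0) {
    strab_error("expansion_px must be >= 0", "configuration_error")
  }
  if (resize_factor <= 0 || resize_factor > 1) {
    strab_error("resize_factor must be in (0, 1]", "configuration_error")
  }
  if (classification_threshold < 1) {
    strab_error("classification_threshold must be >= 1", "configuration_error")
  }
  structure(
    list(
      expansion_px = as.integer(expansion_px),
      resize_factor = resize_factor,
      landmark_backend = landmark_backend,
      classification_threshold = classification_threshold,
      random_seed = as.integer(random_seed)
    ),
    class = "pipeline_config"
  )
}

#' Construct a 68-point facial landmark set
#'
#' Landmarks follow the iBUG 68-point layout, 1-based index order: points
#' 37-42 ring the subject's right eye and 43-48 the left eye. Coordinates are
#' 1-based pixel positions (x = column, y = row, y increasing downward).
#'
#' @param points A 68 x 2 numeric matrix (columns x, y) in index order.
#' @param source_size Optional `c(width, height)` of the image the coordinates
#'   refer to; when given, coordinates are clamped into the image.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, source_size = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L) {
    strab_error(sprintf("expected 68 landmarks with 2 coordinates, got %d x %d",
                        nrow(points), ncol(points)), "cardinality_error")
  }
  if (!all(is.finite(points))) {
    strab_error("landmark coordinates must all be finite", "parse_error")
  }
  if (!is.null(source_size)) {
    points[, 1] <- pmin(pmax(points[, 1], 1), source_size[1])
    points[, 2] <- pmin(pmax(points[, 2], 1), source_size[2])
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, source_size = source_size),
            class = "landmark_set")
}

#' Read facial landmarks from a .pts or JSON file
#'
#' Supports the iBUG `.pts` dialect (optional `version:` line, `n_points:`
#' line, brace-delimited `x y` pairs in 1-based index order) and a JSON array
#' of 68 `[x, y]` pairs.
#'
#' @param path Path to the landmark file.
#' @param format `"pts"`, `"json"`, or `"auto"` (by file extension).
#' @return A [landmark_set()].
#' @export
load_landmarks <- function(path, format = c("auto", "pts", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    strab_error(sprintf("landmark file not found: %s", path), "io_error")
  }
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "pts"
  }
  if (format == "json") {
    pts <- tryCatch(jsonlite::fromJSON(path),
                    error = function(e) strab_error(
                      sprintf("malformed JSON landmark file %s: %s",
                              path, conditionMessage(e)), "parse_error"))
    pts <- as.matrix(pts)
    return(landmark_set(pts))
  }
  lines <- readLines(path, warn = FALSE)
  parse_pts(lines, path)
}

#' @noRd
parse_pts <- function(lines, path = "<pts>") {
  n_declared <- NA_integer_
  coords <- list()
  in_body <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^version:", ln)) next
    if (grepl("^n_points:", ln)) {
      n_declared <- suppressWarnings(as.integer(sub("^n_points:\\s*", "", ln)))
      if (is.na(n_declared)) {
        strab_error(sprintf("%s line %d: unreadable n_points: '%s'",
                            path, i, lines[i]), "parse_error")
      }
      next
    }
    if (ln == "{") { in_body <- TRUE; next }
    if (ln == "}") { in_body <- FALSE; next }
    if (!in_body) {
      strab_error(sprintf("%s line %d: unexpected content outside braces: '%s'",
                          path, i, lines[i]), "parse_error")
    }
    xy <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(xy) != 2L || anyNA(xy)) {
      strab_error(sprintf("%s line %d: expected 'x y', got '%s'",
                          path, i, lines[i]), "parse_error")
    }
    coords[[length(coords) + 1L]] <- xy
  }
  pts <- do.call(rbind, coords)
  n <- if (is.null(pts)) 0L else nrow(pts)
  if (!is.na(n_declared) && n_declared != n) {
    strab_error(sprintf("%s: declares %d points but contains %d",
                        path, n_declared, n), "cardinality_error")
  }
  if (n != 68L) {
    strab_error(sprintf("%s: expected 68 landmarks, found %d", path, n),
                "cardinality_error")
  }
  landmark_set(pts)
}

#' Write a landmark set to a .pts or JSON file
#'
#' @param lms A [landmark_set()].
#' @param path Output path.
#' @param format `"pts"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lms, path, format = c("pts", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unname(lms$points), path, digits = NA)
  } else {
    body <- sprintf("%.6f %.6f", lms$points[, 1], lms$points[, 2])
    writeLines(c("version: 1", "n_points:  68", "{", body, "}"), path)
  }
  invisible(path)
}

#' Extract the two eye regions from a facial image
#'
#' The subject's right-eye rectangle runs from upper-left
#' `(x37 - e, y38 - e)` to lower-right `(x40 + e, y41 + e)` where `e` is
#' `cfg$expansion_px`; the left eye analogously uses landmarks 43/44 and
#' 46/47. Rectangles are clamped to the image. Canthus points: for the right
#' eye landmark 37 is the lateral (temple-side) and 40 the medial (nose-side)
#' canthus; for the left eye 43 is medial and 46 lateral.
#'
#' @param image RGB array (see [read_image()]).
#' @param lms A [landmark_set()] in this image's coordinates.
#' @param cfg A [pipeline_config()].
#' @return A list with elements `right` and `left`, each an `eye_region`:
#'   `image` (the crop), `offset` (`c(x0, y0)`, 1-based position of the crop's
#'   first pixel in the source image), `side`, and `medial_canthus` /
#'   `lateral_canthus` in crop-local coordinates (source coordinate =
#'   crop-local + offset - 1).
#' @export
extract_eye_regions <- function(image, lms, cfg = pipeline_config()) {
  stopifnot_rgb(image)
  p <- lms$points
  right <- crop_eye(image, p,
                    start = c(p[37, 1], p[38, 2]), end = c(p[40, 1], p[41, 2]),
                    lateral = p[37, ], medial = p[40, ],
                    side = "right", e = cfg$expansion_px)
  left <- crop_eye(image, p,
                   start = c(p[43, 1], p[44, 2]), end = c(p[46, 1], p[47, 2]),
                   medial = p[43, ], lateral = p[46, ],
                   side = "left", e = cfg$expansion_px)
  list(right = right, left = left)
}

#' @noRd
crop_eye <- function(image, p, start, end, medial, lateral, side, e) {
  W <- img_width(image); H <- img_height(image)
  x0 <- max(1L, as.integer(floor(start[1])) - e)
  y0 <- max(1L, as.integer(floor(start[2])) - e)
  x1 <- min(W, as.integer(ceiling(end[1])) + e)
  y1 <- min(H, as.integer(ceiling(end[2])) + e)
  if (x1 < x0 || y1 < y0) {
    strab_error(sprintf(
      "%s eye rectangle [%d,%d]x[%d,%d] is empty after clamping to %dx%d image",
      side, x0, x1, y0, y1, W, H), "extraction_error")
  }
  offset <- c(x = x0, y = y0)
  to_local <- function(pt) {
    loc <- unname(pt) - offset + 1
    c(x = min(max(loc[1], 1), x1 - x0 + 1), y = min(max(loc[2], 1), y1 - y0 + 1))
  }
  structure(
    list(
      image = image[y0:y1, x0:x1, , drop = FALSE],
      offset = offset,
      side = side,
      medial_canthus = to_local(medial),
      lateral_canthus = to_local(lateral)
    ),
    class = "eye_region"
  )
}

#' Detect 68 facial landmarks via a pluggable pretrained backend
#'
#' No detector ships with this package; a backend (for instance a wrapper
#' around an external face-alignment tool) is registered as
#' `options(strabscreen.landmark_backend = function(image) ...)`. The backend
#' receives the image downscaled by `cfg$resize_factor` (detection at reduced
#' resolution keeps the memory footprint of CNN-style detectors down) and must
#' return a list with one 68 x 2 coordinate matrix per detected face, in the
#' downscaled frame. Coordinates are rescaled to the original resolution.
#'
#' @param image RGB array.
#' @param cfg A [pipeline_config()] with `landmark_backend = "pretrained"`.
#' @param backend Optional backend function, overriding the option.
#' @return A [landmark_set()] at the original image resolution.
#' @export
detect_landmarks <- function(image, cfg = pipeline_config(landmark_backend = "pretrained"),
                             backend = NULL) {
  stopifnot_rgb(image)
  if (is.null(backend)) backend <- getOption("strabscreen.landmark_backend")
  if (cfg$landmark_backend != "pretrained" || !is.function(backend)) {
    strab_error(paste(
      "no pretrained face/landmark backend is registered;",
      "supply a landmark file (.pts or JSON) instead, or register one via",
      "options(strabscreen.landmark_backend = <function>)"),
      "configuration_error")
  }
  f <- cfg$resize_factor
  small <- resize_image(image, f)
  faces <- backend(small)
  if (!is.list(faces)) faces <- list(faces)
  if (length(faces) != 1L) {
    strab_error(sprintf("expected exactly one face, backend detected %d",
                        length(faces)), "detection_error", n_faces = length(faces))
  }
  pts <- as.matrix(faces[[1]]) / f
  landmark_set(pts, source_size = c(img_width(image), img_height(image)))
}

# Nearest-neighbour downscale; adequate for detector input.
#' @noRd
resize_image <- function(image, factor) {
  if (factor == 1) return(image)
  H <- img_height(image); W <- img_width(image)
  h2 <- max(1L, as.integer(round(H * factor)))
  w2 <- max(1L, as.integer(round(W * factor)))
  ri <- pmin(H, pmax(1L, as.integer(round((seq_len(h2) - 0.5) / factor + 0.5))))
  ci <- pmin(W, pmax(1L, as.integer(round((seq_len(w2) - 0.5) / factor + 0.5))))
  image[ri, ci, , drop = FALSE]
}
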