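#' Read an 8-bit RGB image
#'
#' Reads a PNG or JPEG file into the array representation used throughout the
#' package: a `height x width x 3` numeric array of 8-bit intensities in
#' `[0, 255]`. Grayscale files are replicated across channels and an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A `height x width x 3` array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    strab_error(sprintf("image file not found: %s", path), "io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw01 <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    strab_error(sprintf("unsupported image format '.%s' (PNG/JPEG only): %s",
                        ext, path), "io_error")
  )
  as_rgb255(raw01 * 255)
}

#' Write an image or mask as PNG
#'
#' @param img A `height x width x 3` RGB array or a 2-D matrix (gray image or
#'   binary mask), values in `[0, 255]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), target = path)
  invisible(path)
}

# Coerce any readPNG/readJPEG result (gray matrix, RGB, RGBA) already scaled
# to [0, 255] into an integer-valued H x W x 3 array.
#' @noRd
as_rgb255 <- function(x) {
  if (is.matrix(x)) {
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  }
  if (length(dim(x)) != 3L) {
    strab_error("expected a 2-D or 3-D image array", "io_error")
  }
  if (dim(x)[3] == 1L) {
    x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  } else if (dim(x)[3] >= 4L) {
    x <- x[, , 1:3, drop = FALSE]
  }
  storage.mode(x) <- "double"
  array(round_half_up(pmin(pmax(x, 0), 255)), dim = dim(x))
}

# round half away from zero (R's round() is banker's rounding)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
stopifnot_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    strab_error(sprintf("%s must be a height x width x 3 RGB array", what),
                "shape_error")
  }
}

#' @noRd
img_width <- function(img) dim(img)[2]
#' @noRd
img_height <- function(img) dim(img)[1]

# Run expr with a private RNG stream; the global .Random.seed is untouched.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
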