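#' Segmentation configuration
#'
#' @param gaussian_kernel Odd kernel size >= 3 for the pre-smoothing Gaussian
#'   (default 5).
#' @param gaussian_sigma Positive standard deviation in pixels; by default
#'   derived from the kernel size as `0.3 * ((k - 1) * 0.5 - 1) + 0.8`
#'   (= 1.1 for k = 5), the usual size-derived rule when only a kernel size is
#'   given.
#' @param hsv_lower Lower HSV bound, `c(h, s, v)` in the 8-bit dialect
#'   H in `[0, 180]`, S and V in `[0, 255]` (default `c(0, 0, 0)`, i.e. black).
#' @param hsv_upper_h,hsv_upper_s Upper hue/saturation bounds (defaults 180 and
#'   255: hue and saturation unrestricted, so the mask keys on darkness only).
#' @param hsv_upper_v_mode `"mean_gray"` (default): the upper brightness bound
#'   is the mean gray level of the whole eye crop, adapting to illumination;
#'   or `"fixed"` to use `hsv_upper_v_fixed`.
#' @param hsv_upper_v_fixed Fixed upper V bound used when
#'   `hsv_upper_v_mode = "fixed"`.
#' @param combine_variant How the Otsu and HSV masks are combined (see
#'   [combine_masks()]): `"preserve_central"` (default) or `"literal"`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(gaussian_kernel = 5L,
                                gaussian_sigma = NULL,
                                hsv_lower = c(0, 0, 0),
                                hsv_upper_h = 180,
                                hsv_upper_s = 255,
                                hsv_upper_v_mode = c("mean_gray", "fixed"),
                                hsv_upper_v_fixed = 255,
                                combine_variant = c("preserve_central", "literal")) {
  hsv_upper_v_mode <- match.arg(hsv_upper_v_mode)
  combine_variant <- match.arg(combine_variant)
  k <- as.integer(gaussian_kernel)
  if (k < 3L || k %% 2L == 0L) {
    strab_error("gaussian_kernel must be an odd integer >= 3", "configuration_error")
  }
  if (is.null(gaussian_sigma)) {
    gaussian_sigma <- 0.3 * ((k - 1) * 0.5 - 1) + 0.8
  }
  if (gaussian_sigma <= 0) {
    strab_error("gaussian_sigma must be positive", "configuration_error")
  }
  if (hsv_upper_h < 0 || hsv_upper_h > 180 || hsv_upper_s < 0 || hsv_upper_s > 255 ||
      any(hsv_lower < 0) || hsv_lower[1] > 180 || any(hsv_lower[-1] > 255)) {
    strab_error("HSV bounds must satisfy H in [0,180], S and V in [0,255]",
                "configuration_error")
  }
  structure(
    list(
      gaussian_kernel = k,
      gaussian_sigma = gaussian_sigma,
      hsv_lower = hsv_lower,
      hsv_upper_h = hsv_upper_h,
      hsv_upper_s = hsv_upper_s,
      hsv_upper_v_mode = hsv_upper_v_mode,
      hsv_upper_v_fixed = hsv_upper_v_fixed,
      combine_variant = combine_variant
    ),
    class = "segmentation_config"
  )
}

#' Gaussian pre-smoothing of an eye crop
#'
#' Separable Gaussian convolution with reflective (mirror, edge not repeated)
#' border handling, applied to each RGB channel.
#'
#' @param crop RGB array.
#' @param cfg A [segmentation_config()].
#' @return Smoothed RGB array of the same shape.
#' @export
smooth <- function(crop, cfg = segmentation_config()) {
  stopifnot_rgb(crop)
  k <- cfg$gaussian_kernel
  if (img_height(crop) < k || img_width(crop) < k) {
    strab_error(sprintf("crop (%d x %d) smaller than the %dx%d Gaussian kernel",
                        img_height(crop), img_width(crop), k, k), "size_error")
  }
  w <- gaussian_kernel_1d(k, cfg$gaussian_sigma)
  out <- crop
  for (ch in 1:3) {
    out[, , ch] <- conv_separable(crop[, , ch], w)
  }
  out
}

#' @noRd
gaussian_kernel_1d <- function(k, sigma) {
  r <- (k - 1) / 2
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable 1-D convolution along rows then columns with reflect-101 padding
# (edge pixel not duplicated), the common default of image libraries.
#' @noRd
conv_separable <- function(m, w) {
  conv_cols(t(conv_cols(t(m), w)), w)
}

#' @noRd
conv_cols <- function(m, w) {
  r <- (length(w) - 1L) / 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(w)) {
    out <- out + w[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

#' Convert an RGB crop to an 8-bit gray image
#'
#' Uses the BT.601 luma weights `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer (half away from zero).
#'
#' @param crop RGB array.
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
to_gray <- function(crop) {
  stopifnot_rgb(crop)
  g <- round_half_up(0.299 * crop[, , 1] + 0.587 * crop[, , 2] + 0.114 * crop[, , 3])
  matrix(g, dim(crop)[1], dim(crop)[2])
}

#' Otsu's automatic threshold
#'
#' Returns the threshold `t` in `[0, 255]` maximizing the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2` over the 256-bin histogram, where class 0
#' holds the values `< t` and class 1 the values `>= t` (equivalently,
#' minimizing the within-class variance). Ties are broken toward the smallest
#' `t`. A constant image yields its constant value (with a warning), which
#' binarizes to an all-background mask.
#'
#' @param gray Integer-valued gray matrix in `[0, 255]`.
#' @return Integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(gray) {
  v <- as.vector(gray)
  if (length(v) == 0L) strab_error("empty image", "size_error")
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0L) == 1L) {
    warning("constant image: Otsu threshold degenerates to the constant value")
    return(as.integer(which(h > 0L) - 1L))
  }
  n <- length(v)
  lev <- 0:255
  cnt_lt <- c(0, cumsum(h))[1:256]          # pixels < t for t = 0..255
  sum_lt <- c(0, cumsum(h * lev))[1:256]
  w0 <- cnt_lt / n
  w1 <- 1 - w0
  mu0 <- ifelse(cnt_lt > 0, sum_lt / cnt_lt, 0)
  mu1 <- ifelse(n - cnt_lt > 0, (sum(h * lev) - sum_lt) / (n - cnt_lt), 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  as.integer(which.max(sigma_b) - 1L)
}

#' Binarize a gray image at a threshold
#'
#' Pixels strictly below `t` become 0 (foreground/dark), pixels at or above `t`
#' become 255 (background).
#'
#' @param gray Gray matrix.
#' @param t Threshold in `[0, 255]` (values above 255 mark everything dark).
#' @return A binary mask matrix over `{0, 255}`.
#' @export
binarize <- function(gray, t) {
  m <- matrix(255, nrow(gray), ncol(gray))
  m[gray < t] <- 0
  m
}

#' HSV dark-pixel mask
#'
#' Converts the crop to HSV (8-bit dialect: H in `[0, 180]`, S and V in
#' `[0, 255]`) and marks pixels whose components fall componentwise within
#' `[hsv_lower, upper]` as dark (0), the rest as 255. The upper bound is
#' `(hsv_upper_h, hsv_upper_s, v)` where `v` is the rounded mean of the gray
#' crop under the default `mean_gray` mode: everything darker than the crop's
#' average brightness — iris, eyelash shadows — is flagged.
#'
#' @param crop RGB array.
#' @param gray Matching gray image (used for the adaptive V bound).
#' @param cfg A [segmentation_config()].
#' @return A binary mask; attribute `v_upper` records the V bound used.
#' @export
hsv_dark_mask <- function(crop, gray, cfg = segmentation_config()) {
  stopifnot_rgb(crop)
  if (!all(dim(gray) == dim(crop)[1:2])) {
    strab_error("crop and gray image shapes differ", "shape_error")
  }
  v_up <- if (cfg$hsv_upper_v_mode == "mean_gray") {
    round_half_up(mean(gray))
  } else {
    cfg$hsv_upper_v_fixed
  }
  hsv <- grDevices::rgb2hsv(
    r = as.vector(crop[, , 1]), g = as.vector(crop[, , 2]),
    b = as.vector(crop[, , 3]), maxColorValue = 255
  )
  h <- hsv[1, ] * 180
  s <- hsv[2, ] * 255
  v <- hsv[3, ] * 255
  lo <- cfg$hsv_lower
  dark <- h >= lo[1] & h <= cfg$hsv_upper_h &
    s >= lo[2] & s <= cfg$hsv_upper_s &
    v >= lo[3] & v <= v_up
  m <- matrix(255, nrow(gray), ncol(gray))
  m[matrix(dark, nrow(gray), ncol(gray))] <- 0
  attr(m, "v_upper") <- v_up
  m
}

#' Combine the Otsu and HSV masks by a per-column scan
#'
#' The `literal` variant implements the published rule verbatim: in each
#' column, find the first (topmost) dark row of the HSV mask and overwrite the
#' Otsu mask from that row down to the bottom with 255 (background); columns
#' with no dark HSV pixel are untouched. Its top/bottom `mirror` instead
#' whitens from the top down to the last dark HSV row. Because the HSV dark
#' mask normally contains the iris itself, either orientation can erase a
#' centrally located iris; the default `preserve_central` variant therefore
#' evaluates both orientations and keeps whichever retains the larger
#' 8-connected dark component at the crop center — falling back to the
#' unmodified Otsu mask when neither retains any central dark component.
#' In every variant the dark pixels of the result are a subset of the Otsu
#' mask's dark pixels.
#'
#' @param otsu,hsv Binary masks of identical shape.
#' @param cfg A [segmentation_config()]; `cfg$combine_variant` selects the
#'   behaviour.
#' @return A binary mask; attribute `combine_used` records which orientation
#'   was applied (`"literal"`, `"mirror"`, or `"otsu_fallback"`).
#' @export
combine_masks <- function(otsu, hsv, cfg = segmentation_config()) {
  if (!all(dim(otsu) == dim(hsv))) {
    strab_error("mask shapes differ", "shape_error")
  }
  if (cfg$combine_variant == "literal") {
    out <- combine_scan(otsu, hsv, "literal")
    attr(out, "combine_used") <- "literal"
    return(out)
  }
  lit <- combine_scan(otsu, hsv, "literal")
  mir <- combine_scan(otsu, hsv, "mirror")
  size_lit <- central_component_size(lit)
  size_mir <- central_component_size(mir)
  if (size_lit == 0 && size_mir == 0) {
    out <- otsu
    attr(out, "combine_used") <- "otsu_fallback"
  } else if (size_lit >= size_mir) {
    out <- lit
    attr(out, "combine_used") <- "literal"
  } else {
    out <- mir
    attr(out, "combine_used") <- "mirror"
  }
  out
}

#' @noRd
combine_scan <- function(otsu, hsv, orientation) {
  H <- nrow(otsu)
  out <- otsu
  for (c in seq_len(ncol(otsu))) {
    dark_rows <- which(hsv[, c] == 0)
    if (length(dark_rows) == 0L) next
    if (orientation == "literal") {
      out[min(dark_rows):H, c] <- 255
    } else {
      out[1:max(dark_rows), c] <- 255
    }
  }
  out
}

# Size of the 8-connected dark component containing (or seeded near) the
# crop-center pixel; 0 when the seed search fails.
#' @noRd
central_component_size <- function(mask) {
  seed <- tryCatch(find_seed(mask), strabscreen_error = function(e) NULL)
  if (is.null(seed)) return(0L)
  iris_component(mask, seed)$size
}
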