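# Independent brute-force oracles and small fixture helpers used across tests.

# Wrap a render_eye() result as the eye_region the pipeline consumes.
as_eye_region <- function(rendered) {
  structure(
    list(image = rendered$image, offset = c(x = 1, y = 1),
         side = rendered$truth$side,
         medial_canthus = rendered$truth$medial_canthus,
         lateral_canthus = rendered$truth$lateral_canthus),
    class = "eye_region"
  )
}

# Exhaustive-search Otsu oracle: for every candidate t, class means computed
# directly from the raw pixel values (no histogram shortcuts).
otsu_oracle <- function(gray) {
  v <- as.vector(gray)
  best_t <- 0L
  best <- -Inf
  for (t in 0:255) {
    lo <- v[v < t]
    hi <- v[v >= t]
    s <- if (length(lo) == 0L || length(hi) == 0L) 0 else {
      w0 <- length(lo) / length(v)
      w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }
    if (s > best + 1e-9) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

# Queue-based 8-connected flood fill, independent of the package's
# dilation-based component extraction. Returns (x, y) coordinates.
flood_oracle <- function(mask, seed) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  queue <- matrix(c(seed[2], seed[1]), ncol = 2)  # (row, col)
  seen[seed[2], seed[1]] <- TRUE
  out <- NULL
  while (nrow(queue) > 0) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    out <- rbind(out, p)
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= H && c >= 1 && c <= W && !seen[r, c] && mask[r, c] == 0) {
        seen[r, c] <- TRUE
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  cbind(x = out[, 2], y = out[, 1])
}

# Rasterized dark disc on a white mask.
disc_mask <- function(W, H, cx, cy, R) {
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  m <- matrix(255, H, W)
  m[(X - cx)^2 + (Y - cy)^2 <= R^2] <- 0
  m
}

# Points exactly on a circle (optionally an arc), for circle-fit tests.
circle_points <- function(n, cx, cy, R, arc = c(0, 2 * pi)) {
  th <- seq(arc[1], arc[2], length.out = n)
  cbind(x = cx + R * cos(th), y = cy + R * sin(th))
}

# Per-column literal combination oracle, straight from the printed rule.
combine_literal_oracle <- function(otsu, hsv) {
  H <- nrow(otsu)
  out <- otsu
  for (c in seq_len(ncol(otsu))) {
    first <- Inf
    for (r in seq_len(H)) {
      if (hsv[r, c] == 0) { first <- r; break }
    }
    if (is.finite(first)) out[first:H, c] <- 255
  }
  out
}

# Eq-1 profile objective: variance of sample distances about their mean.
circle_objective <- function(pts, a, b) {
  d <- sqrt((pts[, 1] - a)^2 + (pts[, 2] - b)^2)
  sum((d - mean(d))^2)
}

# A landmark set with prescribed eye-corner coordinates; all other points are
# parked on a benign diagonal inside the image.
landmarks_with_eyes <- function(W, H, right = NULL, left = NULL) {
  pts <- cbind(seq(10, min(W, 60), length.out = 68),
               seq(10, min(H, 60), length.out = 68))
  set_ring <- function(pts, idx, ring) {
    # ring: list(x_start, y_top, x_end, y_bottom) -> 6 iBUG-ordered points
    xs <- ring$x_start + (ring$x_end - ring$x_start) * c(1 / 3, 2 / 3)
    ym <- (ring$y_top + ring$y_bottom) / 2
    pts[idx, ] <- rbind(
      c(ring$x_start, ym), c(xs[1], ring$y_top), c(xs[2], ring$y_top),
      c(ring$x_end, ym), c(xs[2], ring$y_bottom), c(xs[1], ring$y_bottom))
    pts
  }
  if (!is.null(right)) pts <- set_ring(pts, 37:42, right)
  if (!is.null(left)) pts <- set_ring(pts, 43:48, left)
  landmark_set(pts)
}

# Plain skin-colored RGB array.
flat_image <- function(W, H, level = 200) {
  array(rep(level, H * W * 3), dim = c(H, W, 3))
}
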