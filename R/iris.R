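#' Find a seed pixel inside the iris
#'
#' The iris normally sits at the center of an eye crop, so the crop-center
#' pixel is tried first. If it is background, the center row is scanned
#' outward (alternating left/right at increasing offsets) for the first dark
#' pixel belonging to a horizontal dark run of length >= `min_run` — the run
#' requirement skips isolated noise pixels.
#'
#' @param mask Binary mask over `{0, 255}` (0 = dark).
#' @param min_run Minimum horizontal dark-run length (default 3).
#' @return `c(x, y)` of the seed pixel (1-based).
#' @export
find_seed <- function(mask, min_run = 3L) {
  H <- nrow(mask); W <- ncol(mask)
  if (H == 0L || W == 0L) strab_error("empty mask", "size_error")
  cx <- ceiling(W / 2); cy <- ceiling(H / 2)
  if (mask[cy, cx] == 0) return(c(x = cx, y = cy))
  row <- mask[cy, ] == 0
  run_len_at <- function(x) {
    l <- x; while (l > 1L && row[l - 1L]) l <- l - 1L
    r <- x; while (r < W && row[r + 1L]) r <- r + 1L
    r - l + 1L
  }
  for (off in seq_len(max(cx - 1L, W - cx))) {
    for (x in c(cx - off, cx + off)) {
      if (x >= 1L && x <= W && row[x] && run_len_at(x) >= min_run) {
        return(c(x = x, y = cy))
      }
    }
  }
  strab_error("no dark iris pixel found on the center row", "iris_not_found_error")
}

#' Extract the 8-connected dark component containing a seed
#'
#' @param mask Binary mask (0 = dark).
#' @param seed `c(x, y)` of a dark pixel.
#' @return A list of class `iris_component`: `coords` (n x 2 matrix of x, y),
#'   `mask` (logical membership matrix), `size`, `seed`, and `bottom` — the
#'   maximum-y member (leftmost on ties), the starting point of limbus
#'   sampling.
#' @export
iris_component <- function(mask, seed) {
  H <- nrow(mask); W <- ncol(mask)
  if (mask[seed[2], seed[1]] != 0) {
    strab_error("seed pixel is not dark", "iris_not_found_error")
  }
  dark <- mask == 0
  comp <- matrix(FALSE, H, W)
  comp[seed[2], seed[1]] <- TRUE
  repeat {
    grown <- comp | dilate8(comp)
    grown <- grown & dark
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  idx <- which(comp, arr.ind = TRUE)       # (row, col)
  coords <- cbind(x = idx[, 2], y = idx[, 1])
  ymax <- max(coords[, 2])
  bottom_x <- min(coords[coords[, 2] == ymax, 1])
  structure(
    list(coords = coords, mask = comp, size = nrow(coords),
         seed = seed, bottom = c(x = bottom_x, y = ymax)),
    class = "iris_component"
  )
}

# One-pixel 8-neighbourhood dilation of a logical matrix.
#' @noRd
dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-H, , drop = FALSE])
  horiz <- function(x) {
    cbind(x[, -1, drop = FALSE], FALSE) | cbind(FALSE, x[, -W, drop = FALSE])
  }
  vert <- up | down
  out | m | vert | horiz(m) | horiz(vert)
}

#' Sample limbus boundary pixels from an iris component
#'
#' Starting from the component's bottom-most row and moving upward, the
#' leftmost and rightmost component pixels of every occupied row are emitted
#' (a single point where they coincide). On an unoccluded iris these row
#' extrema trace the limbus — the iris/sclera border — and feed the circle
#' fit.
#'
#' @param component An [iris_component()].
#' @param row_fraction Use only the lowest `row_fraction` of occupied rows
#'   (default 1 = all rows); useful under heavy upper-lid occlusion.
#' @return A list of class `limbus_samples`: `points` (n x 2 matrix, ordered
#'   bottom-to-top, left before right), `seed`, `component_size`.
#' @export
sample_limbus <- function(component, row_fraction = 1) {
  coords <- component$coords
  rows <- sort(unique(coords[, 2]), decreasing = TRUE)
  if (row_fraction < 1) {
    rows <- rows[seq_len(max(3L, ceiling(length(rows) * row_fraction)))]
  }
  pts <- matrix(0, 0, 2)
  for (y in rows) {
    xs <- coords[coords[, 2] == y, 1]
    xl <- min(xs); xr <- max(xs)
    pts <- rbind(pts, c(xl, y))
    if (xr != xl) pts <- rbind(pts, c(xr, y))
  }
  if (nrow(pts) < 3L) {
    strab_error(sprintf("only %d limbus sample(s); need >= 3 to fit a circle",
                        nrow(pts)), "insufficient_samples_error")
  }
  colnames(pts) <- c("x", "y")
  structure(
    list(points = pts, seed = component$seed, component_size = component$size),
    class = "limbus_samples"
  )
}

#' Fit a circle to limbus samples by geometric least squares
#'
#' Estimates the pupil center `(a, b)` and iris radius `R` by minimizing
#' `sum_i (d_i - R)^2` with `d_i = sqrt((x_i - a)^2 + (y_i - b)^2)`, where `R`
#' is tied to the mean of the `d_i` at every evaluation (the radius is not
#' known in advance and is set to the mean sample distance). The profile
#' objective over `(a, b)` — the variance of the distances — is initialized
#' from the algebraic Kåsa fit and refined by damped Gauss–Newton iterations
#' to an objective-change tolerance of 1e-9.
#'
#' @param samples A [limbus_samples()] object or an n x 2 coordinate matrix
#'   (n >= 3, not all collinear).
#' @param max_iter Iteration cap (default 500).
#' @param tol Objective-change convergence tolerance (default 1e-9).
#' @return A list of class `iris_fit`: `center` (`c(a, b)`), `radius`,
#'   `residual` (RMS of `d_i - R`), `n_samples`, `objective`, `iterations`.
#' @export
fit_circle <- function(samples, max_iter = 500L, tol = 1e-9) {
  pts <- if (inherits(samples, "limbus_samples")) samples$points else as.matrix(samples)
  n <- nrow(pts)
  if (n < 3L) {
    strab_error("need at least 3 sample points", "insufficient_samples_error")
  }
  x <- pts[, 1]; y <- pts[, 2]
  # Kåsa algebraic fit: x^2 + y^2 = A x + B y + C, center (A/2, B/2)
  M <- cbind(x, y, 1)
  rhs <- x^2 + y^2
  sv <- svd(crossprod(M))$d
  if (min(sv) < max(sv) * 1e-12) {
    strab_error("samples are collinear; no finite circle fits them",
                "degenerate_geometry_error")
  }
  abc <- solve(crossprod(M), crossprod(M, rhs))
  center <- c(abc[1], abc[2]) / 2

  obj <- function(ab) {
    d <- sqrt((x - ab[1])^2 + (y - ab[2])^2)
    sum((d - mean(d))^2)
  }
  f <- obj(center)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- sqrt((x - center[1])^2 + (y - center[2])^2)
    d <- pmax(d, 1e-12)
    r <- d - mean(d)
    Ja <- (center[1] - x) / d
    Jb <- (center[2] - y) / d
    J <- cbind(Ja - mean(Ja), Jb - mean(Jb))
    step <- tryCatch(solve(crossprod(J), -crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (halving in 1:30) {
      cand <- center + lambda * as.vector(step)
      fc <- obj(cand)
      if (fc <= f) {
        improved <- TRUE
        delta <- f - fc
        center <- cand
        f <- fc
        break
      }
      lambda <- lambda / 2
    }
    if (!improved || delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter) {
    strab_error(sprintf(
      "circle fit did not converge in %d iterations (last center %.4f, %.4f, objective %.3e)",
      max_iter, center[1], center[2], f), "convergence_error",
      last_center = center, objective = f)
  }
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  R <- mean(d)
  structure(
    list(center = c(a = center[1], b = center[2]), radius = R,
         residual = sqrt(mean((d - R)^2)), n_samples = n,
         objective = f, iterations = iter),
    class = "iris_fit"
  )
}
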