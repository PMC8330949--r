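#' Specification of a synthetic eye-region fixture
#'
#' Describes one rendered eye crop with exact ground truth: a skin background,
#' an almond-shaped palpebral fissure of white sclera between two canthi, a
#' dark anti-aliased iris disc with a darker pupil core, optional upper-lid
#' occlusion, eyelash-shadow strokes above the lid, and additive Gaussian
#' noise. The canthi sit `5 * iris_radius` apart; the lid arcs open to
#' `1.25 * iris_radius` so the whole disc is visible when unoccluded.
#'
#' @param iris_radius Iris radius in pixels (default 20).
#' @param deviation_dx,deviation_dy Imposed displacement of the iris center
#'   from the fissure center, pixels; simulated strabismus.
#' @param side `"right"` or `"left"` (anatomical): decides which canthus is
#'   medial. The subject's right eye appears on the image's left, so its
#'   lateral (temple-side) canthus is the leftmost point.
#' @param skin_level,sclera_level,iris_level,pupil_level 8-bit base
#'   intensities (defaults 200, 245, 45, 20).
#' @param eyelid_occlusion Fraction of the iris diameter hidden from the top
#'   by the upper lid, in `[0, 0.5)`.
#' @param shadow_strength Eyelash-shadow darkness in `[0, 1]` (0 = none).
#' @param noise_sigma Additive Gaussian noise standard deviation, intensity
#'   levels.
#' @param width,height Crop size; defaults derived from the radius.
#' @param seed Integer seed; rendering is deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(iris_radius = 20,
                         deviation_dx = 0, deviation_dy = 0,
                         side = c("right", "left"),
                         skin_level = 200, sclera_level = 245,
                         iris_level = 45, pupil_level = 20,
                         eyelid_occlusion = 0, shadow_strength = 0,
                         noise_sigma = 0,
                         width = NULL, height = NULL, seed = 1L) {
  side <- match.arg(side)
  R <- iris_radius
  span <- round(5 * R)
  amp <- 1.25 * R
  if (is.null(width)) width <- span + 2L * (round(0.3 * R) + 4L) + 1L
  if (is.null(height)) height <- 2L * ceiling(amp) + 2L * (round(0.15 * R) + 4L)
  if (eyelid_occlusion < 0 || eyelid_occlusion >= 0.5) {
    strab_error("eyelid_occlusion must be in [0, 0.5)", "spec_error")
  }
  if (iris_level >= sclera_level) {
    strab_error("iris_level must be darker than sclera_level", "spec_error")
  }
  if (R < 3) strab_error("iris_radius must be >= 3 px", "spec_error")
  margin <- (width - span) / 2
  x_left <- round(margin)
  x_right <- x_left + span
  cy <- (height + 1) / 2
  center <- c(x = (x_left + x_right) / 2 + deviation_dx, y = cy + deviation_dy)
  if (center[1] + R < 1 || center[1] - R > width ||
      center[2] + R < 1 || center[2] - R > height) {
    strab_error("iris disc does not intersect the crop", "spec_error")
  }
  structure(
    list(iris_radius = R, deviation_dx = deviation_dx, deviation_dy = deviation_dy,
         side = side, skin_level = skin_level, sclera_level = sclera_level,
         iris_level = iris_level, pupil_level = pupil_level,
         eyelid_occlusion = eyelid_occlusion, shadow_strength = shadow_strength,
         noise_sigma = noise_sigma, width = as.integer(width),
         height = as.integer(height), seed = as.integer(seed),
         span = span, amp = amp, x_left = x_left, x_right = x_right,
         cy = cy, center = center),
    class = "fixture_spec"
  )
}

#' Render a synthetic eye crop with ground truth
#'
#' Deterministic given the spec (including its seed). The returned truth
#' record holds the exact iris center and radius, the canthus coordinates
#' with their medial/lateral roles, and the upper-lid occlusion line.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `image` (RGB array) and `truth` (`center`, `radius`,
#'   `medial_canthus`, `lateral_canthus`, `lid_y`, `side`, plus the fissure
#'   membership matrix `fissure` used for rasterization oracles).
#' @export
render_eye <- function(spec) {
  W <- spec$width; H <- spec$height
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  R <- spec$iris_radius
  cx <- spec$center[1]; cy_i <- spec$center[2]

  # base level map: skin
  level <- matrix(spec$skin_level, H, W)
  tint <- matrix(1L, H, W)  # 1 skin, 2 sclera, 3 iris, 4 lid, 5 shadow

  # almond fissure between the canthi: arcs amp * sin(pi u)^0.6
  u <- (X - spec$x_left) / spec$span
  open_ok <- u > 0 & u < 1
  arc <- matrix(0, H, W)
  arc[open_ok] <- spec$amp * sin(pi * u[open_ok])^0.6
  fissure <- open_ok & abs(Y - spec$cy) < arc
  level[fissure] <- spec$sclera_level
  tint[fissure] <- 2L

  # anti-aliased iris disc with pupil core, visible only inside the fissure
  dist <- sqrt((X - cx)^2 + (Y - cy_i)^2)
  alpha <- pmin(pmax(R + 0.5 - dist, 0), 1)
  ia <- fissure & alpha > 0
  level[ia] <- (1 - alpha[ia]) * level[ia] + alpha[ia] * spec$iris_level
  pup <- fissure & dist < 0.45 * R
  level[pup] <- spec$pupil_level
  tint[ia] <- 3L

  # upper-lid occlusion: lid covers fissure rows above the occlusion line
  lid_y <- NA_real_
  if (spec$eyelid_occlusion > 0) {
    lid_y <- cy_i - R + spec$eyelid_occlusion * 2 * R
    occ <- fissure & Y < lid_y
    level[occ] <- spec$skin_level * 0.92
    tint[occ] <- 4L
  }

  # eyelash shadows: short oblique strokes on the skin above the upper arc
  if (spec$shadow_strength > 0) {
    shadow_level <- spec$iris_level +
      (1 - spec$shadow_strength) * (spec$skin_level - spec$iris_level)
    anchors <- spec$x_left + round(spec$span * seq(0.2, 0.8, length.out = 6))
    len <- max(3L, round(0.45 * R))
    for (k in seq_along(anchors)) {
      xa <- anchors[k]
      ua <- (xa - spec$x_left) / spec$span
      ya <- floor(spec$cy - spec$amp * sin(pi * ua)^0.6) - 1L
      dir <- if (k %% 2L == 0L) 1L else -1L
      for (d in 0:len) {
        xx <- xa + dir * round(0.5 * d)
        yy <- ya - d
        if (xx >= 1L && xx <= W && yy >= 1L && !fissure[yy, xx]) {
          level[yy, xx] <- shadow_level
          tint[yy, xx] <- 5L
        }
      }
    }
  }

  # compose RGB with mild per-material tints, then add luminance noise
  tints <- rbind(
    skin   = c(1.00, 0.84, 0.72),
    sclera = c(1.00, 0.99, 0.97),
    iris   = c(1.10, 0.95, 0.85),
    lid    = c(1.00, 0.82, 0.70),
    shadow = c(1.00, 0.90, 0.84)
  )
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- level * matrix(tints[tint, ch], H, W)
  }
  if (spec$noise_sigma > 0) {
    nz <- with_seed(spec$seed, matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + nz
  }
  img <- array(round_half_up(pmin(pmax(img, 0), 255)), dim = dim(img))

  canthi <- list(left = c(x = spec$x_left, y = spec$cy),
                 right = c(x = spec$x_right, y = spec$cy))
  if (spec$side == "right") {
    lateral <- canthi$left; medial <- canthi$right
  } else {
    medial <- canthi$left; lateral <- canthi$right
  }
  list(
    image = img,
    truth = list(center = spec$center, radius = R,
                 medial_canthus = medial, lateral_canthus = lateral,
                 lid_y = lid_y, side = spec$side, fissure = fissure)
  )
}

#' Render a right/left fixture pair with its analytic similarity
#'
#' The analytic S is computed from the ground-truth geometry by the same
#' distance/ratio definitions the pipeline uses, so pipeline output can be
#' compared against a closed-form reference.
#'
#' @param right_spec,left_spec [fixture_spec()]s with `side = "right"` and
#'   `"left"`.
#' @return A list: `right`, `left` (each a [render_eye()] result),
#'   `ratios` (named per-eye ground-truth ratios), `S_analytic`.
#' @export
render_pair <- function(right_spec, left_spec) {
  if (right_spec$side != "right" || left_spec$side != "left") {
    strab_error("render_pair needs one 'right' and one 'left' spec", "spec_error")
  }
  r <- render_eye(right_spec)
  l <- render_eye(left_spec)
  rr <- truth_ratio(r$truth)
  rl <- truth_ratio(l$truth)
  list(right = r, left = l,
       ratios = c(right = rr, left = rl),
       S_analytic = max(rr, rl) / min(rr, rl))
}

#' @noRd
truth_ratio <- function(truth) {
  canthus_distance(truth$lateral_canthus, truth$center) /
    canthus_distance(truth$medial_canthus, truth$center)
}

#' Render a synthetic frontal face with 68 landmarks
#'
#' Pastes a right and a left rendered eye crop onto a skin canvas and builds a
#' full iBUG-style 68-point landmark set: the twelve eye points (37-48) are
#' placed exactly on the rendered canthi and lid arcs; the remaining points
#' (jaw, brows, nose, mouth) are plausible fillers, since only the eye indices
#' drive the pipeline.
#'
#' @param right_spec,left_spec [fixture_spec()]s for the two eyes.
#' @param gap Horizontal gap between the two eye crops, pixels (default one
#'   crop-width's quarter).
#' @return A list: `image`, `landmarks` ([landmark_set()]), `truth` (per-eye
#'   ground truth in face coordinates), `S_analytic`.
#' @export
render_face <- function(right_spec, left_spec, gap = NULL) {
  pair <- render_pair(right_spec, left_spec)
  wr <- right_spec$width; hr <- right_spec$height
  wl <- left_spec$width; hl <- left_spec$height
  if (is.null(gap)) gap <- round(wr / 4)
  hm <- 30L; vm <- 40L
  W <- hm + wr + gap + wl + hm
  H <- vm + max(hr, hl) + vm + 40L  # extra chin room for filler landmarks
  img <- array(0, dim = c(H, W, 3))
  skin <- c(1.00, 0.84, 0.72) * 180
  for (ch in 1:3) img[, , ch] <- skin[ch]
  off_r <- c(x = hm + 1L, y = vm + 1L)
  off_l <- c(x = hm + wr + gap + 1L, y = vm + 1L)
  img[off_r[2]:(off_r[2] + hr - 1), off_r[1]:(off_r[1] + wr - 1), ] <- pair$right$image
  img[off_l[2]:(off_l[2] + hl - 1), off_l[1]:(off_l[1] + wl - 1), ] <- pair$left$image

  to_face <- function(pt, off) unname(pt)[1:2] + unname(off) - 1
  eye_ring <- function(spec, off) {
    # 6 points: corner, two upper-lid, corner, two lower-lid (iBUG order)
    xs <- spec$x_left + spec$span * c(1 / 3, 2 / 3)
    lid <- function(x, sgn) {
      u <- (x - spec$x_left) / spec$span
      c(x, spec$cy + sgn * (spec$amp * sin(pi * u)^0.6 + 1))
    }
    rbind(
      to_face(c(spec$x_left, spec$cy), off),
      to_face(lid(xs[1], -1), off),
      to_face(lid(xs[2], -1), off),
      to_face(c(spec$x_right, spec$cy), off),
      to_face(lid(xs[2], 1), off),
      to_face(lid(xs[1], 1), off)
    )
  }
  pts <- matrix(NA_real_, 68, 2)
  pts[37:42, ] <- eye_ring(right_spec, off_r)
  pts[43:48, ] <- eye_ring(left_spec, off_l)

  # plausible fillers for the remaining indices
  cx <- W / 2
  eye_y <- vm + max(hr, hl) / 2
  jaw_t <- seq(pi, 2 * pi, length.out = 17)
  pts[1:17, ] <- cbind(cx + (W / 2 - 8) * cos(jaw_t),
                       eye_y - (H - eye_y - 8) * sin(jaw_t))
  brow_y <- max(4, vm - 12)
  pts[18:22, ] <- cbind(seq(off_r[1], off_r[1] + wr - 1, length.out = 5), brow_y)
  pts[23:27, ] <- cbind(seq(off_l[1], off_l[1] + wl - 1, length.out = 5), brow_y)
  nose_y0 <- eye_y + 6
  pts[28:31, ] <- cbind(cx, seq(nose_y0, nose_y0 + 24, length.out = 4))
  pts[32:36, ] <- cbind(seq(cx - 12, cx + 12, length.out = 5), nose_y0 + 30)
  mouth_y <- nose_y0 + 44
  mo <- seq(0, 2 * pi, length.out = 13)[1:12]
  pts[49:60, ] <- cbind(cx + 20 * cos(mo), mouth_y + 8 * sin(mo))
  mi <- seq(0, 2 * pi, length.out = 9)[1:8]
  pts[61:68, ] <- cbind(cx + 12 * cos(mi), mouth_y + 4 * sin(mi))
  pts[, 1] <- pmin(pmax(pts[, 1], 1), W)
  pts[, 2] <- pmin(pmax(pts[, 2], 1), H)

  truth <- list(
    right = within_face_truth(pair$right$truth, off_r),
    left = within_face_truth(pair$left$truth, off_l)
  )
  list(image = img, landmarks = landmark_set(pts, source_size = c(W, H)),
       truth = truth, S_analytic = pair$S_analytic)
}

#' @noRd
within_face_truth <- function(truth, off) {
  shift <- function(p) unname(p)[1:2] + unname(off) - 1
  list(center = shift(truth$center), radius = truth$radius,
       medial_canthus = shift(truth$medial_canthus),
       lateral_canthus = shift(truth$lateral_canthus),
       side = truth$side)
}

#' Generate a synthetic screening cohort
#'
#' Emulates a validation cohort of frontal images: `n_normal` subjects whose
#' iris positions carry only sub-pixel jitter (up to +/- 1 px) and `n_strab`
#' subjects with one eye horizontally displaced by a magnitude drawn uniformly
#' from `deviation_range` (side and direction random). Reproducible given
#' `seed`.
#'
#' @param n_normal,n_strab Group sizes (>= 1).
#' @param deviation_range `c(lo, hi)` displacement magnitudes in pixels.
#' @param seed Integer seed.
#' @param dir Optional output directory: writes one PNG + `.pts` + truth JSON
#'   per subject into `normal/` and `strabismus/` subdirectories (the layout
#'   [screen_cohort()] consumes) plus a top-level `manifest.csv`.
#' @param iris_radius,noise_sigma,eyelid_occlusion,shadow_strength Rendering
#'   parameters shared by all subjects (defaults 20 px, 4 levels, 0.10, 0.4 —
#'   a mildly degraded but clean frontal capture).
#' @param keep_images Return the rendered faces in memory (default `TRUE` when
#'   `dir` is `NULL`).
#' @return A list: `manifest` (data frame: id, group, deviation per eye,
#'   analytic S, file paths when written) and `faces` (list of [render_face()]
#'   results, when kept).
#' @export
generate_cohort <- function(n_normal, n_strab, deviation_range = c(5, 15),
                            seed = 1L, dir = NULL,
                            iris_radius = 20, noise_sigma = 4,
                            eyelid_occlusion = 0.10, shadow_strength = 0.4,
                            keep_images = is.null(dir)) {
  if (n_normal < 1L || n_strab < 1L) {
    strab_error("both group sizes must be >= 1", "spec_error")
  }
  if (length(deviation_range) != 2L || diff(deviation_range) < 0 ||
      any(deviation_range < 0)) {
    strab_error("deviation_range must be c(lo, hi) with 0 <= lo <= hi", "spec_error")
  }
  n <- n_normal + n_strab
  groups <- rep(c("normal", "strabismus"), c(n_normal, n_strab))
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      jit <- stats::runif(2, -1, 1)
      dev <- c(right = jit[1], left = jit[2])
      if (groups[i] == "strabismus") {
        eye <- sample(c("right", "left"), 1)
        dev[eye] <- sample(c(-1, 1), 1) * stats::runif(1, deviation_range[1],
                                                       deviation_range[2])
      }
      list(dev = dev, seeds = sample.int(.Machine$integer.max - 1L, 2))
    })
  })
  if (!is.null(dir)) {
    for (g in c("normal", "strabismus")) {
      dir.create(file.path(dir, g), recursive = TRUE, showWarnings = FALSE)
    }
  }
  faces <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    mk <- function(side, k) {
      fixture_spec(iris_radius = iris_radius, deviation_dx = d$dev[[side]],
                   side = side, eyelid_occlusion = eyelid_occlusion,
                   shadow_strength = shadow_strength, noise_sigma = noise_sigma,
                   seed = d$seeds[k])
    }
    face <- render_face(mk("right", 1), mk("left", 2))
    img_file <- pts_file <- truth_file <- NA_character_
    if (!is.null(dir)) {
      id <- sprintf("subject_%03d", i)
      img_file <- file.path(dir, groups[i], paste0(id, ".png"))
      pts_file <- file.path(dir, groups[i], paste0(id, ".pts"))
      truth_file <- file.path(dir, groups[i], paste0(id, "_truth.json"))
      write_image(face$image, img_file)
      write_landmarks(face$landmarks, pts_file)
      jsonlite::write_json(face$truth, truth_file, auto_unbox = TRUE, digits = NA)
    }
    if (keep_images) faces[[i]] <- face
    rows[[i]] <- data.frame(
      id = i, group = groups[i],
      dev_dx_right = unname(d$dev["right"]), dev_dx_left = unname(d$dev["left"]),
      S_analytic = face$S_analytic,
      image = img_file, pts = pts_file, truth = truth_file,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, faces = if (keep_images) faces)
}
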