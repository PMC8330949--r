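test_that("pts and JSON landmark files round-trip within 1e-6 px", {
  set.seed(11)
  pts <- cbind(runif(68, 1, 500), runif(68, 1, 400))
  lms <- landmark_set(pts)
  for (fmt in c("pts", "json")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_landmarks(lms, f, format = fmt)
    back <- load_landmarks(f)
    expect_equal(back$points, lms$points, tolerance = 1e-6,
                 ignore_attr = TRUE)
    unlink(f)
  }
})

test_that("malformed and miscounted landmark files raise informative errors", {
  f <- tempfile(fileext = ".pts")
  # 67 points
  writeLines(c("version: 1", "n_points: 67", "{",
               sprintf("%d %d", 1:67, 1:67), "}"), f)
  expect_error(load_landmarks(f), class = "cardinality_error")
  # declared 68 but holds 67
  writeLines(c("version: 1", "n_points: 68", "{",
               sprintf("%d %d", 1:67, 1:67), "}"), f)
  expect_error(load_landmarks(f), "declares 68", class = "cardinality_error")
  # garbage on a body line, error names the line
  writeLines(c("version: 1", "n_points: 68", "{",
               sprintf("%d %d", 1:30, 1:30), "not-a-point",
               sprintf("%d %d", 31:67, 31:67), "}"), f)
  expect_error(load_landmarks(f), "line 34", class = "parse_error")
  unlink(f)
  expect_error(landmark_set(cbind(1:68, c(NA, 2:68))), class = "parse_error")
  expect_error(load_landmarks(tempfile()), class = "io_error")
})

test_that("eye rectangles follow the corner-landmark rule with expansion", {
  img <- flat_image(W = 400, H = 200)
  lms <- landmarks_with_eyes(400, 200,
    right = list(x_start = 100, y_top = 50, x_end = 140, y_bottom = 60),
    left = list(x_start = 220, y_top = 52, x_end = 262, y_bottom = 61))
  r10 <- extract_eye_regions(img, lms, pipeline_config(expansion_px = 10))
  expect_equal(unname(r10$right$offset), c(90, 40))
  expect_equal(dim(r10$right$image)[1:2], c(70 - 40 + 1, 150 - 90 + 1))
  expect_equal(unname(r10$left$offset), c(210, 42))

  # zero expansion: crop exactly the landmark bounding rectangle
  r0 <- extract_eye_regions(img, lms, pipeline_config(expansion_px = 0))
  expect_equal(unname(r0$right$offset), c(100, 50))
  expect_equal(dim(r0$right$image)[1:2], c(60 - 50 + 1, 140 - 100 + 1))

  # medial/lateral anatomical assignment (right eye: 37 lateral, 40 medial)
  expect_equal(unname(r0$right$lateral_canthus + r0$right$offset - 1),
               unname(lms$points[37, ]))
  expect_equal(unname(r0$right$medial_canthus + r0$right$offset - 1),
               unname(lms$points[40, ]))
  expect_equal(unname(r0$left$medial_canthus + r0$left$offset - 1),
               unname(lms$points[43, ]))
  expect_equal(unname(r0$left$lateral_canthus + r0$left$offset - 1),
               unname(lms$points[46, ]))
})

test_that("rectangles partially outside the image clamp to the brute-force intersection", {
  img <- flat_image(W = 120, H = 80)
  lms <- landmarks_with_eyes(120, 80,
    right = list(x_start = 4, y_top = 6, x_end = 40, y_bottom = 18),
    left = list(x_start = 80, y_top = 6, x_end = 118, y_bottom = 18))
  ex <- extract_eye_regions(img, lms, pipeline_config(expansion_px = 10))
  # brute-force clamp oracle
  expect_equal(unname(ex$right$offset), c(max(1, 4 - 10), max(1, 6 - 10)))
  expect_equal(dim(ex$right$image)[2], min(120, 40 + 10) - max(1, 4 - 10) + 1)
  expect_equal(dim(ex$left$image)[2], min(120, 118 + 10) - (80 - 10) + 1)

  # fully degenerate rectangle errors
  bad <- landmarks_with_eyes(120, 80,
    right = list(x_start = 40, y_top = 18, x_end = 4, y_bottom = 6),
    left = list(x_start = 80, y_top = 6, x_end = 118, y_bottom = 18))
  expect_error(extract_eye_regions(img, bad, pipeline_config(expansion_px = 0)),
               class = "extraction_error")
})

test_that("extraction is translation-equivariant and canthi reconstruct source coords", {
  set.seed(21)
  base <- list(x_start = 60, y_top = 40, x_end = 100, y_bottom = 52)
  basel <- list(x_start = 150, y_top = 41, x_end = 192, y_bottom = 53)
  img <- flat_image(W = 320, H = 160)
  for (k in 1:5) {
    dx <- sample(-20:20, 1); dy <- sample(-15:15, 1)
    sh <- function(r) list(x_start = r$x_start + dx, y_top = r$y_top + dy,
                           x_end = r$x_end + dx, y_bottom = r$y_bottom + dy)
    e0 <- extract_eye_regions(img, landmarks_with_eyes(320, 160, base, basel),
                              pipeline_config())
    e1 <- extract_eye_regions(img, landmarks_with_eyes(320, 160, sh(base), sh(basel)),
                              pipeline_config())
    expect_equal(unname(e1$right$offset), unname(e0$right$offset) + c(dx, dy))
    expect_equal(unname(e1$left$offset), unname(e0$left$offset) + c(dx, dy))
    # right/left labels invariant, canthus reconstruction exact
    expect_identical(e1$right$side, "right")
    expect_identical(e1$left$side, "left")
    expect_equal(unname(e1$right$lateral_canthus + e1$right$offset - 1),
                 c(base$x_start + dx, (base$y_top + base$y_bottom) / 2 + dy))
  }
})

test_that("detect_landmarks honours the pluggable backend contract", {
  f <- render_face(fixture_spec(side = "right", seed = 1),
                   fixture_spec(side = "left", seed = 2))
  truth_pts <- f$landmarks$points
  cfg <- pipeline_config(landmark_backend = "pretrained", resize_factor = 1 / 2)

  # backend sees the downscaled frame; coordinates must be rescaled back
  backend <- function(small) {
    fct <- nrow(small) / nrow(f$image)
    list(truth_pts * fct)
  }
  det <- detect_landmarks(f$image, cfg, backend = backend)
  expect_lt(max(abs(det$points - truth_pts)), 2)

  # eye indices of the detected set bound the rendered eyes
  ex <- extract_eye_regions(f$image, det, pipeline_config())
  rc <- f$truth$right$center
  expect_true(rc[1] >= ex$right$offset[1] &&
                rc[1] <= ex$right$offset[1] + dim(ex$right$image)[2] - 1)

  expect_error(detect_landmarks(f$image, cfg, backend = function(small) list()),
               "0", class = "detection_error")
  expect_error(
    detect_landmarks(f$image, cfg,
                     backend = function(small) list(truth_pts / 2, truth_pts / 2)),
    "2", class = "detection_error")
  # no backend registered: configuration error pointing at landmark files
  old <- options(strabscreen.landmark_backend = NULL)
  on.exit(options(old))
  expect_error(detect_landmarks(f$image, cfg),
               "landmark file", class = "configuration_error")
})
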