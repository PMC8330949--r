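test_that("Gaussian smoothing preserves constants and mass, matches a direct stamp", {
  cfg <- segmentation_config()
  const <- flat_image(20, 14, level = 123)
  expect_equal(smooth(const, cfg), const)

  # single bright pixel: output is the symmetric separable kernel stamp
  img <- flat_image(21, 21, level = 0)
  img[11, 11, ] <- 255
  sm <- smooth(img, cfg)
  expect_equal(sum(sm[, , 1]), 255, tolerance = 1e-6)     # weights sum to 1
  expect_equal(sm[11 - 2, 11, 1], sm[11 + 2, 11, 1])      # symmetry
  expect_equal(sm[11, 11 - 1, 1], sm[11 - 1, 11, 1])      # isotropy of stamp
  # direct-convolution oracle at the center
  s <- cfg$gaussian_sigma
  w <- exp(-(-2:2)^2 / (2 * s^2)); w <- w / sum(w)
  expect_equal(sm[9:13, 9:13, 1], 255 * outer(w, w), tolerance = 1e-9,
               ignore_attr = TRUE)

  # sigma -> 0 limit approaches the identity
  tiny <- segmentation_config(gaussian_sigma = 1e-3)
  expect_equal(smooth(img, tiny), img, tolerance = 1e-6)

  expect_error(smooth(flat_image(4, 4), cfg), class = "size_error")
})

test_that("grayscale conversion uses BT.601 luma", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(to_gray(px(255, 255, 255))[1, 1], 255)
  expect_equal(to_gray(px(0, 0, 0))[1, 1], 0)
  expect_equal(to_gray(px(100, 100, 100))[1, 1], 100)
  expect_equal(to_gray(px(255, 0, 0))[1, 1], floor(0.299 * 255 + 0.5))
})

test_that("Otsu threshold matches the exhaustive-search oracle", {
  # two-level image: 40% at 50, 60% at 200
  g <- matrix(c(rep(50, 40), rep(200, 60)), 10, 10)
  t <- otsu_threshold(g)
  expect_identical(t, otsu_oracle(g))
  expect_true(t > 50 && t <= 200)            # classes are exactly the two groups
  expect_identical(t, 51L)                   # smallest maximizing threshold

  # constant image degenerates to the constant with a warning
  expect_warning(tc <- otsu_threshold(matrix(77, 5, 5)), "constant")
  expect_identical(tc, 77L)

  # random images: equality with the brute-force oracle
  set.seed(31)
  for (i in 1:60) {
    g <- matrix(sample(0:255, 15 * 11, replace = TRUE), 11, 15)
    expect_identical(otsu_threshold(g), otsu_oracle(g))
  }

  # histogram-scaling invariance: duplicating the image leaves t unchanged
  g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_identical(otsu_threshold(g), otsu_threshold(rbind(g, g)))
})

test_that("binarization partitions pixels by the threshold", {
  set.seed(32)
  g <- matrix(sample(0:255, 200, replace = TRUE), 10, 20)
  expect_true(all(binarize(g, 0) == 255))
  expect_true(all(binarize(g, 256) == 0))
  for (t in c(1, 64, 128, 200)) {
    m <- binarize(g, t)
    expect_true(all(m %in% c(0, 255)))
    expect_identical(sum(m == 0), sum(g < t))                # histogram-count oracle
    expect_identical(sum(m == 0) + sum(m == 255), length(g)) # partition
  }
})

test_that("HSV dark mask flags pixels componentwise within the bounds", {
  cfg <- segmentation_config()
  set.seed(33)
  crop <- array(sample(0:255, 12 * 9 * 3, replace = TRUE), dim = c(9, 12, 3))
  gray <- to_gray(crop)
  m <- hsv_dark_mask(crop, gray, cfg)
  v_up <- attr(m, "v_upper")
  expect_equal(v_up, floor(mean(gray) + 0.5))
  # per-pixel brute-force oracle via rgb2hsv
  for (i in seq_len(nrow(gray))) for (j in seq_len(ncol(gray))) {
    hsv <- grDevices::rgb2hsv(crop[i, j, 1], crop[i, j, 2], crop[i, j, 3],
                              maxColorValue = 255)
    dark <- hsv[1] * 180 <= 180 && hsv[2] * 255 <= 255 && hsv[3] * 255 <= v_up
    expect_identical(m[i, j] == 0, dark)
  }
  # corner cases
  black <- array(0, dim = c(2, 2, 3))
  expect_true(all(hsv_dark_mask(black, to_gray(black), cfg) == 0))
  bright <- array(255, dim = c(2, 2, 3)); bright[1, 1, ] <- 10
  mb <- hsv_dark_mask(bright, to_gray(bright), cfg)
  expect_identical(mb[2, 2], 255)   # brightness above the mean-gray bound
  expect_identical(mb[1, 1], 0)
  # upper (180,255,255) with lower (0,0,0) marks everything dark
  all_cfg <- segmentation_config(hsv_upper_v_mode = "fixed", hsv_upper_v_fixed = 255)
  expect_true(all(hsv_dark_mask(crop, gray, all_cfg) == 0))
  expect_error(hsv_dark_mask(crop, gray[1:3, ], cfg), class = "shape_error")
})

test_that("literal mask combination matches the per-column scan rule", {
  lit <- segmentation_config(combine_variant = "literal")
  # no dark HSV pixel anywhere: output identical to the Otsu mask
  set.seed(34)
  otsu <- matrix(sample(c(0, 255), 30, replace = TRUE), 5, 6)
  hsv_white <- matrix(255, 5, 6)
  expect_equal(combine_masks(otsu, hsv_white, lit), otsu, ignore_attr = TRUE)

  # printed-rule example on a 3x3 all-dark Otsu mask, one dark HSV pixel in
  # the middle column's middle row: that column is whitened from there down
  otsu3 <- matrix(0, 3, 3)
  hsv3 <- matrix(255, 3, 3); hsv3[2, 2] <- 0
  got <- combine_masks(otsu3, hsv3, lit)
  want <- matrix(0, 3, 3); want[2:3, 2] <- 255
  expect_equal(got, want, ignore_attr = TRUE)

  # random mask pairs equal the brute-force column-scan oracle
  for (i in 1:25) {
    o <- matrix(sample(c(0, 255), 8 * 7, replace = TRUE, prob = c(.4, .6)), 7, 8)
    h <- matrix(sample(c(0, 255), 8 * 7, replace = TRUE, prob = c(.3, .7)), 7, 8)
    expect_equal(combine_masks(o, h, lit), combine_literal_oracle(o, h),
                 ignore_attr = TRUE)
  }
  expect_error(combine_masks(otsu3, matrix(255, 2, 3), lit), class = "shape_error")
})

test_that("combination never creates foreground and preserves the central iris", {
  set.seed(35)
  cfg_pc <- segmentation_config()  # preserve_central default
  lit <- segmentation_config(combine_variant = "literal")
  for (i in 1:20) {
    o <- matrix(sample(c(0, 255), 90, replace = TRUE), 9, 10)
    h <- matrix(sample(c(0, 255), 90, replace = TRUE), 9, 10)
    for (cfg in list(cfg_pc, lit)) {
      comb <- combine_masks(o, h, cfg)
      expect_true(all(comb[o == 255] == 255))  # dark(combined) subset dark(otsu)
    }
  }

  # fixture-recall: >= 90% of ground-truth iris pixels dark in Otsu stay dark
  for (seed in 1:5) {
    sp <- fixture_spec(iris_radius = 18, deviation_dx = sample(-8:8, 1),
                       eyelid_occlusion = 0.15, shadow_strength = 0.5,
                       noise_sigma = 4, seed = seed)
    re <- render_eye(sp)
    gray <- to_gray(re$image)
    t <- otsu_threshold(gray)
    o <- binarize(gray, t)
    h <- hsv_dark_mask(re$image, gray)
    comb <- combine_masks(o, h, cfg_pc)
    X <- matrix(rep(seq_len(sp$width), each = sp$height), sp$height, sp$width)
    Y <- matrix(rep(seq_len(sp$height), sp$width), sp$height, sp$width)
    iris_px <- (X - sp$center[1])^2 + (Y - sp$center[2])^2 <= sp$iris_radius^2
    dark_in_otsu <- iris_px & o == 0
    expect_gt(sum(comb[dark_in_otsu] == 0) / sum(dark_in_otsu), 0.9)
    expect_true(all(comb[o == 255] == 255))
  }
})
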