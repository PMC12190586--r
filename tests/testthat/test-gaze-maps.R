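# Gaussian field-of-view model and gaze-attention map rendering.

test_that("point_spread evaluates the Gaussian field-of-view model", {
  # center value: exponent vanishes, only the normalizer remains
  expect_equal(point_spread(10, 20, center = c(10, 20), sigma = 30),
               1 / (sqrt(2 * pi) * 30), tolerance = 1e-12)
  # radial symmetry about the center
  for (d in c(1, 7.5, 40)) {
    expect_equal(point_spread(10 + d, 20, c(10, 20), 5),
                 point_spread(10 - d, 20, c(10, 20), 5))
    expect_equal(point_spread(10, 20 + d, c(10, 20), 5),
                 point_spread(10 + d, 20, c(10, 20), 5))
  }
  # at Euclidean distance sigma the value is e^(-1/2) of the center value
  s <- 12
  expect_equal(point_spread(5 + s, 9, c(5, 9), s),
               point_spread(5, 9, c(5, 9), s) * exp(-0.5), tolerance = 1e-12)
  expect_true(point_spread(150, 200, c(0, 0), 30) > 0)
  expect_error(point_spread(0, 0, c(0, 0), 0), "sigma")
  expect_error(point_spread(0, 0, c(0, 0), -2), "sigma")
})

test_that("effective_sigma follows the viewing-geometry formula", {
  # frozen hand-arithmetic oracle: (1/360)*pi*50*sqrt((1080*1920)/(48*64))
  expect_equal(effective_sigma(viewing_geometry(eye_distance = 50)),
               11.33624603, tolerance = 1e-8)
  expect_equal(effective_sigma(viewing_geometry(eye_distance = 80)),
               18.13799364, tolerance = 1e-8)
  # linear in R and theta
  g1 <- viewing_geometry(eye_distance = 31)
  g2 <- viewing_geometry(eye_distance = 62)
  expect_equal(effective_sigma(g2), 2 * effective_sigma(g1), tolerance = 1e-12)
  ga <- viewing_geometry(perspective_error_deg = 0.7)
  gb <- viewing_geometry(perspective_error_deg = 2.1)
  expect_equal(effective_sigma(gb), 3 * effective_sigma(ga), tolerance = 1e-12)
  # theta -> 0 limit is 0 (by linearity)
  expect_lt(effective_sigma(viewing_geometry(perspective_error_deg = 1e-9)),
            1e-7)
  # strictly increasing in theta, R, and pixel density
  th <- seq(0.2, 3, by = 0.2)
  v <- vapply(th, function(t)
    effective_sigma(viewing_geometry(perspective_error_deg = t)), numeric(1))
  expect_true(all(diff(v) > 0))
  lo <- effective_sigma(viewing_geometry(screen_w_px = 1280, screen_h_px = 720))
  hi <- effective_sigma(viewing_geometry(screen_w_px = 3840, screen_h_px = 2160))
  expect_gt(hi, lo)
  expect_error(viewing_geometry(eye_distance = -1), "positive")
  expect_error(viewing_geometry(perspective_error_deg = 95), "90")
})

test_that("fixation sequences sort by timestamp and validate inputs", {
  fs <- fixation_sequence("a", x_px = c(3, 1, 2), y_px = c(30, 10, 20),
                          timestamp_ms = c(300, 100, 200))
  expect_equal(fs$points$x_px, c(1, 2, 3))
  expect_equal(fs$points$duration_ms, rep(1, 3))
  expect_error(fixation_sequence("a", NaN, 1, 1), "finite")
  expect_error(fixation_sequence("a", 1, 1, 1, duration_ms = -5), "duration")
})

test_that("rendered gaze maps match the sum-of-Gaussians oracle", {
  # fixations at integer screen pixels, image centered on a 1920x1080 display
  off_x <- (1920 - 64) / 2; off_y <- (1080 - 64) / 2
  set.seed(41)
  for (K in c(1, 3, 5)) {
    xs <- sample(0:63, K); ys <- sample(0:63, K)
    fix <- fixation_sequence("o", xs + off_x, ys + off_y, seq_len(K))
    gm <- render_gaze_map(fix, 64, 64)          # defaults sigma 30, 199 taps
    orc <- oracle_gaze_map(xs, ys, 30, 64, 64)
    expect_lt(max(abs(gm$values - orc) / pmax(orc, 1e-300)), 1e-5)
  }
})

test_that("gaze map range, normalization and symmetry invariants hold", {
  off <- c((1920 - 64) / 2, (1080 - 64) / 2)
  center <- fixation_sequence("c", 32 + off[1], 32 + off[2], 1)
  gm <- render_gaze_map(center, 64, 64, sigma = 6, kernel_taps = 199)
  expect_true(all(gm$values >= 0 & gm$values <= 1))
  expect_equal(max(gm$values), 1)
  # single impulse: the argmax is exactly the fixated pixel
  am <- which(gm$values == 1, arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(33, 33))
  # a pair of impulses straddling the vertical midline is LR-symmetric
  pair <- fixation_sequence("p", c(31, 32) + off[1], c(40, 40) + off[2], 1:2)
  gp <- render_gaze_map(pair, 64, 64, sigma = 6, kernel_taps = 199)$values
  expect_equal(gp, gp[, 64:1], tolerance = 1e-12)
  # two mirror-symmetric fixations: map equals its own left-right flip
  fix2 <- fixation_sequence("m", c(20, 43) + off[1], c(30, 30) + off[2], 1:2)
  g2 <- render_gaze_map(fix2, 64, 64, sigma = 10)$values
  expect_equal(g2, g2[, 64:1], tolerance = 1e-10)
})

test_that("gaze map translation equivariance holds on interior pixels", {
  off <- c((1920 - 64) / 2, (1080 - 64) / 2)
  f1 <- fixation_sequence("t1", 30 + off[1], 30 + off[2], 1)
  f2 <- fixation_sequence("t2", 34 + off[1], 35 + off[2], 1)
  m1 <- render_gaze_map(f1, 64, 64, sigma = 4, kernel_taps = 33)$values
  m2 <- render_gaze_map(f2, 64, 64, sigma = 4, kernel_taps = 33)$values
  # shift by (dx, dy) = (4, 5); compare away from borders (kernel half-width 16)
  rows <- 20:44; cols <- 20:44
  expect_equal(m2[rows + 5, cols + 4], m1[rows, cols], tolerance = 1e-10)
})

test_that("empty or off-image fixations give warned all-zero maps", {
  empty <- fixation_sequence("e", numeric(), numeric(), numeric())
  expect_warning(gm <- render_gaze_map(empty, 32, 32), "empty")
  expect_true(all(gm$values == 0))
  far <- fixation_sequence("f", 5, 5, 1)   # outside a centered 32x32 image
  expect_warning(gm2 <- render_gaze_map(far, 32, 32), "no fixation")
  expect_true(all(gm2$values == 0))
})

test_that("duration weighting shifts mass toward long fixations", {
  off <- c((1920 - 64) / 2, (1080 - 64) / 2)
  fix <- fixation_sequence("d", c(16, 48) + off[1], c(32, 32) + off[2], 1:2,
                           duration_ms = c(900, 100))
  gw <- render_gaze_map(fix, 64, 64, sigma = 5, weight_by_duration = TRUE)$values
  gu <- render_gaze_map(fix, 64, 64, sigma = 5)$values
  expect_gt(gw[33, 17] / gw[33, 49], 5)        # 9:1 weight ratio
  expect_equal(gu[33, 17], gu[33, 49], tolerance = 1e-9)
})

test_that("overlay_heatmap blends image and colormapped attention", {
  set.seed(7)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  zero <- matrix(0, 16, 16); one <- matrix(1, 16, 16)
  expect_equal(overlay_heatmap(img, zero, alpha = 0), img)
  # alpha = 1 on an all-zero map: uniform colormap-zero color
  o1 <- overlay_heatmap(img, zero, alpha = 1)
  for (ch in 1:3) expect_equal(stats::sd(o1[, , ch]), 0)
  # alpha = 0.5 on a constant-1 map: mean of image and colormap-max color
  cmax <- gazecam:::heat_colors(1)
  o2 <- overlay_heatmap(img, one, alpha = 0.5)
  for (ch in 1:3)
    expect_equal(o2[, , ch], (img[, , ch] + cmax[ch]) / 2, tolerance = 1e-12)
  expect_true(all(o2 >= 0 & o2 <= 1))
  expect_error(overlay_heatmap(img, matrix(0, 8, 8)), "shape")
})
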