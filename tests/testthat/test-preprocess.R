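# Trial delimitation, spline resampling, and geometric augmentation.

test_that("trial window matches constructed press times within 2 ms", {
  keys <- make_press_keytrace(list(c(100, 600)))
  w <- detect_trial_window(keys)
  expect_lt(abs(w$t_start - 0.100), 0.0025)
  expect_lt(abs(w$t_end - 0.600), 0.0025)

  two <- make_press_keytrace(list(c(100, 300), c(900, 1200)))
  w2 <- detect_trial_window(two)
  expect_lt(abs(w2$t_start - 0.100), 0.0025)
  expect_lt(abs(w2$t_end - 1.200), 0.0025)
})

test_that("trial window agrees with simulator ground truth", {
  for (seed in 1:3) {
    keys <- gen_key_trace(task_spec(1), seed = seed)
    ev <- attr(keys, "events")
    w <- detect_trial_window(keys)
    expect_lt(abs(w$t_start - min(ev$onset_s)), 0.003)
    expect_lt(abs(w$t_end - max(ev$offset_s)), 0.003)
  }
})

test_that("all-zero trace raises NoKeystrokeDetected, hysteresis is checked", {
  kt <- key_trace(make_zero_keytrace_df(500))
  expect_error(detect_trial_window(kt), class = "dscreen_no_keystroke_detected")
  keys <- make_press_keytrace(list(c(100, 600)))
  expect_error(detect_trial_window(keys, press_threshold_mm = 0.3,
                                   release_threshold_mm = 0.5),
               class = "dscreen_bad_threshold")
})

test_that("segment extraction keeps the closed interval and frame minimum", {
  traj <- make_random_trajectory(n_frames = 121)    # 0..2 s at 60 Hz
  seg <- extract_segment(traj, list(t_start = 0.5, t_end = 1.5))
  expect_identical(length(unique(seg$frame)), 61L)  # closed interval on 60 Hz

  full <- extract_segment(traj, list(t_start = 0, t_end = 2))
  expect_identical(nrow(full), nrow(traj))

  expect_error(extract_segment(traj, list(t_start = 1.90, t_end = 1.92)),
               class = "dscreen_segment_too_short")
})

test_that("time normalization is exact at knots and on linear channels", {
  # 128 uniformly spaced frames: resampling must reproduce the input
  df <- make_landmark_df(128)
  set.seed(9)
  df$x <- runif(nrow(df)); df$y <- runif(nrow(df)); df$z <- rnorm(nrow(df))
  traj <- landmark_trajectory(df, fps = 60)
  tn <- time_normalize(traj, 128)
  v <- matrix(df$x, nrow = 21)                      # landmark x frame
  expect_equal(tn[5, "x", ], v[5, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(dim(tn), c(21L, 3L, 128L))

  # linear channels are reproduced exactly by a natural cubic spline
  lin <- make_landmark_df(200)
  lin$x <- 0.1 + 0.3 * lin$time_s
  traj_lin <- landmark_trajectory(lin, fps = 60)
  tn_lin <- time_normalize(traj_lin, 128)
  t_out <- seq(min(lin$time_s), max(lin$time_s), length.out = 128)
  expect_equal(as.numeric(tn_lin[1, "x", ]), 0.1 + 0.3 * t_out,
               tolerance = 1e-9)

  expect_error(time_normalize(landmark_trajectory(make_landmark_df(3))),
               class = "dscreen_segment_too_short")
})

test_that("time normalization preserves endpoint values of every channel", {
  traj <- make_random_trajectory(n_frames = 77)
  tn <- time_normalize(traj, 128)
  df <- as.data.frame(traj)
  first <- matrix(df$x, nrow = 21)[, 1]
  last <- matrix(df$x, nrow = 21)[, 77]
  expect_equal(as.numeric(tn[, "x", 1]), first, tolerance = 1e-12)
  expect_equal(as.numeric(tn[, "x", 128]), last, tolerance = 1e-12)
})

test_that("augmentation geometry behaves as plane geometry demands", {
  tn <- make_random_tensor()

  # identity parameters return the input bit-exactly
  expect_identical(augment(tn, 0, 1, 1), tn)

  # 90-degree rotation maps (0.5 + d, 0.5) to (0.5, 0.5 + d)
  pt <- trial_tensor(array(0.5, c(21, 3, 8)))
  d <- 0.17
  pt[3, 1, ] <- 0.5 + d
  rot <- augment(pt, 90)
  expect_lt(max(abs(rot[3, 1, ] - 0.5)), 1e-9)
  expect_lt(max(abs(rot[3, 2, ] - (0.5 + d))), 1e-9)

  # anisotropic x-scaling leaves y untouched
  sc <- augment(tn, 0, scale_x = 1.1, scale_y = 1)
  expect_equal(sc[, 2, ], tn[, 2, ], tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(sc[, 1, ] - 0.5, 1.1 * (tn[, 1, ] - 0.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sc[, 3, ], tn[, 3, ], ignore_attr = TRUE)

  expect_error(augment(tn, 0, scale_x = -1), class = "dscreen_invalid_scale")
})

test_that("rotation preserves pairwise (x, y) distances to 1e-9", {
  tn <- make_random_tensor(n = 16, seed = 3)
  rot <- augment(tn, rotation_deg = 33)
  for (s in c(1, 8, 16)) {
    d0 <- dist(cbind(tn[, 1, s], tn[, 2, s]))
    d1 <- dist(cbind(rot[, 1, s], rot[, 2, s]))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("batch augmentation is deterministic and counts correctly", {
  tns <- lapply(1:10, function(i) make_random_tensor(n = 16, seed = i))
  expect_identical(augment_batch(tns, n_per_tensor = 0), tns)
  a <- augment_batch(tns, n_per_tensor = 3, seed = 7)
  expect_length(a, 40L)
  b <- augment_batch(tns, n_per_tensor = 3, seed = 7)
  expect_identical(a, b)
  # originals are carried through unchanged
  expect_identical(a[[1]], tns[[1]])
  expect_identical(a[[5]], tns[[2]])
})

test_that("left-hand trials are mirrored onto the right-hand frame", {
  tr <- gen_healthy_trial(1, seed = 4, hand = "left")
  tn <- trial_to_tensor(tr, mirror_left = TRUE)
  tn_raw <- trial_to_tensor(tr, mirror_left = FALSE)
  expect_equal(tn[, 1, ], 1 - tn_raw[, 1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tn[, 2, ], tn_raw[, 2, ], ignore_attr = TRUE)
})
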