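# Synthetic trial, cohort, biomechanics and observer generators.

test_that("generators are pure functions of parameters and seed", {
  a <- gen_healthy_trial(4, seed = 9)
  b <- gen_healthy_trial(4, seed = 9)
  expect_identical(as.data.frame(a$trajectory), as.data.frame(b$trajectory))
  expect_identical(as.data.frame(a$keys), as.data.frame(b$keys))

  k1 <- gen_key_trace(task_spec(2), seed = 5)
  k2 <- gen_key_trace(task_spec(2), seed = 5)
  expect_identical(as.data.frame(k1), as.data.frame(k2))

  c1 <- gen_biomech_cohort(n_healthy = 4, n_md = 3, seed = 2)
  c2 <- gen_biomech_cohort(n_healthy = 4, n_md = 3, seed = 2)
  expect_identical(c1, c2)
})

test_that("key traces carry one excursion per note event at the tempo grid", {
  keys <- gen_key_trace(task_spec(1), tempo_bpm = 100, seed = 3,
                        onset_jitter_sd = 0)
  ev <- attr(keys, "events")
  expect_identical(nrow(ev), 16L)                       # sixteen sixteenths
  expect_equal(diff(ev$onset_s), rep(0.15, 15), tolerance = 1e-9)

  # a task stripped of events yields a silent trace
  tk <- task_spec(1)
  tk$events <- list()
  tk$n_events <- 0L
  silent <- gen_key_trace(tk, seed = 1)
  expect_true(all(as.matrix(silent[-1]) == 0))
  expect_error(detect_trial_window(silent),
               class = "dscreen_no_keystroke_detected")
})

test_that("generated trials satisfy the io invariants and tensorize", {
  tr <- gen_healthy_trial(7, seed = 2)                  # chord task
  expect_s3_class(tr, "validated_trial")
  tn <- trial_to_tensor(tr)
  expect_equal(dim(tn), c(21L, 3L, 128L))
  expect_true(all(is.finite(tn)))
})

test_that("severity zero reproduces the healthy trial bitwise", {
  h <- gen_healthy_trial(4, seed = 31, subject_id = "X")
  d0 <- gen_dystonic_trial(4, pattern = dystonia_pattern(severity = 0),
                           seed = 31, subject_id = "X")
  expect_identical(as.data.frame(h$trajectory), as.data.frame(d0$trajectory))
  expect_identical(as.data.frame(h$keys), as.data.frame(d0$keys))
  expect_identical(d0$meta$group, "md")
})

test_that("affected fingertips sit closer to the keys at full severity", {
  h <- gen_healthy_trial(4, seed = 17, subject_id = "X")
  d <- gen_dystonic_trial(4, pattern = dystonia_pattern(c("index", "middle"), 1),
                          seed = 17, subject_id = "X")
  hy <- as.data.frame(h$trajectory)
  dy <- as.data.frame(d$trajectory)
  for (lm in c(8L, 12L)) {                              # index tip, middle tip
    expect_lt(mean(dy$y[dy$landmark_id == lm]),
              mean(hy$y[hy$landmark_id == lm]) - 0.01)
  }
  # unaffected little finger is at most mildly disturbed (noise + coupling)
  expect_lt(abs(mean(dy$y[dy$landmark_id == 20]) -
                mean(hy$y[hy$landmark_id == 20])), 0.01)
})

test_that("tensor distance to the healthy template grows with severity", {
  dist_at <- function(sev, seed) {
    h <- trial_to_tensor(gen_healthy_trial(4, seed = seed, subject_id = "X"))
    d <- trial_to_tensor(gen_dystonic_trial(
      4, pattern = dystonia_pattern(severity = sev), seed = seed,
      subject_id = "X"))
    mean((d - h)^2)
  }
  for (seed in c(5, 6)) {
    dd <- vapply(c(0, 0.5, 1), dist_at, numeric(1), seed = seed)
    expect_identical(dd[1], 0)
    expect_true(all(diff(dd) > 0))
  }
})

test_that("noise-free trials equal their deterministic template", {
  cfg0 <- generator_config(noise_sd = 0)
  a <- gen_healthy_trial(1, config = cfg0, seed = 8)
  b <- gen_healthy_trial(1, config = cfg0, seed = 8)
  expect_identical(as.data.frame(a$trajectory), as.data.frame(b$trajectory))
  # with noise on, the deviation from the template is noise-sized
  cfg <- generator_config(noise_sd = 0.003)
  n <- gen_healthy_trial(1, config = cfg, seed = 8)
  dev <- n$trajectory$y - a$trajectory$y
  expect_equal(sd(dev), 0.003, tolerance = 0.15)
})

test_that("biomech cohorts have the stated structure and shifts", {
  coh <- gen_biomech_cohort(n_healthy = 12, n_md = 10, seed = 4)
  expect_identical(nrow(coh), (12L + 10L) * 2L * 5L * 6L)
  expect_setequal(unique(coh$fn),
                  c("strength", "reduction_ratio", "independence", "agility",
                    "rom_flex_ext", "rom_abd_add"))
  # affected hand of MD subjects is depressed on independence
  md <- coh[coh$group == "md" & coh$fn == "independence", ]
  aff <- md$value[md$hand == md$affected_hand]
  una <- md$value[md$hand != md$affected_hand]
  expect_lt(mean(aff), mean(una))
})

test_that("simulated observers follow the stated psychometric function", {
  obs <- gen_observer(60, slope = 3, lapse = 0)
  expect_equal(observer_p_correct(obs, 60), 0.75)
  expect_equal(observer_p_correct(obs, 1e9), 1, tolerance = 1e-6)
  obs_l <- gen_observer(60, slope = 3, lapse = 0.05)
  expect_equal(observer_p_correct(obs_l, 1e9), 0.95, tolerance = 1e-6)
  expect_error(gen_observer(-5), "threshold")
})
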