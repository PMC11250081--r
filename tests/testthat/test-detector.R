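# Participant-level splitting, threshold calibration, classification
# and per-task evaluation.

test_that("participant split is deterministic, disjoint and sized 80/20", {
  tns <- make_subject_tensors(10)
  sp <- split_by_participant(tns, 0.8, seed = 3)
  expect_length(sp$train_subjects, 8L)
  expect_length(sp$validation_subjects, 2L)
  expect_length(intersect(sp$train_subjects, sp$validation_subjects), 0L)
  sp2 <- split_by_participant(tns, 0.8, seed = 3)
  expect_identical(sp$train_subjects, sp2$train_subjects)
  # no trial of a validation participant leaks into training
  train_ids <- vapply(sp$train, function(tn) attr(tn, "meta")$subject_id, "")
  expect_true(all(train_ids %in% sp$train_subjects))

  expect_error(split_by_participant(make_subject_tensors(1)),
               class = "dscreen_too_few_participants")
})

test_that("threshold calibration is exactly mean plus two sample SDs", {
  r <- calibrate_threshold(c(1, 1, 1, 1))
  expect_identical(r$threshold, 1)
  expect_identical(r$sd_err, 0)

  r2 <- calibrate_threshold(c(0, 2))
  expect_equal(r2$threshold, 1 + 2 * sqrt(2), tolerance = 1e-15)

  r3 <- calibrate_threshold(rep(3e-4, 5))
  expect_equal(r3$threshold, 3e-4)

  # property: threshold identity holds to machine precision
  for (seed in 1:20) {
    set.seed(seed)
    e <- rexp(sample(2:50, 1))
    r <- calibrate_threshold(e)
    expect_identical(r$threshold, r$mean_err + 2 * r$sd_err)
    expect_identical(r$n_validation, length(e))
  }

  expect_error(calibrate_threshold(3e-4), class = "dscreen_too_few_errors")
})

test_that("classification is strict exceedance and monotone", {
  rec <- calibrate_threshold(c(0.1, 0.2, 0.3))
  th <- rec$threshold
  expect_identical(classify(th, rec), "normal")
  expect_identical(classify(th + 1e-12, rec), "abnormal")
  e <- sort(runif(50))
  lab <- classify(e, rec)
  expect_true(all(diff(lab == "abnormal") >= 0))   # never flips back to normal
})

test_that("per-task evaluation implements the sensitivity/specificity rules", {
  preds <- tibble::tibble(
    task_id = rep(4L, 30),
    group = rep(c("md", "healthy"), c(10, 20)),
    label = c(rep("abnormal", 9), "normal",
              rep("normal", 19), "abnormal")
  )
  rep4 <- evaluate(preds)
  expect_equal(rep4$sensitivity, 0.9)
  expect_equal(rep4$specificity, 0.95)
  expect_identical(rep4$tp, 9L)
  expect_false(rep4$chance_flag)

  low <- preds
  low$label[low$group == "md"] <- c(rep("abnormal", 5), rep("normal", 5))
  expect_true(evaluate(low)$chance_flag)           # sensitivity 0.5 is chance

  no_md <- preds[preds$group == "healthy", ]
  expect_error(evaluate(no_md), class = "dscreen_empty_group")
})

test_that("the fitted detector exposes tidy/glance/predict accessors", {
  tns <- make_subject_tensors(5, trials_each = 2, n = 32)
  det <- fit_detector(tns, conv_ae_config(channels = c(4L, 6L, 8L),
                                          latent_channels = 8L,
                                          max_epochs = 3L),
                      split_seed = 1, train_seed = 2, augment_seed = 3,
                      n_augment = 1)
  td <- tidy(det)
  expect_true(all(c("subject_id", "error", "threshold", "label") %in% names(td)))
  expect_equal(nrow(td), length(det$split$validation))
  gl <- glance(det)
  expect_identical(gl$threshold, det$calibration$threshold)
  pr <- predict(det, tns[1:3])
  expect_identical(nrow(pr), 3L)
  expect_true(all(pr$error >= 0))
})
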