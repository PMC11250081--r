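# Split, threshold calibration, classification and per-task evaluation
# of the one-class detector, plus the high-level fit_detector() wrapper.

#' Split trial tensors by participant
#'
#' The healthy data are divided at the participant level — no
#' participant contributes trials to both sets — with `train_fraction`
#' of participants (rounded) assigned to training.  Deterministic given
#' `seed`.
#'
#' @param tensors list of `trial_tensor`s whose metadata carry
#'   `subject_id`.
#' @param train_fraction fraction of participants used for training
#'   (default 0.8).
#' @param seed integer seed.
#' @return A list with elements `train`, `validation` (lists of
#'   tensors), `train_subjects`, `validation_subjects`.
#' @export
split_by_participant <- function(tensors, train_fraction = 0.8, seed = 1L) {
  subjects <- vapply(tensors, function(tn) attr(tn, "meta")$subject_id,
                     character(1))
  uniq <- sort(unique(subjects))
  if (length(uniq) < 2L) {
    abort_dscreen("need at least 2 distinct participants to split",
                  "dscreen_too_few_participants")
  }
  n_train <- round(train_fraction * length(uniq))
  n_train <- max(1L, min(length(uniq) - 1L, n_train))
  train_subj <- with_seed(seed, sort(sample(uniq, n_train)))
  is_train <- subjects %in% train_subj
  list(train = tensors[is_train],
       validation = tensors[!is_train],
       train_subjects = train_subj,
       validation_subjects = setdiff(uniq, train_subj))
}

#' Calibrate the anomaly threshold from validation errors
#'
#' The decision threshold is the mean reconstruction error of the
#' healthy validation trials plus two standard deviations (sample SD,
#' n - 1 denominator).
#'
#' @param validation_errors numeric vector of MSEs, length >= 2.
#' @param split_seed optional integer recorded for provenance.
#' @return A list of class `calibration_record` with `mean_err`,
#'   `sd_err`, `threshold`, `n_validation`, `split_seed`,
#'   `train_fraction`.
#' @export
calibrate_threshold <- function(validation_errors, split_seed = NA_integer_) {
  if (length(validation_errors) < 2L) {
    abort_dscreen("need at least 2 validation errors to calibrate",
                  "dscreen_too_few_errors")
  }
  m <- mean(validation_errors)
  s <- stats::sd(validation_errors)
  structure(list(mean_err = m, sd_err = s, threshold = m + 2 * s,
                 n_validation = length(validation_errors),
                 split_seed = split_seed, train_fraction = 0.8),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf(
    "<calibration_record> mean %.3e + 2 x sd %.3e -> threshold %.3e (n = %d)\n",
    x$mean_err, x$sd_err, x$threshold, x$n_validation))
  invisible(x)
}

#' Classify reconstruction errors against a calibrated threshold
#'
#' A trial is abnormal iff its reconstruction error strictly exceeds the
#' threshold; an error exactly at the threshold is normal.
#'
#' @param error numeric vector of MSEs.
#' @param record a [calibrate_threshold()] result.
#' @return Character vector, `"normal"` or `"abnormal"`.
#' @export
classify <- function(error, record) {
  stopifnot(inherits(record, "calibration_record"))
  ifelse(error > record$threshold, "abnormal", "normal")
}

#' Per-task sensitivity and specificity
#'
#' Sensitivity is the proportion of patient trials classified abnormal,
#' specificity the proportion of healthy trials classified normal.
#' Tasks whose sensitivity does not exceed the 50% chance level are
#' flagged as failed classification.
#'
#' @param predictions tibble with columns `task_id`, `group`
#'   (`"healthy"` / `"md"`) and `label` (`"normal"` / `"abnormal"`).
#' @return A tibble of class `eval_report`: one row per task with
#'   confusion counts `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity` and `chance_flag` (TRUE when sensitivity <= 0.5).
#' @export
evaluate <- function(predictions) {
  stopifnot(all(c("task_id", "group", "label") %in% names(predictions)))
  out <- predictions |>
    dplyr::group_by(.data$task_id) |>
    dplyr::summarise(
      tp = sum(.data$group == "md" & .data$label == "abnormal"),
      fn = sum(.data$group == "md" & .data$label == "normal"),
      tn = sum(.data$group == "healthy" & .data$label == "normal"),
      fp = sum(.data$group == "healthy" & .data$label == "abnormal"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sensitivity = .data$tp / (.data$tp + .data$fn),
      specificity = .data$tn / (.data$tn + .data$fp),
      chance_flag = !(.data$sensitivity > 0.5)
    )
  if (any(out$tp + out$fn == 0) || any(out$tn + out$fp == 0)) {
    abort_dscreen("every task needs at least one healthy and one patient trial",
                  "dscreen_empty_group")
  }
  class(out) <- c("eval_report", class(out))
  out
}

# ---- high-level detector ---------------------------------------------------

#' Fit the one-class dystonia detector on healthy trials
#'
#' End-to-end training for one pianistic task: splits the healthy trial
#' tensors by participant (80/20), augments the training set
#' geometrically (originals plus `n_augment` rotated/scaled copies per
#' trial; validation trials stay unaugmented), trains the convolutional
#' autoencoder, and calibrates the mean + 2 SD anomaly threshold on the
#' held-out participants' reconstruction errors.
#'
#' @param tensors list of healthy `trial_tensor`s with `subject_id`
#'   metadata.
#' @param config a [conv_ae_config()].
#' @param split_seed,train_seed,augment_seed independent integer seeds
#'   for the participant split, weight initialization/shuffling, and
#'   augmentation draws; all are recorded in the fitted object.
#' @param n_augment augmented copies per training trial (default 2).
#' @param rotation_range_deg,scale_range augmentation ranges, see
#'   [augment_batch()].
#' @param train_fraction participant-level training fraction (default
#'   0.8).
#' @param verbose passed to [train_autoencoder()].
#' @return A `dystonia_detector`: list with `model`, `calibration`,
#'   `split`, `config`, `seeds`, `validation_errors`.
#' @export
fit_detector <- function(tensors, config = conv_ae_config(), split_seed = 1L,
                         train_seed = 2L, augment_seed = 3L, n_augment = 2L,
                         rotation_range_deg = 10, scale_range = 0.1,
                         train_fraction = 0.8, verbose = FALSE) {
  sp <- split_by_participant(tensors, train_fraction, seed = split_seed)
  train_set <- augment_batch(sp$train, n_per_tensor = n_augment,
                             rotation_range_deg = rotation_range_deg,
                             scale_range = scale_range, seed = augment_seed)
  model <- train_autoencoder(train_set, config, seed = train_seed,
                             verbose = verbose)
  val_err <- reconstruction_errors(model, sp$validation)
  cal <- calibrate_threshold(val_err, split_seed = split_seed)
  structure(list(model = model, calibration = cal, split = sp,
                 config = config,
                 seeds = list(split = split_seed, train = train_seed,
                              augment = augment_seed),
                 validation_errors = val_err),
            class = "dystonia_detector")
}

#' @export
print.dystonia_detector <- function(x, ...) {
  cat("<dystonia_detector>\n")
  print(x$model)
  print(x$calibration)
  invisible(x)
}

#' Score and classify new trials with a fitted detector
#'
#' @param object a `dystonia_detector`.
#' @param tensors list of `trial_tensor`s.
#' @param ... unused.
#' @return A tibble with one row per trial: `subject_id`, `group`,
#'   `task_id` (from metadata when present), `error`, `threshold`,
#'   `label`.
#' @export
predict.dystonia_detector <- function(object, tensors, ...) {
  err <- reconstruction_errors(object$model, tensors)
  meta_field <- function(field, default) {
    vapply(tensors, function(tn) {
      m <- attr(tn, "meta")
      if (is.null(m) || is.null(m[[field]])) default else as.character(m[[field]])
    }, character(1))
  }
  tibble::tibble(
    subject_id = meta_field("subject_id", NA_character_),
    group = meta_field("group", NA_character_),
    task_id = suppressWarnings(as.integer(meta_field("task_id", NA_character_))),
    error = err,
    threshold = object$calibration$threshold,
    label = classify(err, object$calibration)
  )
}

#' Broom-style accessors for fitted detectors
#'
#' `tidy()` returns the healthy validation errors with their
#' classification; `glance()` the calibration summary.
#'
#' @param x a `dystonia_detector`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.dystonia_detector <- function(x, ...) {
  subj <- vapply(x$split$validation, function(tn) attr(tn, "meta")$subject_id,
                 character(1))
  tibble::tibble(subject_id = subj, error = x$validation_errors,
                 threshold = x$calibration$threshold,
                 label = classify(x$validation_errors, x$calibration))
}

#' @rdname tidy.dystonia_detector
#' @export
glance.dystonia_detector <- function(x, ...) {
  cal <- x$calibration
  tibble::tibble(
    mean_err = cal$mean_err, sd_err = cal$sd_err, threshold = cal$threshold,
    n_validation = cal$n_validation,
    n_train_trials = length(x$split$train),
    n_train_participants = length(x$split$train_subjects),
    epochs = length(x$model$loss_history),
    final_mse = utils::tail(x$model$loss_history, 1)
  )
}
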