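# Readers, writers and validators for the on-disk trial dialects:
# long-format landmark CSV, wide key-trace CSV and trial-metadata JSON.
# All files are UTF-8, '.' decimal, comma-separated, and carry the schema
# line "#dystonia-screen v1" as their first line.

.schema_line <- "#dystonia-screen v1"

# ---- landmark trajectories -------------------------------------------------

#' Construct a landmark trajectory
#'
#' A landmark trajectory is a long tibble with one row per frame per
#' landmark and columns `frame`, `time_s`, `landmark_id`, `x`, `y`, `z`.
#' Coordinates are MediaPipe-style normalized image coordinates (x, y in
#' units of image width/height; z is unitless relative depth).  Every
#' frame must carry all 21 landmarks (ids 0-20) and timestamps must be
#' strictly increasing across frames.
#'
#' @param data data frame with the six columns above.
#' @param fps nominal frame rate in Hz (default 60).
#' @param hand `"left"` or `"right"`.
#' @return A tibble of class `landmark_trajectory` with attributes `fps`
#'   and `hand`.
#' @export
landmark_trajectory <- function(data, fps = 60, hand = c("right", "left")) {
  hand <- match.arg(hand)
  cols <- c("frame", "time_s", "landmark_id", "x", "y", "z")
  if (!all(cols %in% names(data))) {
    abort_dscreen(
      paste0("landmark data must have columns ", paste(cols, collapse = ", ")),
      "dscreen_malformed_row"
    )
  }
  data <- tibble::as_tibble(data)[cols]
  if (anyNA(data) || !all(vapply(data, is.numeric, logical(1)))) {
    abort_dscreen("landmark data contains missing or non-numeric values",
                  "dscreen_malformed_row")
  }
  data <- dplyr::arrange(data, .data$frame, .data$landmark_id)

  by_frame <- split(data$landmark_id, data$frame)
  ok <- vapply(by_frame, function(ids) identical(as.integer(sort(ids)), 0:20),
               logical(1))
  if (!all(ok)) {
    bad <- names(by_frame)[!ok][1]
    abort_dscreen(
      sprintf("frame %s does not carry exactly landmarks 0-20", bad),
      "dscreen_missing_landmark"
    )
  }
  t_frame <- vapply(split(data$time_s, data$frame), function(t) t[1], numeric(1))
  t_frame <- t_frame[order(as.numeric(names(t_frame)))]
  if (length(t_frame) > 1 && any(diff(t_frame) <= 0)) {
    abort_dscreen("frame timestamps must be strictly increasing",
                  "dscreen_non_monotone_time")
  }
  structure(data,
            class = c("landmark_trajectory", class(tibble::tibble())),
            fps = fps, hand = hand)
}

#' @export
print.landmark_trajectory <- function(x, ...) {
  nf <- length(unique(x$frame))
  cat(sprintf("<landmark_trajectory> %d frames, %s hand, %g fps, t = [%.3f, %.3f] s\n",
              nf, attr(x, "hand"), attr(x, "fps"),
              min(x$time_s), max(x$time_s)))
  NextMethod()
}

#' Read / write landmark-trajectory CSV files
#'
#' The long dialect has header `frame,time_s,landmark_id,x,y,z` preceded
#' by the schema comment line.  `read_landmark_csv()` validates that
#' every frame has all 21 landmarks and that time is strictly increasing;
#' `write_landmark_csv()` is its lossless inverse.
#'
#' @param path file path.
#' @param fps,hand passed to [landmark_trajectory()] (the file stores
#'   them in its header comment when written by this package).
#' @return `read_landmark_csv()`: a `landmark_trajectory`;
#'   `write_landmark_csv()`: `path`, invisibly.
#' @export
read_landmark_csv <- function(path, fps = 60, hand = NULL) {
  if (!file.exists(path)) {
    abort_dscreen(sprintf("file not found: %s", path), "dscreen_io_error")
  }
  header <- readLines(path, n = 2L)
  meta <- .parse_header_meta(header)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- c("frame", "time_s", "landmark_id", "x", "y", "z")
  if (!identical(names(df), cols)) {
    abort_dscreen("landmark CSV must have header frame,time_s,landmark_id,x,y,z",
                  "dscreen_malformed_row")
  }
  landmark_trajectory(df,
                      fps = fps %||% meta$fps %||% 60,
                      hand = hand %||% meta$hand %||% "right")
}

#' @rdname read_landmark_csv
#' @param traj a `landmark_trajectory`.
#' @export
write_landmark_csv <- function(traj, path) {
  stopifnot(inherits(traj, "landmark_trajectory"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s fps=%g hand=%s", .schema_line,
                     attr(traj, "fps"), attr(traj, "hand")), con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_header_meta <- function(lines) {
  out <- list()
  ln <- lines[startsWith(lines, "#")]
  if (length(ln)) {
    m <- regmatches(ln[1], gregexpr("(fps|hand)=[^ ]+", ln[1]))[[1]]
    for (kv in m) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      out[[parts[1]]] <- if (parts[1] == "fps") as.numeric(parts[2]) else parts[2]
    }
  }
  out
}

# ---- key traces ------------------------------------------------------------

#' Construct a piano key-displacement trace
#'
#' A key trace records the vertical displacement of all 88 keys (mm,
#' downwards positive, 0 = key at rest) on a uniform 1 ms grid, matching
#' the optical key-measurement format: columns `time_ms`, `k00` .. `k87`
#' with key 0 = A0 and key 87 = C8.  Displacements are quantized at
#' 0.01 mm.
#'
#' @param data data frame with columns `time_ms, k00..k87`.
#' @return A tibble of class `key_trace`.
#' @export
key_trace <- function(data) {
  keys <- sprintf("k%02d", 0:87)
  cols <- c("time_ms", keys)
  if (!all(cols %in% names(data))) {
    abort_dscreen("key trace must have columns time_ms, k00..k87",
                  "dscreen_malformed_row")
  }
  data <- tibble::as_tibble(data)[cols]
  dt <- diff(data$time_ms)
  if (length(dt) && !all(dt == 1)) {
    abort_dscreen("key trace must be uniformly sampled at 1 ms",
                  "dscreen_non_uniform_sampling")
  }
  disp <- as.matrix(data[keys])
  if (anyNA(disp)) {
    abort_dscreen("key trace contains missing values", "dscreen_malformed_row")
  }
  if (any(disp < 0)) {
    abort_dscreen("key displacements must be non-negative",
                  "dscreen_negative_displacement")
  }
  structure(data, class = c("key_trace", class(tibble::tibble())))
}

#' @export
print.key_trace <- function(x, ...) {
  cat(sprintf("<key_trace> %d ms at 1 kHz, max displacement %.2f mm\n",
              nrow(x), max(as.matrix(x[-1]))))
  NextMethod()
}

#' Read / write key-trace CSV files
#'
#' Wide dialect: header `time_ms,k00,...,k87`; one row per millisecond;
#' displacements written at the sensor's 0.01 mm quantization so the
#' round trip is bit-exact.
#'
#' @param path file path.
#' @return `read_keytrace_csv()`: a `key_trace`; `write_keytrace_csv()`:
#'   `path`, invisibly.
#' @export
read_keytrace_csv <- function(path) {
  if (!file.exists(path)) {
    abort_dscreen(sprintf("file not found: %s", path), "dscreen_io_error")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  key_trace(df)
}

#' @rdname read_keytrace_csv
#' @param keys a `key_trace`.
#' @export
write_keytrace_csv <- function(keys, path) {
  stopifnot(inherits(keys, "key_trace"))
  df <- as.data.frame(keys)
  kcols <- setdiff(names(df), "time_ms")
  df[kcols] <- lapply(df[kcols], function(v) sprintf("%.2f", v))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.schema_line, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- trial metadata --------------------------------------------------------

#' Construct trial metadata
#'
#' Describes one recorded performance: who played, which of the 11
#' pianistic tasks, at what tempo and loudness, and with which hand.
#' Fixed-tempo trials must obey the task tempo rule: 100 bpm for the
#' single-note tasks 1-6 and 80 bpm for the chord tasks 7-11.
#'
#' @param subject_id character scalar.
#' @param group `"healthy"` or `"md"` (musician's dystonia).
#' @param hand `"left"` or `"right"`: the hand this trajectory tracks.
#' @param task_id integer 1-11.
#' @param tempo_bpm numeric beats per minute, or `"fastest"`.
#' @param loudness `"pp"` or `"ff"`.
#' @param affected_hand `"left"`, `"right"` or `"none"`.
#' @return A list of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, group = c("healthy", "md"),
                       hand = c("right", "left"), task_id,
                       tempo_bpm = NULL, loudness = c("pp", "ff"),
                       affected_hand = "none") {
  group <- match.arg(group)
  hand <- match.arg(hand)
  loudness <- match.arg(loudness)
  stopifnot(affected_hand %in% c("left", "right", "none"))
  task_id <- as.integer(task_id)
  if (is.na(task_id) || task_id < 1L || task_id > 11L) {
    abort_dscreen("task_id must be in 1..11", "dscreen_malformed_row")
  }
  tempo_bpm <- tempo_bpm %||% task_fixed_tempo(task_id)
  if (is.numeric(tempo_bpm)) tempo_bpm <- as.numeric(tempo_bpm)
  structure(list(subject_id = as.character(subject_id), group = group,
                 hand = hand, affected_hand = affected_hand,
                 task_id = task_id, tempo_bpm = tempo_bpm,
                 loudness = loudness),
            class = "trial_meta")
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("<trial_meta> subject %s (%s), task %d, %s hand, tempo %s, %s\n",
              x$subject_id, x$group, x$task_id, x$hand,
              as.character(x$tempo_bpm), x$loudness))
  invisible(x)
}

#' Fixed tempo prescribed for a task
#'
#' @param task_id integer 1-11.
#' @return 100 (bpm) for the single-note tasks 1-6, 80 for the
#'   chord-striking tasks 7-11.
#' @export
task_fixed_tempo <- function(task_id) {
  ifelse(task_id <= 6, 100, 80)
}

#' Read / write trial-metadata JSON
#'
#' @param path file path.
#' @return `read_trial_meta()`: a `trial_meta`; `write_trial_meta()`:
#'   `path`, invisibly.
#' @export
read_trial_meta <- function(path) {
  if (!file.exists(path)) {
    abort_dscreen(sprintf("file not found: %s", path), "dscreen_io_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trial_meta(subject_id = x$subject_id, group = x$group, hand = x$hand,
             task_id = x$task_id, tempo_bpm = x$tempo_bpm,
             loudness = x$loudness,
             affected_hand = x$affected_hand %||% "none")
}

#' @rdname read_trial_meta
#' @param meta a `trial_meta`.
#' @export
write_trial_meta <- function(meta, path) {
  stopifnot(inherits(meta, "trial_meta"))
  jsonlite::write_json(c(list(schema = "dystonia-screen v1"), unclass(meta)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- trial validation ------------------------------------------------------

#' Assemble and validate one trial
#'
#' Checks that the landmark trajectory and the key trace overlap in time
#' and that a fixed-tempo trial obeys the task tempo rule, then bundles
#' the three parts into a `validated_trial` consumed by the
#' preprocessing pipeline.
#'
#' @param traj a [landmark_trajectory()].
#' @param keys a [key_trace()].
#' @param meta a [trial_meta()].
#' @return A list of class `validated_trial` with elements `trajectory`,
#'   `keys`, `meta`.
#' @export
validate_trial <- function(traj, keys, meta) {
  stopifnot(inherits(traj, "landmark_trajectory"), inherits(keys, "key_trace"),
            inherits(meta, "trial_meta"))
  t_traj <- range(traj$time_s)
  t_keys <- range(keys$time_ms) / 1000
  if (t_traj[1] > t_keys[2] || t_traj[2] < t_keys[1]) {
    abort_dscreen("landmark trajectory and key trace do not overlap in time",
                  "dscreen_no_temporal_overlap")
  }
  if (is.numeric(meta$tempo_bpm)) {
    expected <- task_fixed_tempo(meta$task_id)
    if (meta$tempo_bpm != expected) {
      abort_dscreen(
        sprintf("task %d fixed-tempo trials must be %d bpm, got %g",
                meta$task_id, expected, meta$tempo_bpm),
        "dscreen_task_tempo_mismatch"
      )
    }
  }
  structure(list(trajectory = traj, keys = keys, meta = meta),
            class = "validated_trial")
}

#' @export
print.validated_trial <- function(x, ...) {
  cat("<validated_trial>\n")
  print(x$meta)
  invisible(x)
}
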