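# Trial delimitation, spline time-normalization to the fixed 21 x 3 x 128
# tensor, hand mirroring, and geometric augmentation.

#' Detect the trial window from key kinematics
#'
#' The trial spans the beginning of the first keystroke to the end of the
#' last keystroke, read off the vertical key displacements: onset is the
#' first time any key rises through `press_threshold_mm`, offset the last
#' time any key falls through `release_threshold_mm`.  The release
#' threshold must sit below the press threshold (hysteresis) so sensor
#' noise near one threshold cannot split a keystroke.
#'
#' @param keys a [key_trace()].
#' @param press_threshold_mm press detection level, mm (default 0.5:
#'   well above the 0.01 mm sensor quantization, far below the ~10 mm
#'   full key travel).
#' @param release_threshold_mm release detection level, mm (default 0.3).
#' @return A list of class `trial_window` with `t_start`, `t_end` in
#'   seconds.
#' @export
detect_trial_window <- function(keys, press_threshold_mm = 0.5,
                                release_threshold_mm = 0.3) {
  stopifnot(inherits(keys, "key_trace"))
  if (release_threshold_mm >= press_threshold_mm) {
    abort_dscreen("release threshold must be below press threshold",
                  "dscreen_bad_threshold")
  }
  disp <- as.matrix(keys[setdiff(names(keys), "time_ms")])
  dmax <- do.call(pmax, c(as.data.frame(disp), list(0)))
  pressed <- dmax >= press_threshold_mm
  if (!any(pressed)) {
    abort_dscreen("no key excursion above the press threshold",
                  "dscreen_no_keystroke_detected")
  }
  i_on <- which(pressed)[1]
  i_off <- max(which(dmax >= release_threshold_mm))
  structure(list(t_start = keys$time_ms[i_on] / 1000,
                 t_end = keys$time_ms[i_off] / 1000),
            class = "trial_window")
}

#' @export
print.trial_window <- function(x, ...) {
  cat(sprintf("<trial_window> [%.3f, %.3f] s\n", x$t_start, x$t_end))
  invisible(x)
}

#' Extract the trajectory frames inside a trial window
#'
#' Keeps frames with `t_start <= time_s <= t_end` (closed interval).  At
#' least 4 frames must remain for the cubic spline resampling to be
#' determined.
#'
#' @param traj a [landmark_trajectory()].
#' @param window a `trial_window` (or list with `t_start`, `t_end`).
#' @return A `landmark_trajectory` restricted to the window.
#' @export
extract_segment <- function(traj, window) {
  stopifnot(inherits(traj, "landmark_trajectory"))
  keep <- traj$time_s >= window$t_start & traj$time_s <= window$t_end
  out <- traj[keep, , drop = FALSE]
  if (length(unique(out$frame)) < 4L) {
    abort_dscreen("fewer than 4 frames inside the trial window",
                  "dscreen_segment_too_short")
  }
  landmark_trajectory(out, fps = attr(traj, "fps"), hand = attr(traj, "hand"))
}

#' Mirror a trajectory across the image vertical midline
#'
#' Maps `x` to `1 - x`.  Used to fold left-hand trajectories onto the
#' right-hand frame of reference so a single model serves both hands.
#'
#' @param traj a [landmark_trajectory()].
#' @return The mirrored trajectory; its `hand` attribute is flipped.
#' @export
mirror_trajectory <- function(traj) {
  stopifnot(inherits(traj, "landmark_trajectory"))
  out <- traj
  out$x <- 1 - out$x
  attr(out, "hand") <- if (attr(traj, "hand") == "left") "right" else "left"
  out
}

#' Time-normalize a trajectory onto a fixed-length tensor
#'
#' Each of the 63 landmark-coordinate channels is resampled
#' independently by a natural cubic spline onto `n_samples` uniformly
#' spaced times spanning the segment's first to last timestamp
#' inclusive.  The result is the fixed-shape trial tensor
#' (21 landmarks x 3 coordinates x `n_samples` time points) that the
#' autoencoder consumes.
#'
#' @param traj a [landmark_trajectory()] with at least 4 frames.
#' @param n_samples number of output time samples (default 128).
#' @param meta optional [trial_meta()] to attach.
#' @return A `trial_tensor`: numeric array `21 x 3 x n_samples` with
#'   attributes `meta` and `time_range`.
#' @export
time_normalize <- function(traj, n_samples = 128, meta = NULL) {
  stopifnot(inherits(traj, "landmark_trajectory"))
  frames <- unique(traj$frame)
  if (length(frames) < 4L) {
    abort_dscreen("need at least 4 frames for cubic spline resampling",
                  "dscreen_segment_too_short")
  }
  ord <- order(traj$frame, traj$landmark_id)
  df <- traj[ord, ]
  n_f <- length(frames)
  t_in <- df$time_s[seq(1, nrow(df), by = 21L)]
  t_out <- seq(t_in[1], t_in[n_f], length.out = n_samples)
  # values as (21 x n_f) per coordinate
  vals <- array(0, dim = c(21L, 3L, n_samples))
  for (ci in 1:3) {
    v <- matrix(df[[c("x", "y", "z")[ci]]], nrow = 21L)
    for (l in 1:21) {
      vals[l, ci, ] <- stats::spline(t_in, v[l, ], xout = t_out,
                                     method = "natural")$y
    }
  }
  trial_tensor(vals, meta = meta, time_range = c(t_in[1], t_in[n_f]))
}

#' Construct a trial tensor
#'
#' @param values numeric array `21 x 3 x n`; dimension order is
#'   landmark (0-20), coordinate (x, y, z), time.
#' @param meta optional [trial_meta()].
#' @param time_range optional numeric length-2, seconds.
#' @return A `trial_tensor`.
#' @export
trial_tensor <- function(values, meta = NULL, time_range = NULL) {
  if (length(dim(values)) != 3L || dim(values)[1] != 21L || dim(values)[2] != 3L) {
    abort_dscreen("trial tensor must be 21 x 3 x n", "dscreen_shape_mismatch")
  }
  if (!all(is.finite(values))) {
    abort_dscreen("trial tensor contains non-finite values",
                  "dscreen_malformed_row")
  }
  dimnames(values) <- list(NULL, c("x", "y", "z"), NULL)
  structure(values, class = "trial_tensor", meta = meta,
            time_range = time_range)
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf("<trial_tensor> 21 x 3 x %d\n", dim(x)[3]))
  if (!is.null(attr(x, "meta"))) print(attr(x, "meta"))
  invisible(x)
}

#' Tidy a trial tensor into long format
#'
#' @param x a `trial_tensor`.
#' @param ... unused.
#' @return A tibble with columns `landmark_id`, `coord`, `sample`,
#'   `value`.
#' @export
tidy.trial_tensor <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    landmark_id = rep(0:20, times = 3L * d[3]),
    coord = rep(rep(c("x", "y", "z"), each = 21L), times = d[3]),
    sample = rep(seq_len(d[3]), each = 63L),
    value = as.vector(x)
  )
}

# ---- augmentation ----------------------------------------------------------

#' Geometric augmentation of a trial tensor
#'
#' Emulates camera mounting deviations: the (x, y) channels are rotated
#' about the image centre (0.5, 0.5) and then scaled anisotropically
#' about the same centre; the relative-depth z channel is left
#' untouched.
#'
#' @param tensor a `trial_tensor`.
#' @param rotation_deg in-plane rotation, degrees (counter-clockwise).
#' @param scale_x,scale_y multiplicative factors, must be > 0.
#' @return The transformed `trial_tensor` (same shape and metadata).
#' @export
augment <- function(tensor, rotation_deg = 0, scale_x = 1, scale_y = 1) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (scale_x <= 0 || scale_y <= 0) {
    abort_dscreen("scale factors must be positive", "dscreen_invalid_scale")
  }
  if (rotation_deg == 0 && scale_x == 1 && scale_y == 1) {
    return(tensor)                    # identity transform, bit-exact
  }
  th <- rotation_deg * pi / 180
  x0 <- tensor[, 1, ] - 0.5
  y0 <- tensor[, 2, ] - 0.5
  xr <- cos(th) * x0 - sin(th) * y0
  yr <- sin(th) * x0 + cos(th) * y0
  out <- tensor
  out[, 1, ] <- 0.5 + scale_x * xr
  out[, 2, ] <- 0.5 + scale_y * yr
  out
}

#' Augment a batch of trial tensors
#'
#' For every input tensor emits the original plus `n_per_tensor`
#' augmented copies whose rotation and scale parameters are drawn
#' uniformly from the stated ranges.  Deterministic given `seed`.
#'
#' @param tensors list of `trial_tensor`s.
#' @param n_per_tensor augmented copies per input (>= 0).
#' @param rotation_range_deg half-width of the uniform rotation range
#'   (default 10: rotations in [-10, 10] degrees).
#' @param scale_range half-width of the uniform scale range (default
#'   0.1: scales in [0.9, 1.1]).
#' @param seed integer seed.
#' @return A list of `length(tensors) * (1 + n_per_tensor)` tensors,
#'   originals first for each input.
#' @export
augment_batch <- function(tensors, n_per_tensor = 2, rotation_range_deg = 10,
                          scale_range = 0.1, seed = 1L) {
  stopifnot(n_per_tensor >= 0)
  if (n_per_tensor == 0) return(tensors)
  with_seed(seed, {
    out <- vector("list", length(tensors) * (1L + n_per_tensor))
    k <- 0L
    for (tn in tensors) {
      k <- k + 1L
      out[[k]] <- tn
      for (j in seq_len(n_per_tensor)) {
        k <- k + 1L
        out[[k]] <- augment(
          tn,
          rotation_deg = stats::runif(1, -rotation_range_deg, rotation_range_deg),
          scale_x = stats::runif(1, 1 - scale_range, 1 + scale_range),
          scale_y = stats::runif(1, 1 - scale_range, 1 + scale_range)
        )
      }
    }
    out
  })
}

# ---- pipeline --------------------------------------------------------------

#' Preprocess a validated trial into a trial tensor
#'
#' Runs the full preprocessing chain: detect the keystroke-delimited
#' window, extract the trajectory segment, optionally mirror left-hand
#' trajectories onto the right-hand frame, and spline-normalize to the
#' fixed tensor length.
#'
#' @param trial a [validate_trial()] result.
#' @param n_samples tensor length (default 128).
#' @param mirror_left fold left-hand trials by `x -> 1 - x` (default
#'   TRUE) so one model serves both hands.
#' @param press_threshold_mm,release_threshold_mm passed to
#'   [detect_trial_window()].
#' @return A `trial_tensor` carrying the trial's metadata.
#' @export
trial_to_tensor <- function(trial, n_samples = 128, mirror_left = TRUE,
                            press_threshold_mm = 0.5,
                            release_threshold_mm = 0.3) {
  stopifnot(inherits(trial, "validated_trial"))
  w <- detect_trial_window(trial$keys, press_threshold_mm, release_threshold_mm)
  seg <- extract_segment(trial$trajectory, w)
  if (mirror_left && attr(seg, "hand") == "left") {
    seg <- mirror_trajectory(seg)
  }
  time_normalize(seg, n_samples = n_samples, meta = trial$meta)
}
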