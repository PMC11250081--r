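# Synthetic study data: keystroke-locked healthy and dystonic hand
# kinematics with matching key traces, biomechanical score cohorts, and
# simulated psychophysical observers.  Every generator is a pure
# function of (parameters, seed).

# ---- task catalogue --------------------------------------------------------

# Exemplar note sequences for the 11 pianistic tasks.  Tasks 1-6 are
# single-note sequences played as sixteenths (fixed tempo 100 bpm),
# tasks 7-11 chord strikes played as eighths (fixed tempo 80 bpm).
# Key indices are 0-based over the 88-key range (C4 = 39); fingers are
# 1 = thumb .. 5 = little.
.task_catalogue <- function() {
  sn <- function(keys, fingers) {
    purrr::map2(keys, fingers, function(k, f) list(keys = k, fingers = f))
  }
  ch <- function(keys, fingers) {
    purrr::map2(keys, fingers, function(k, f) list(keys = k, fingers = f))
  }
  list(
    # 1: C-major scale, one octave up and down
    list(name = "scale", category = "single",
         events = sn(as.list(c(39,41,43,44,46,48,50,51,50,48,46,44,43,41,39,41)),
                     as.list(c(1,2,3,1,2,3,4,5,4,3,2,1,3,2,1,2)))),
    # 2: two-note trill
    list(name = "trill", category = "single",
         events = sn(as.list(rep(c(43,44), 8)), as.list(rep(c(2,3), 8)))),
    # 3: arpeggio on white keys
    list(name = "arpeggio", category = "single",
         events = sn(as.list(rep(c(39,43,46,51), 4)), as.list(rep(c(1,2,3,5), 4)))),
    # 4: arpeggio with black keys (thumb-under figure)
    list(name = "arpeggio_black", category = "single",
         events = sn(as.list(rep(c(42,46,49,54), 4)), as.list(rep(c(1,2,3,5), 4)))),
    # 5: broken thirds
    list(name = "broken_thirds", category = "single",
         events = sn(as.list(rep(c(39,43,41,44,43,46,44,48), 2)),
                     as.list(rep(c(1,3,2,4,1,3,2,4), 2)))),
    # 6: five-finger run
    list(name = "five_finger", category = "single",
         events = sn(as.list(rep(c(39,41,43,44,46,44,43,41), 2)),
                     as.list(rep(c(1,2,3,4,5,4,3,2), 2)))),
    # 7: thirds chords
    list(name = "thirds", category = "chord",
         events = ch(list(c(39,43), c(41,44), c(43,46), c(44,48),
                          c(43,46), c(41,44), c(39,43), c(41,44)),
                     list(c(1,3), c(2,4), c(3,5), c(2,4),
                          c(3,5), c(2,4), c(1,3), c(2,4)))),
    # 8: repeated triads
    list(name = "triad_repeat", category = "chord",
         events = ch(rep(list(c(39,43,46)), 8), rep(list(c(1,3,5)), 8))),
    # 9: repeated five-note chords
    list(name = "five_note_chord", category = "chord",
         events = ch(rep(list(c(39,41,43,44,46)), 8),
                     rep(list(1:5), 8))),
    # 10: repeated octaves
    list(name = "octave_repeat", category = "chord",
         events = ch(rep(list(c(39,51)), 8), rep(list(c(1,5)), 8))),
    # 11: octaves up and down
    list(name = "octave_walk", category = "chord",
         events = ch(list(c(39,51), c(41,53), c(43,55), c(44,56),
                          c(43,55), c(41,53), c(39,51), c(41,53)),
                     rep(list(c(1,5)), 8)))
  )
}

#' Task specification
#'
#' Exemplar note/fingering content for one of the 11 pianistic tasks:
#' single-note sequences (scale, trill, arpeggios, broken thirds,
#' five-finger run; tasks 1-6) and chord strikes (thirds, repeated
#' triads, five-note chords, octaves; tasks 7-11).  The printed scores
#' of the original tasks are not recoverable from text, so these are
#' plausible exemplars with the same categories.
#'
#' @param task_id integer 1-11.
#' @return A list of class `task_spec` with `task_id`, `name`,
#'   `category` (`"single"` / `"chord"`), `fixed_tempo_bpm`, `n_events`
#'   and `events` (list of `keys` / `fingers` per strike).
#' @export
task_spec <- function(task_id) {
  task_id <- as.integer(task_id)
  stopifnot(task_id >= 1L, task_id <= 11L)
  tk <- .task_catalogue()[[task_id]]
  structure(list(task_id = task_id, name = tk$name, category = tk$category,
                 fixed_tempo_bpm = task_fixed_tempo(task_id),
                 n_events = length(tk$events), events = tk$events),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> task %d (%s, %s), %d events, fixed tempo %d bpm\n",
              x$task_id, x$name, x$category, x$n_events, x$fixed_tempo_bpm))
  invisible(x)
}

#' Generator configuration
#'
#' Recording rates and noise level the generator emulates: 60 Hz video
#' landmarks, 1 kHz key displacement, and Gaussian landmark noise of
#' 0.003 normalized image units (about 4 px at 1280-px image width) —
#' visible but not class-dominating.
#'
#' @param fps video frame rate (default 60).
#' @param key_rate_hz key-trace sampling rate (default 1000).
#' @param noise_sd landmark noise SD in normalized units (default
#'   0.003).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(fps = 60, key_rate_hz = 1000, noise_sd = 0.003) {
  structure(list(fps = fps, key_rate_hz = key_rate_hz, noise_sd = noise_sd),
            class = "generator_config")
}

#' Dystonic perturbation pattern
#'
#' Which fingers are affected and how strongly.  At `severity` 0 every
#' perturbation magnitude is exactly 0; at 1 the affected fingertips
#' carry a sustained flexion bias toward the key plane of 0.03
#' normalized units, strike dips lose 50% of their amplitude, strike
#' timing jitters with SD 20 ms, and 40% of the affected dip couples
#' onto adjacent fingers.
#'
#' @param fingers character subset of thumb/index/middle/ring/little.
#' @param severity numeric in `[0, 1]`.
#' @return A list of class `dystonia_pattern`.
#' @export
dystonia_pattern <- function(fingers = c("index", "middle"), severity = 0.8) {
  stopifnot(all(fingers %in% .finger_names), severity >= 0, severity <= 1)
  structure(list(fingers = fingers, severity = severity),
            class = "dystonia_pattern")
}

# ---- key traces ------------------------------------------------------------

# single-key excursion: raised-cosine attack and release (10 ms each)
# around a flat hold at `depth` mm
.key_excursion <- function(t_ms, onset_ms, offset_ms, depth, ramp_ms = 10) {
  d <- numeric(length(t_ms))
  rise <- t_ms >= onset_ms & t_ms < onset_ms + ramp_ms
  hold <- t_ms >= onset_ms + ramp_ms & t_ms <= offset_ms - ramp_ms
  fall <- t_ms > offset_ms - ramp_ms & t_ms <= offset_ms
  d[rise] <- depth * (1 - cos(pi * (t_ms[rise] - onset_ms) / ramp_ms)) / 2
  d[hold] <- depth
  d[fall] <- depth * (1 + cos(pi * (t_ms[fall] - (offset_ms - ramp_ms)) / ramp_ms)) / 2
  d
}

#' Generate a key trace for a task
#'
#' One depression/release excursion (about 10 mm deep, 10 ms
#' raised-cosine attack and release) per note event, at tempo-determined
#' onsets plus a small timing jitter.  Single-note tasks are played as
#' sixteenths, chord tasks as eighths.  Ground-truth event onsets and
#' offsets are attached as attribute `"events"`.
#'
#' @param task a [task_spec()] (or task id).
#' @param tempo_bpm tempo (default: the task's fixed tempo).
#' @param seed integer seed.
#' @param onset_jitter_sd SD of the per-event onset jitter, s (default
#'   0.005).
#' @param start_s time of the first nominal onset (default 0.5).
#' @return A [key_trace()]; `attr(, "events")` is a tibble with
#'   `event`, `onset_s`, `offset_s` and list-columns `keys`, `fingers`.
#' @export
gen_key_trace <- function(task, tempo_bpm = NULL, seed = 1L,
                          onset_jitter_sd = 0.005, start_s = 0.5) {
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  tempo_bpm <- tempo_bpm %||% task$fixed_tempo_bpm
  ioi <- if (task$category == "single") 60 / tempo_bpm / 4 else 60 / tempo_bpm / 2
  n_ev <- task$n_events
  with_seed(seed, {
    onsets <- start_s + (seq_len(n_ev) - 1L) * ioi +
      if (n_ev) stats::rnorm(n_ev, 0, onset_jitter_sd) else numeric(0)
    durations <- pmin(0.4, pmax(0.08, 0.6 * ioi))
    offsets <- onsets + durations
    depths <- if (n_ev) pmin(11, pmax(8, stats::rnorm(n_ev, 10, 0.5))) else numeric(0)
    total_ms <- ceiling((if (n_ev) max(offsets) else start_s) * 1000) + 300
    t_ms <- 0:total_ms
    disp <- matrix(0, nrow = length(t_ms), ncol = 88)
    for (e in seq_len(n_ev)) {
      exc <- .key_excursion(t_ms, onsets[e] * 1000, offsets[e] * 1000, depths[e])
      for (k in task$events[[e]]$keys) {
        disp[, k + 1L] <- pmax(disp[, k + 1L], exc)
      }
    }
    disp <- round(disp, 2)                      # 0.01 mm quantization
    df <- tibble::as_tibble(as.data.frame(disp))
    names(df) <- sprintf("k%02d", 0:87)
    df <- dplyr::bind_cols(tibble::tibble(time_ms = t_ms), df)
    out <- key_trace(df)
    attr(out, "events") <- tibble::tibble(
      event = seq_len(n_ev), onset_s = onsets, offset_s = offsets,
      keys = purrr::map(task$events, "keys"),
      fingers = purrr::map(task$events, "fingers")
    )
    out
  })
}

# ---- hand kinematics -------------------------------------------------------

# static right-hand template in normalized image coordinates, hand
# centred at wrist (x, y) = (0, 0.62); keys lie toward smaller y
.hand_template <- function() {
  wrist <- c(0, 0.62, 0)
  dx <- c(-0.045, -0.02, 0, 0.02, 0.042)        # thumb..little spread
  len <- c(0.10, 0.165, 0.18, 0.17, 0.135)      # chain length in y
  frac <- c(0.45, 0.70, 0.88, 1.00)             # mcp, pip, dip, tip
  xspread <- c(0.55, 0.75, 0.90, 1.00)
  x <- c(wrist[1], unlist(lapply(1:5, function(f) dx[f] * xspread)))
  y <- c(wrist[2], unlist(lapply(1:5, function(f) wrist[2] - len[f] * frac)))
  z <- rep(0, 21)
  list(x = x, y = y, z = z)
}

# raised-cosine strike profile centred between onset and offset,
# with 40 ms of anticipation/recovery on each side
.strike_profile <- function(t, onset, offset, lead = 0.04) {
  a <- onset - lead
  b <- offset + lead
  w <- numeric(length(t))
  inside <- t >= a & t <= b
  w[inside] <- (1 - cos(2 * pi * (t[inside] - a) / (b - a))) / 2
  w
}

# weights of the dip along a finger chain (mcp, pip, dip, tip)
.chain_weights <- c(0.10, 0.40, 0.70, 1.00)

#' Generate a healthy piano trial
#'
#' Builds a schematic articulated right hand over the keyboard: the
#' hand translates along the key axis so the assigned finger reaches
#' each note, the striking finger's chain dips toward the key plane in
#' synchrony with the key excursion, smooth low-frequency wrist sway and
#' Gaussian landmark noise are added, and per-subject style offsets
#' (dip amplitude, hand position, timing lead) are drawn once per
#' subject.
#'
#' @param task a [task_spec()] or task id.
#' @param tempo_bpm tempo (default: the task's fixed tempo).
#' @param config a [generator_config()].
#' @param seed integer seed (drives everything: subject style, key
#'   timing, noise).
#' @param subject_id,hand,loudness,group metadata fields.
#' @param subject_params optional list overriding the per-subject draws
#'   (`amp_scale`, `y_offset`, `x_offset`, `timing_lead`); used by the
#'   cohort generator to keep a subject's style constant across trials.
#' @return A [validate_trial()] result (trajectory + keys + meta).
#' @export
gen_healthy_trial <- function(task, tempo_bpm = NULL,
                              config = generator_config(), seed = 1L,
                              subject_id = "S01", hand = "right",
                              loudness = "pp", group = "healthy",
                              subject_params = NULL) {
  .gen_trial_impl(task, tempo_bpm, config, seed, subject_id, hand, loudness,
                  group, subject_params, pattern = NULL)
}

#' Generate a dystonic piano trial
#'
#' Applies a [dystonia_pattern()] on top of the healthy trial for the
#' same seed: affected finger chains acquire a sustained flexion bias
#' toward the key plane, reduced strike-dip amplitude, extra strike
#' timing jitter, and co-movement coupling onto adjacent fingers — all
#' scaled by `severity`, so severity 0 reproduces the healthy trial
#' bitwise.
#'
#' @inheritParams gen_healthy_trial
#' @param pattern a [dystonia_pattern()].
#' @return A [validate_trial()] result with `group = "md"` metadata.
#' @export
gen_dystonic_trial <- function(task, tempo_bpm = NULL,
                               pattern = dystonia_pattern(),
                               config = generator_config(), seed = 1L,
                               subject_id = "P01", hand = "right",
                               loudness = "pp", subject_params = NULL) {
  stopifnot(inherits(pattern, "dystonia_pattern"))
  .gen_trial_impl(task, tempo_bpm, config, seed, subject_id, hand, loudness,
                  group = "md", subject_params, pattern = pattern)
}

.gen_trial_impl <- function(task, tempo_bpm, config, seed, subject_id, hand,
                            loudness, group, subject_params, pattern) {
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  stopifnot(inherits(config, "generator_config"))
  tempo_bpm <- tempo_bpm %||% task$fixed_tempo_bpm

  subject_params <- subject_params %||% with_seed(child_seed(seed, 1L), list(
    amp_scale = stats::rnorm(1, 1, 0.08),
    y_offset = stats::rnorm(1, 0, 0.008),
    x_offset = stats::rnorm(1, 0, 0.010),
    timing_lead = stats::rnorm(1, 0, 0.008)
  ))

  keys <- gen_key_trace(task, tempo_bpm, seed = child_seed(seed, 2L))
  events <- attr(keys, "events")
  duration_s <- max(keys$time_ms) / 1000
  n_frames <- floor(duration_s * config$fps) + 1L
  t <- (seq_len(n_frames) - 1L) / config$fps

  tmpl <- .hand_template()
  dip_amp <- 0.030 * subject_params$amp_scale      # fingertip dip, y units
  z_amp <- 0.018 * subject_params$amp_scale

  # hand translation: assigned finger over its key at each event
  dx_f <- tmpl$x[vapply(.finger_chain, function(ch) ch[4] + 1L, integer(1))]
  target_t <- events$onset_s
  target_x <- vapply(seq_len(nrow(events)), function(e) {
    f1 <- events$fingers[[e]][1]
    key_to_x(events$keys[[e]][1]) - dx_f[f1]
  }, numeric(1))
  knots_t <- c(0, target_t, duration_s)
  knots_x <- c(target_x[1], target_x, target_x[length(target_x)])
  wrist_x <- stats::spline(knots_t, knots_x, xout = t, method = "natural")$y +
    subject_params$x_offset

  with_seed(child_seed(seed, 3L), {
    sway_phase <- stats::runif(1, 0, 2 * pi)
    ev_jit <- stats::rnorm(nrow(events), 0, 0.005)

    X <- matrix(rep(tmpl$x, each = n_frames), n_frames, 21) + wrist_x
    Y <- matrix(rep(tmpl$y, each = n_frames), n_frames, 21) +
      subject_params$y_offset + 0.004 * sin(2 * pi * 0.5 * t + sway_phase)
    Z <- matrix(rep(tmpl$z, each = n_frames), n_frames, 21)

    # keystroke-locked dips of the striking finger chains
    dip_w <- matrix(0, n_frames, 5)              # per-finger strike weight
    for (e in seq_len(nrow(events))) {
      sh <- subject_params$timing_lead + ev_jit[e]
      w <- .strike_profile(t, events$onset_s[e] + sh, events$offset_s[e] + sh)
      for (f in events$fingers[[e]]) {
        dip_w[, f] <- pmax(dip_w[, f], w)
      }
    }
    for (f in 1:5) {
      ids <- .finger_chain[[f]] + 1L             # landmark columns
      for (j in 1:4) {
        Y[, ids[j]] <- Y[, ids[j]] - dip_amp * .chain_weights[j] * dip_w[, f]
        Z[, ids[j]] <- Z[, ids[j]] - z_amp * .chain_weights[j] * dip_w[, f]
      }
    }

    # measurement noise on every landmark coordinate
    X <- X + stats::rnorm(length(X), 0, config$noise_sd)
    Y <- Y + stats::rnorm(length(Y), 0, config$noise_sd)
    Z <- Z + stats::rnorm(length(Z), 0, config$noise_sd)
  })

  # dystonic perturbation, every term scaled by severity
  if (!is.null(pattern) && length(pattern$fingers)) {
    sev <- pattern$severity
    aff <- match(pattern$fingers, .finger_names)
    with_seed(child_seed(seed, 4L), {
      ev_jit2 <- stats::rnorm(nrow(events), 0, 0.020)
      for (f in aff) {
        ids <- .finger_chain[[f]] + 1L
        # rebuild this finger's healthy strike weight and its jittered copy
        w0 <- numeric(n_frames); w1 <- numeric(n_frames)
        for (e in seq_len(nrow(events))) {
          if (!(f %in% events$fingers[[e]])) next
          sh <- subject_params$timing_lead + ev_jit[e]
          w0 <- pmax(w0, .strike_profile(t, events$onset_s[e] + sh,
                                         events$offset_s[e] + sh))
          sh2 <- sh + sev * ev_jit2[e]
          w1 <- pmax(w1, .strike_profile(t, events$onset_s[e] + sh2,
                                         events$offset_s[e] + sh2))
        }
        for (j in 2:4) {                         # pip, dip, tip
          cw <- .chain_weights[j]
          # sustained flexion bias toward the key plane, strongest between strikes
          Y[, ids[j]] <- Y[, ids[j]] -
            sev * 0.030 * cw * (1 - 0.5 * w0)
          Z[, ids[j]] <- Z[, ids[j]] - sev * 0.012 * cw * (1 - 0.5 * w0)
          # reduced, time-jittered strike dip: remove half the healthy dip
          # and replace the remainder at the jittered time
          Y[, ids[j]] <- Y[, ids[j]] + dip_amp * cw * (w0 - (1 - 0.5 * sev) * w1)
        }
        # co-movement coupling onto adjacent fingers
        for (nb in intersect(c(f - 1L, f + 1L), 1:5)) {
          idn <- .finger_chain[[nb]] + 1L
          for (j in 2:4) {
            Y[, idn[j]] <- Y[, idn[j]] -
              sev * 0.4 * dip_amp * .chain_weights[j] * w0
          }
        }
      }
    })
  }

  if (hand == "left") X <- 1 - X

  traj <- landmark_trajectory(tibble::tibble(
    frame = rep(0:(n_frames - 1L), times = 21L),
    time_s = rep(t, times = 21L),
    landmark_id = rep(0:20, each = n_frames),
    x = as.vector(X), y = as.vector(Y), z = as.vector(Z)
  ), fps = config$fps, hand = hand)

  meta <- trial_meta(subject_id = subject_id, group = group, hand = hand,
                     task_id = task$task_id, tempo_bpm = tempo_bpm,
                     loudness = loudness,
                     affected_hand = if (identical(group, "md")) hand else "none")
  validate_trial(traj, keys, meta)
}

#' Generate a cohort of piano trials
#'
#' Draws `n_subjects` subjects, each with a stable per-subject style,
#' and `trials_per_subject` trials per subject.  Dystonic subjects all
#' carry `pattern`.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials per subject.
#' @param task a [task_spec()] or task id (default 4).
#' @param group `"healthy"` or `"md"`.
#' @param pattern a [dystonia_pattern()] (used when `group = "md"`).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param id_prefix subject-id prefix (default `"H"` for healthy,
#'   `"P"` for md).
#' @return A tibble with columns `subject_id`, `group`, `trial_idx` and
#'   list-column `trial` of [validate_trial()] objects.
#' @export
gen_cohort <- function(n_subjects, trials_per_subject, task = 4L,
                       group = c("healthy", "md"),
                       pattern = dystonia_pattern(),
                       config = generator_config(), seed = 1L,
                       id_prefix = NULL) {
  group <- match.arg(group)
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  id_prefix <- id_prefix %||% if (group == "healthy") "H" else "P"
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", id_prefix, s)
    sp <- with_seed(child_seed(seed, s, 0L), list(
      amp_scale = stats::rnorm(1, 1, 0.08),
      y_offset = stats::rnorm(1, 0, 0.008),
      x_offset = stats::rnorm(1, 0, 0.010),
      timing_lead = stats::rnorm(1, 0, 0.008)
    ))
    for (r in seq_len(trials_per_subject)) {
      tseed <- child_seed(seed, s, r)
      trial <- if (group == "healthy") {
        gen_healthy_trial(task, config = config, seed = tseed,
                          subject_id = sid, subject_params = sp)
      } else {
        gen_dystonic_trial(task, pattern = pattern, config = config,
                           seed = tseed, subject_id = sid, subject_params = sp)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, group = group, trial_idx = r, trial = list(trial))
    }
  }
  dplyr::bind_rows(rows)
}

#' Preprocess a cohort into trial tensors
#'
#' @param cohort a [gen_cohort()] tibble (or any tibble with a `trial`
#'   list-column of validated trials).
#' @param ... passed to [trial_to_tensor()].
#' @return A list of `trial_tensor`s.
#' @export
cohort_tensors <- function(cohort, ...) {
  purrr::map(cohort$trial, trial_to_tensor, ...)
}

# ---- biomechanical cohorts -------------------------------------------------

# plausible healthy reference for the six function scores; per finger
# (thumb, index, middle, ring, little)
.biomech_reference <- function() {
  ref <- list(
    strength = list(mean = c(45, 40, 42, 32, 26), sd = 8),          # N
    reduction_ratio = list(mean = c(0.65, 0.60, 0.58, 0.55, 0.50), sd = 0.10),
    independence = list(mean = c(0.92, 0.85, 0.75, 0.70, 0.78), sd = 0.07),
    agility = list(mean = c(5.5, 6.5, 6.3, 5.8, 5.5), sd = 0.8),    # taps/s
    rom_flex_ext = list(mean = c(110, 100, 105, 100, 95), sd = 10), # deg
    rom_abd_add = list(mean = c(60, 25, 20, 22, 30), sd = 6)        # deg
  )
  dplyr::bind_rows(lapply(names(ref), function(f) {
    tibble::tibble(fn = f, finger = .finger_names,
                   ref_mean = ref[[f]]$mean, ref_sd = ref[[f]]$sd)
  }))
}

#' Generate a biomechanical score cohort
#'
#' Healthy subjects score `Normal(reference mean, reference SD)` in
#' every cell of both hands; dystonic subjects additionally receive an
#' `effect[fn]`-SD shift on all five fingers of their affected hand for
#' the named functions (default: force-reduction ratio and independence
#' shifted by -1.5 SD, strength/agility/range-of-motion untouched,
#' mirroring the structure of deficits limited to multi-finger
#' control).
#'
#' @param n_healthy,n_md subjects per group (>= 2).
#' @param effect named numeric: SD shift per function on the affected
#'   hand.
#' @param seed integer seed.
#' @return A long tibble `subject`, `group`, `affected_hand`, `hand`,
#'   `finger`, `fn`, `value`.
#' @export
gen_biomech_cohort <- function(n_healthy = 20L, n_md = 16L,
                               effect = c(reduction_ratio = -1.5,
                                          independence = -1.5),
                               seed = 1L) {
  stopifnot(n_healthy >= 2L, n_md >= 2L)
  ref <- .biomech_reference()
  cells <- tidyr::crossing(hand = c("left", "right"),
                           tibble::tibble(fn = ref$fn, finger = ref$finger,
                                          ref_mean = ref$ref_mean,
                                          ref_sd = ref$ref_sd))
  with_seed(seed, {
    gen_subject <- function(sid, group) {
      affected <- if (group == "md") sample(c("left", "right"), 1L) else "none"
      d <- cells
      shift <- numeric(nrow(d))
      if (group == "md") {
        for (fn in names(effect)) {
          hit <- d$fn == fn & d$hand == affected
          shift[hit] <- effect[[fn]] * d$ref_sd[hit]
        }
      }
      d$value <- stats::rnorm(nrow(d), d$ref_mean + shift, d$ref_sd)
      tibble::tibble(subject = sid, group = group, affected_hand = affected,
                     hand = d$hand, finger = d$finger, fn = d$fn,
                     value = d$value)
    }
    dplyr::bind_rows(
      purrr::map(seq_len(n_healthy),
                 function(i) gen_subject(sprintf("H%02d", i), "healthy")),
      purrr::map(seq_len(n_md),
                 function(i) gen_subject(sprintf("P%02d", i), "md"))
    )
  })
}

# ---- psychophysical observers ----------------------------------------------

#' Simulated temporal-order-judgment observer
#'
#' Responds correctly with probability
#' `0.5 + (0.5 - lapse) * pnorm(slope * (log10(soa) - log10(threshold)))`.
#' With `lapse = 0`, `threshold_ms` is exactly the observer's 75%
#' correct point.
#'
#' @param threshold_ms location of the psychometric function, ms (> 0).
#' @param slope slope per log10-ms (default 3).
#' @param lapse lapse rate (default 0).
#' @return A list of class `sim_observer`.
#' @export
gen_observer <- function(threshold_ms, slope = 3, lapse = 0) {
  stopifnot(threshold_ms > 0, lapse >= 0, lapse < 0.5)
  structure(list(threshold_ms = threshold_ms, slope = slope, lapse = lapse),
            class = "sim_observer")
}

#' Probability of a correct response from a simulated observer
#'
#' @param observer a [gen_observer()].
#' @param soa_ms stimulus-onset asynchrony, ms.
#' @return Numeric probability (vectorized over `soa_ms`).
#' @export
observer_p_correct <- function(observer, soa_ms) {
  stopifnot(inherits(observer, "sim_observer"))
  .psychometric(soa_ms, observer$threshold_ms, observer$slope, observer$lapse)
}
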