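# Small fixtures built in code, shared across test files.

# minimal well-formed landmark data frame: all 21 landmarks per frame
make_landmark_df <- function(n_frames = 2, fps = 60) {
  df <- expand.grid(landmark_id = 0:20, frame = 0:(n_frames - 1))
  df$time_s <- df$frame / fps
  df$x <- 0.4 + 0.01 * df$landmark_id / 20
  df$y <- 0.5 + 0.002 * df$frame
  df$z <- 0
  df[, c("frame", "time_s", "landmark_id", "x", "y", "z")]
}

# random smooth-ish trajectory for round-trip and resampling tests
make_random_trajectory <- function(n_frames = 100, fps = 60, seed = 42) {
  set.seed(seed)
  base <- make_landmark_df(n_frames, fps)
  base$x <- 0.5 + 0.05 * sin(2 * pi * base$time_s) + rnorm(nrow(base), 0, 0.01)
  base$y <- 0.5 + 0.05 * cos(2 * pi * base$time_s) + rnorm(nrow(base), 0, 0.01)
  base$z <- rnorm(nrow(base), 0, 0.02)
  landmark_trajectory(base, fps = fps, hand = "right")
}

# zero key-trace tibble of n_ms milliseconds
make_zero_keytrace_df <- function(n_ms = 1000) {
  df <- as.data.frame(matrix(0, n_ms, 88))
  names(df) <- sprintf("k%02d", 0:87)
  cbind(data.frame(time_ms = 0:(n_ms - 1)), df)
}

# key trace with raised-cosine presses; press_windows is a list of
# c(onset_ms, offset_ms) pairs on key `key`
make_press_keytrace <- function(press_windows, key = 39, n_ms = 1500,
                                depth = 10, ramp = 10) {
  df <- make_zero_keytrace_df(n_ms)
  t <- df$time_ms
  for (w in press_windows) {
    on <- w[1]; off <- w[2]
    d <- numeric(length(t))
    rise <- t >= on & t < on + ramp
    hold <- t >= on + ramp & t <= off - ramp
    fall <- t > off - ramp & t <= off
    d[rise] <- depth * (1 - cos(pi * (t[rise] - on) / ramp)) / 2
    d[hold] <- depth
    d[fall] <- depth * (1 + cos(pi * (t[fall] - (off - ramp)) / ramp)) / 2
    col <- sprintf("k%02d", key)
    df[[col]] <- pmax(df[[col]], round(d, 2))
  }
  key_trace(df)
}

# random trial tensor
make_random_tensor <- function(n = 128, seed = 1) {
  set.seed(seed)
  trial_tensor(array(runif(21 * 3 * n), c(21, 3, n)))
}

# tensors with subject metadata, for split/detector tests
make_subject_tensors <- function(n_subjects, trials_each = 2, n = 32) {
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(trials_each)) {
      tn <- make_random_tensor(n, seed = s * 100 + r)
      attr(tn, "meta") <- trial_meta(sprintf("S%02d", s), "healthy", "right",
                                     task_id = 4)
      out[[length(out) + 1L]] <- tn
    }
  }
  out
}

# brute-force Mann-Whitney oracle: enumerate every subset of pooled
# indices by bitmask, midranks via base rank(); independent of the
# package's combn-based path
mwu_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  devs <- c()
  for (m in 0:(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    if (length(idx) != n1) next
    devs <- c(devs, abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - mu))
  }
  list(u = u_obs, p = mean(devs >= abs(u_obs - mu) - 1e-12))
}

# smooth, compressible tensor: a few shared low-frequency temporal
# components with per-channel loadings, plus light noise
make_smooth_tensor <- function(n = 32, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  basis <- rbind(sin(2 * pi * t), cos(2 * pi * t), sin(4 * pi * t))
  gain <- seq(0.5, 1.5, length.out = 21)         # per-landmark amplitude
  comp <- as.numeric(rnorm(3) %*% basis)         # shared temporal component
  arr <- array(0, c(21, 3, n))
  for (ci in 1:3) {
    for (l in 1:21) {
      arr[l, ci, ] <- 0.5 + 0.1 * gain[l] * comp + rnorm(n, 0, 0.002)
    }
  }
  trial_tensor(arr)
}
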