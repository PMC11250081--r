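# Per-finger biomechanical function scores, z-score profiles, the
# left-right asymmetry norm, and the Mann-Whitney U + Benjamini-Hochberg
# group comparison.

#' Force reduction ratio under simultaneous exertion
#'
#' Ratio of the force a finger exerts while all five fingers press
#' simultaneously to that finger's maximum individual strength.
#'
#' @param simultaneous_force force during all-finger exertion, N.
#' @param max_force maximum individual finger strength, N (> 0).
#' @return Non-negative numeric (vectorized).
#' @export
force_reduction_ratio <- function(simultaneous_force, max_force) {
  if (any(max_force <= 0)) {
    abort_dscreen("max_force must be positive", "dscreen_zero_max_force")
  }
  if (any(simultaneous_force < 0)) {
    abort_dscreen("forces must be non-negative", "dscreen_malformed_row")
  }
  simultaneous_force / max_force
}

#' Finger independence index
#'
#' During the 20%-MVC sustained hold of one designated finger, the other
#' fingers involuntarily co-contract (enslaving).  The index is
#' `1 - other_forces_sum / designated_force`, floored at 0: 1 means
#' perfect individuation, 0 means the enslaved force matches or exceeds
#' the instructed force.  Forces should be trial means over the central
#' 3 s of the 5 s hold (see [sustained_hold_mean()]).
#'
#' @param designated_force instructed-finger force, N (> 0).
#' @param other_forces_sum summed force of the four other fingers, N.
#' @return Numeric in `[0, 1]` (vectorized).
#' @export
independence_index <- function(designated_force, other_forces_sum) {
  if (any(designated_force <= 0)) {
    abort_dscreen("designated_force must be positive",
                  "dscreen_zero_designated_force")
  }
  pmax(0, 1 - other_forces_sum / designated_force)
}

#' Mean force over the central window of a sustained hold
#'
#' Summarizes a 5 s sustained-hold force trace by its mean over the
#' central 3 s, discarding the 1 s ramp-in/ramp-out transients.
#'
#' @param time_s sample times, seconds.
#' @param force force samples, N.
#' @param duration_s nominal trial duration (default 5).
#' @param trim_s transient trimmed from each end (default 1).
#' @return Numeric scalar.
#' @export
sustained_hold_mean <- function(time_s, force, duration_s = 5, trim_s = 1) {
  keep <- time_s >= trim_s & time_s <= duration_s - trim_s
  if (!any(keep)) {
    abort_dscreen("no samples inside the central window",
                  "dscreen_malformed_row")
  }
  mean(force[keep])
}

#' Tapping agility rate
#'
#' @param tap_times tap onset times within the trial, seconds.
#' @param trial_duration trial length, seconds (default 5).
#' @return Taps per second.
#' @export
agility_rate <- function(tap_times, trial_duration = 5) {
  if (length(tap_times) &&
      (any(tap_times < 0) || any(tap_times > trial_duration))) {
    abort_dscreen("tap times must lie within the trial",
                  "dscreen_malformed_row")
  }
  length(tap_times) / trial_duration
}

# ---- z-score profiles and asymmetry ---------------------------------------

#' Fit a reference distribution for z-scoring
#'
#' Computes the per-function, per-finger mean and SD over a reference
#' cohort (normally the healthy controls), pooling the two hands so
#' left and right scores share one scale — a prerequisite for a
#' meaningful left-minus-right difference.
#'
#' @param profiles long tibble with columns `subject`, `group`, `hand`,
#'   `finger`, `fn` (function name) and `value`.
#' @return A tibble `fn`, `finger`, `ref_mean`, `ref_sd`.
#' @export
fit_reference <- function(profiles) {
  stopifnot(all(c("finger", "fn", "value") %in% names(profiles)))
  out <- profiles |>
    dplyr::group_by(.data$fn, .data$finger) |>
    dplyr::summarise(ref_mean = mean(.data$value),
                     ref_sd = stats::sd(.data$value), .groups = "drop")
  if (any(!is.finite(out$ref_sd)) || any(out$ref_sd <= 0)) {
    abort_dscreen("reference SD must be positive for every cell",
                  "dscreen_zero_reference_sd")
  }
  out
}

#' Z-score biomechanical profiles against a reference
#'
#' @param profiles long tibble as in [fit_reference()].
#' @param reference a [fit_reference()] result.
#' @return `profiles` with an added `z` column.
#' @export
zscore_profile <- function(profiles, reference) {
  if (any(reference$ref_sd <= 0)) {
    abort_dscreen("reference SD must be positive", "dscreen_zero_reference_sd")
  }
  out <- dplyr::inner_join(profiles, reference, by = c("fn", "finger"))
  if (nrow(out) != nrow(profiles)) {
    abort_dscreen("reference is missing cells present in the profiles",
                  "dscreen_malformed_row")
  }
  dplyr::mutate(out, z = (.data$value - .data$ref_mean) / .data$ref_sd,
                ref_mean = NULL, ref_sd = NULL)
}

#' Left-right asymmetry of a five-finger z-profile
#'
#' The Euclidean norm of the difference between the left- and
#' right-hand z-score vectors ordered (thumb, index, middle, ring,
#' little).
#'
#' @param z_left,z_right numeric length-5 vectors.
#' @return Non-negative scalar; 0 iff the profiles are identical.
#' @export
asymmetry <- function(z_left, z_right) {
  if (length(z_left) != length(z_right)) {
    abort_dscreen("z-profiles must have equal length", "dscreen_length_mismatch")
  }
  sqrt(sum((z_left - z_right)^2))
}

# ---- group statistics ------------------------------------------------------

#' Mann-Whitney U test with midranks and exact small-sample p-values
#'
#' Computes the U statistic of `x` (rank sum of `x` minus
#' `n1 (n1 + 1) / 2`) using midranks for ties.  For pooled sample sizes
#' up to `exact_max` the two-sided p-value is exact, obtained by
#' enumerating every allocation of the pooled midranks; above that, the
#' normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y numeric samples.
#' @param exact_max pooled-size cutoff for exact enumeration (default
#'   12).
#' @return A list `u`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (length(x) < 1L || length(y) < 1L) {
    abort_dscreen("both groups must be non-empty", "dscreen_empty_group")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                       # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    dev_obs <- abs(u_obs - mu)
    sets <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= dev_obs - 1e-12)
    list(u = u_obs, p = p, method = "exact")
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u_obs, p = 1, method = "normal"))
    z <- u_obs - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(u = u_obs, p = p, method = "normal")
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    abort_dscreen("p-values must lie in [0, 1]", "dscreen_out_of_range_p")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Compare left-right asymmetry between groups, function by function
#'
#' For each biomechanical function: z-scores every subject's per-finger
#' scores against the healthy reference (pooled over hands), forms the
#' left-minus-right asymmetry norm per subject, compares healthy
#' vs. dystonic asymmetries with the Mann-Whitney U test, and adjusts
#' the p-values across the tested functions with Benjamini-Hochberg.
#'
#' @param profiles long tibble with columns `subject`, `group`
#'   (`"healthy"` / `"md"`), `hand` (`"left"` / `"right"`), `finger`,
#'   `fn`, `value`.
#' @param functions functions to test (default: all present).
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return A tibble of class `asymmetry_comparison`: one row per
#'   function with `n_healthy`, `n_md`, `median_healthy`, `median_md`,
#'   `u`, `p`, `p_adj`, `significant`.  The per-subject asymmetry
#'   values are attached as attribute `"asymmetries"` (see
#'   [tidy.asymmetry_comparison()]).
#' @export
compare_groups <- function(profiles, functions = NULL, alpha = 0.05) {
  need <- c("subject", "group", "hand", "finger", "fn", "value")
  stopifnot(all(need %in% names(profiles)))
  functions <- functions %||% sort(unique(profiles$fn))
  profiles <- dplyr::filter(profiles, .data$fn %in% functions)

  for (g in c("healthy", "md")) {
    if (length(unique(profiles$subject[profiles$group == g])) < 2L) {
      abort_dscreen("need at least 2 subjects per group", "dscreen_empty_group")
    }
  }

  ref <- fit_reference(dplyr::filter(profiles, .data$group == "healthy"))
  z <- zscore_profile(profiles, ref)

  finger_order <- .finger_names
  asym <- z |>
    dplyr::mutate(finger = factor(.data$finger, levels = finger_order)) |>
    dplyr::arrange(.data$fn, .data$subject, .data$finger) |>
    dplyr::group_by(.data$fn, .data$subject, .data$group) |>
    dplyr::summarise(
      assym = asymmetry(.data$z[.data$hand == "left"],
                        .data$z[.data$hand == "right"]),
      .groups = "drop"
    )

  rows <- lapply(split(asym, asym$fn), function(d) {
    hx <- d$assym[d$group == "healthy"]
    mx <- d$assym[d$group == "md"]
    mw <- mann_whitney_u(hx, mx)
    tibble::tibble(fn = d$fn[1], n_healthy = length(hx), n_md = length(mx),
                   median_healthy = stats::median(hx),
                   median_md = stats::median(mx),
                   u = mw$u, p = mw$p, method = mw$method)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  attr(out, "asymmetries") <- asym
  class(out) <- c("asymmetry_comparison", class(out))
  out
}

#' Per-subject asymmetry values behind a group comparison
#'
#' @param x an `asymmetry_comparison`.
#' @param ... unused.
#' @return Tibble with columns `fn`, `subject`, `group`, `assym`.
#' @export
tidy.asymmetry_comparison <- function(x, ...) {
  attr(x, "asymmetries")
}

#' @rdname tidy.asymmetry_comparison
#' @export
glance.asymmetry_comparison <- function(x, ...) {
  tibble::tibble(n_functions = nrow(x),
                 n_significant = sum(x$significant),
                 min_p_adj = min(x$p_adj))
}
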