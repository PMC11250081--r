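# Temporal-order-judgment threshold measurement: Bayesian ZEST staircase
# over a log-spaced SOA grid, with a simulated observer for testing and
# a trial-log replay interface for real sessions.

#' Default log-spaced SOA grid
#'
#' @param n number of grid points (default 61).
#' @param lo,hi grid bounds in ms (default 1 and 500).
#' @return Numeric vector of candidate thresholds, ms.
#' @export
zest_grid <- function(n = 61L, lo = 1, hi = 500) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

# probability of a correct order judgment at a given SOA for a
# threshold candidate theta: guess rate 0.5 (two-alternative task),
# cumulative Gaussian in log10-SOA, lapse rate capping the asymptote
.psychometric <- function(soa_ms, theta_ms, slope, lapse) {
  0.5 + (0.5 - lapse) * stats::pnorm(slope * (log10(soa_ms) - log10(theta_ms)))
}

#' Initialize a ZEST staircase
#'
#' The staircase maintains a discrete posterior over candidate
#' thresholds on a log-spaced SOA grid.  Each trial is placed at the
#' (geometric) posterior mean, and the posterior is multiplied by the
#' likelihood of the observed response under the assumed psychometric
#' function.
#'
#' @param grid candidate thresholds, ms (default [zest_grid()]).
#' @param prior prior mass over `grid` (default uniform); must be
#'   non-negative with positive sum.
#' @param slope psychometric slope per log10-ms (default 3).
#' @param lapse lapse rate (default 0.02).
#' @return A list of class `zest_state` with `grid`, `posterior`,
#'   `slope`, `lapse` and an empty `trials` log.
#' @export
zest_init <- function(grid = zest_grid(), prior = NULL, slope = 3,
                      lapse = 0.02) {
  prior <- prior %||% rep(1, length(grid))
  stopifnot(length(prior) == length(grid), all(diff(grid) > 0))
  if (any(prior < 0) || sum(prior) <= 0) {
    abort_dscreen("prior must be non-negative with positive mass",
                  "dscreen_degenerate_prior")
  }
  structure(list(
    grid = grid,
    posterior = prior / sum(prior),
    slope = slope,
    lapse = lapse,
    trials = tibble::tibble(trial = integer(), soa_ms = numeric(),
                            first_stimulus = character(),
                            response = character(), correct = logical())
  ), class = "zest_state")
}

#' @export
print.zest_state <- function(x, ...) {
  cat(sprintf("<zest_state> %d trials, next SOA %.1f ms\n",
              nrow(x$trials), zest_next_soa(x)))
  invisible(x)
}

#' Next stimulus placement of a ZEST staircase
#'
#' The geometric posterior mean of the threshold distribution, snapped
#' to the nearest grid point (in log distance).
#'
#' @param state a [zest_init()] state.
#' @return SOA in ms (a grid point).
#' @export
zest_next_soa <- function(state) {
  stopifnot(inherits(state, "zest_state"))
  lg <- log10(state$grid)
  m <- sum(state$posterior * lg)
  state$grid[which.min(abs(lg - m))]
}

#' Update a ZEST staircase with one response
#'
#' Multiplies the posterior by the likelihood of the response under the
#' assumed psychometric function and renormalizes; the trial is
#' appended to the log.
#'
#' @param state a `zest_state`.
#' @param soa_ms stimulus-onset asynchrony presented, ms; must lie
#'   within the grid bounds.
#' @param correct logical: was the order judged correctly?
#' @param first_stimulus,response optional labels logged verbatim.
#' @return The updated `zest_state`.
#' @export
zest_update <- function(state, soa_ms, correct, first_stimulus = NA_character_,
                        response = NA_character_) {
  stopifnot(inherits(state, "zest_state"), is.logical(correct))
  if (soa_ms < min(state$grid) - 1e-9 || soa_ms > max(state$grid) + 1e-9) {
    abort_dscreen(sprintf("SOA %.1f ms lies outside the grid", soa_ms),
                  "dscreen_out_of_grid_soa")
  }
  lik <- .psychometric(soa_ms, state$grid, state$slope, state$lapse)
  if (!correct) lik <- 1 - lik
  post <- state$posterior * lik
  state$posterior <- post / sum(post)
  state$trials <- dplyr::bind_rows(state$trials, tibble::tibble(
    trial = nrow(state$trials) + 1L, soa_ms = soa_ms,
    first_stimulus = first_stimulus, response = response, correct = correct
  ))
  state
}

#' Threshold estimate from a ZEST state
#'
#' The SOA at which the posterior-mean psychometric curve crosses the
#' 75% correct criterion: with guess rate 0.5 and lapse `lambda`, that
#' is `10^(mu + qnorm(0.25 / (0.5 - lambda)) / slope)` where `mu` is
#' the posterior mean of log10-threshold.  Clamped to the grid bounds.
#'
#' @param state a `zest_state`.
#' @return Threshold in ms.
#' @export
zest_threshold <- function(state) {
  stopifnot(inherits(state, "zest_state"))
  mu <- sum(state$posterior * log10(state$grid))
  shift <- stats::qnorm(0.25 / (0.5 - state$lapse)) / state$slope
  th <- 10^(mu + shift)
  min(max(th, min(state$grid)), max(state$grid))
}

#' Run a simulated (or replayed) TOJ session
#'
#' Runs the init -> place -> respond -> update loop for `n_trials`
#' trials against a [gen_observer()] and returns the threshold at which
#' the fitted psychometric curve crosses 75% correct.  The finger
#' receiving the first stimulus alternates randomly per trial.
#' Deterministic given `seed`.
#'
#' @param observer a [gen_observer()].
#' @param n_trials number of trials (default 40).
#' @param seed integer seed.
#' @param state optional pre-configured [zest_init()] state.
#' @return A list of class `toj_result` with `threshold_ms` and the
#'   final `state` (including the full trial log).
#' @export
run_session <- function(observer, n_trials = 40L, seed = 1L, state = NULL) {
  stopifnot(inherits(observer, "sim_observer"), n_trials >= 1L)
  state <- state %||% zest_init()
  with_seed(seed, {
    for (i in seq_len(n_trials)) {
      soa <- zest_next_soa(state)
      first <- sample(c("index", "middle"), 1L)
      correct <- stats::runif(1) < .psychometric(soa, observer$threshold_ms,
                                                 observer$slope, observer$lapse)
      resp <- if (correct) first else setdiff(c("index", "middle"), first)
      state <- zest_update(state, soa, correct, first_stimulus = first,
                           response = resp)
    }
    structure(list(threshold_ms = zest_threshold(state), state = state),
              class = "toj_result")
  })
}

#' @export
print.toj_result <- function(x, ...) {
  cat(sprintf("<toj_result> TOJ threshold %.1f ms after %d trials\n",
              x$threshold_ms, nrow(x$state$trials)))
  invisible(x)
}

#' Trial log / summary of a TOJ session
#'
#' @param x a `toj_result`.
#' @param ... unused.
#' @return `tidy()`: the trial log tibble; `glance()`: a one-row
#'   summary.
#' @export
tidy.toj_result <- function(x, ...) {
  x$state$trials
}

#' @rdname tidy.toj_result
#' @export
glance.toj_result <- function(x, ...) {
  tibble::tibble(threshold_ms = x$threshold_ms,
                 n_trials = nrow(x$state$trials),
                 prop_correct = mean(x$state$trials$correct))
}

#' Re-estimate a TOJ threshold from a session log
#'
#' Replays a logged session (columns `soa_ms`, `correct`) through the
#' ZEST posterior and returns the 75%-criterion threshold.
#'
#' @param log data frame with columns `soa_ms` and `correct`.
#' @param state optional [zest_init()] state.
#' @return A `toj_result`.
#' @export
replay_session <- function(log, state = NULL) {
  stopifnot(all(c("soa_ms", "correct") %in% names(log)))
  state <- state %||% zest_init()
  for (i in seq_len(nrow(log))) {
    state <- zest_update(state, log$soa_ms[i], as.logical(log$correct[i]))
  }
  structure(list(threshold_ms = zest_threshold(state), state = state),
            class = "toj_result")
}
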