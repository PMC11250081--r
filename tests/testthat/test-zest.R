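# ZEST staircase: posterior bookkeeping, placement rule, threshold
# readout, and simulated sessions.

test_that("initialization normalizes the prior and rejects degenerate ones", {
  st <- zest_init()
  expect_length(st$posterior, 61L)
  expect_equal(st$posterior, rep(1 / 61, 61))
  expect_equal(sum(st$posterior), 1)
  expect_error(zest_init(prior = rep(0, 61)), class = "dscreen_degenerate_prior")
})

test_that("placement is the geometric posterior mean snapped to the grid", {
  st <- zest_init()
  g <- st$grid
  # uniform prior on a symmetric log grid: the central grid point
  expect_equal(zest_next_soa(st), g[31])
  # point mass: that grid point itself
  pm <- rep(0, 61); pm[40] <- 1
  st2 <- zest_init(prior = pm)
  expect_equal(zest_next_soa(st2), g[40])
})

test_that("updates keep the posterior normalized and respond monotonically", {
  st <- zest_init()
  s0 <- zest_next_soa(st)
  up_c <- zest_update(st, s0, TRUE)
  expect_equal(sum(up_c$posterior), 1, tolerance = 1e-12)
  expect_lte(zest_next_soa(up_c), s0)       # correct: next SOA shrinks
  up_i <- zest_update(st, s0, FALSE)
  expect_gte(zest_next_soa(up_i), s0)       # incorrect: next SOA grows

  # normalization holds along a random response sequence
  set.seed(3)
  for (i in 1:30) {
    st <- zest_update(st, zest_next_soa(st), runif(1) < 0.7)
    expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
  }
  expect_identical(nrow(st$trials), 30L)

  expect_error(zest_update(zest_init(), 1000, TRUE),
               class = "dscreen_out_of_grid_soa")
})

test_that("opposite responses at one SOA flatten back toward the prior", {
  st <- zest_init()
  soa <- 60
  st2 <- zest_update(zest_update(st, soa, TRUE), soa, FALSE)
  # direct product-of-likelihoods oracle
  p <- 0.5 + (0.5 - st$lapse) *
    pnorm(st$slope * (log10(soa) - log10(st$grid)))
  oracle <- (p * (1 - p)) / sum(p * (1 - p)) * 61 / 61
  oracle <- (st$posterior * p * (1 - p))
  oracle <- oracle / sum(oracle)
  expect_equal(st2$posterior, oracle, tolerance = 1e-12)
  # note: with a 0.5 guess floor an incorrect response is far more
  # informative than a correct one, so the pair does not cancel; the
  # exact product-of-likelihoods identity above is the invariant
})

test_that("sessions are reproducible and follow the staircase rule", {
  obs <- gen_observer(60, slope = 3)
  r1 <- run_session(obs, n_trials = 40, seed = 12)
  r2 <- run_session(obs, n_trials = 40, seed = 12)
  expect_identical(tidy(r1), tidy(r2))
  log <- tidy(r1)
  # correct response => next placement not larger; incorrect => not smaller
  for (i in seq_len(nrow(log) - 1)) {
    if (log$correct[i]) {
      expect_lte(log$soa_ms[i + 1], log$soa_ms[i])
    } else {
      expect_gte(log$soa_ms[i + 1], log$soa_ms[i])
    }
  }
  expect_true(r1$threshold_ms >= 1 && r1$threshold_ms <= 500)
})

test_that("replaying a logged session reproduces the estimate", {
  obs <- gen_observer(80, slope = 3)
  r <- run_session(obs, n_trials = 30, seed = 5)
  re <- replay_session(tidy(r))
  expect_equal(re$threshold_ms, r$threshold_ms, tolerance = 1e-12)
})

test_that("a sharp observer pins the threshold to within one grid step", {
  obs <- gen_observer(60, slope = 1e6, lapse = 0)
  r <- run_session(obs, n_trials = 40, seed = 2, state = zest_init(lapse = 0))
  step <- log10(500) / 60                     # log10 spacing of the grid
  expect_lt(abs(log10(r$threshold_ms) - log10(60)), step + 1e-9)
})
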