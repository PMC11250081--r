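# Biomechanical function scores, asymmetry, and the group statistics.

test_that("per-finger function scores follow their defining formulas", {
  expect_equal(force_reduction_ratio(6, 10), 0.6)
  expect_equal(force_reduction_ratio(10, 10), 1.0)
  expect_error(force_reduction_ratio(5, 0), class = "dscreen_zero_max_force")

  expect_equal(independence_index(10, 0), 1.0)
  expect_equal(independence_index(10, 2), 0.8)
  expect_equal(independence_index(10, 15), 0.0)      # floored at zero
  expect_error(independence_index(0, 1),
               class = "dscreen_zero_designated_force")

  expect_equal(agility_rate(runif(30, 0, 5)), 6.0)
  expect_equal(agility_rate(numeric(0)), 0.0)
  expect_equal(agility_rate(seq(0.1, 5.0, by = 0.1)), 10.0)
  expect_error(agility_rate(c(1, 7)), "within the trial")

  # central-window mean discards the 1 s transients
  t <- seq(0, 5, by = 0.01)
  f <- ifelse(t < 1 | t > 4, 100, 2)                 # wild transients
  expect_equal(sustained_hold_mean(t, f), 2)
})

test_that("z-scoring against the reference cohort self-standardizes", {
  coh <- gen_biomech_cohort(n_healthy = 40, n_md = 2, seed = 6)
  healthy <- dplyr::filter(coh, group == "healthy")
  ref <- fit_reference(healthy)
  z <- zscore_profile(healthy, ref)
  stats <- dplyr::summarise(dplyr::group_by(z, fn, finger),
                            m = mean(z), s = sd(z), .groups = "drop")
  expect_lt(max(abs(stats$m)), 1e-10)                # exact by construction
  expect_equal(stats$s, rep(1, nrow(stats)), tolerance = 1e-10)

  bad_ref <- ref
  bad_ref$ref_sd[1] <- 0
  expect_error(zscore_profile(healthy, bad_ref),
               class = "dscreen_zero_reference_sd")
})

test_that("asymmetry is a norm with the expected symmetries", {
  expect_identical(asymmetry(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 0)
  expect_equal(asymmetry(c(1, 0, 0, 0, 0), rep(0, 5)), 1.0)
  expect_equal(asymmetry(rep(1, 5), rep(0, 5)), sqrt(5))
  set.seed(2)
  zl <- rnorm(5); zr <- rnorm(5)
  expect_equal(asymmetry(zl, zr), asymmetry(zr, zl))
  p <- sample(5)
  expect_equal(asymmetry(zl[p], zr[p]), asymmetry(zl, zr))
  expect_error(asymmetry(zl, zr[1:4]), class = "dscreen_length_mismatch")
})

test_that("Mann-Whitney U reproduces hand-worked exact cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$u, 0)
  expect_equal(r$p, 0.1)                             # 2 of 20 rank splits
  expect_identical(r$method, "exact")

  tied <- mann_whitney_u(c(1, 1, 1), c(1, 1, 1))
  expect_equal(tied$u, 4.5)                          # n1 n2 / 2 with midranks
  expect_equal(tied$p, 1)

  single <- mann_whitney_u(1, 2)
  expect_identical(single$u, 0)
  expect_equal(single$p, 1.0)

  expect_error(mann_whitney_u(numeric(0), 1), class = "dscreen_empty_group")
})

test_that("exact Mann-Whitney matches brute-force enumeration with ties", {
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(1:4, 1)
    n2 <- sample(1:(8 - n1), 1)
    x <- sample(1:4, n1, replace = TRUE)             # heavy ties
    y <- sample(1:4, n2, replace = TRUE)
    got <- mann_whitney_u(x, y)
    ora <- mwu_oracle(x, y)
    expect_equal(got$u, ora$u, info = sprintf("rep %d", rep))
    expect_equal(got$p, ora$p, info = sprintf("rep %d", rep))
  }
})

test_that("large-sample mode agrees with the normal approximation in stats", {
  set.seed(4)
  x <- rnorm(20); y <- rnorm(16, 0.5)                # untied continuous data
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_identical(got$method, "normal")
  expect_equal(got$u, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment matches the hand-worked step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  set.seed(1)
  p <- runif(10)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "dscreen_out_of_range_p")
})

test_that("group comparison flags a strong engineered independence deficit", {
  coh <- gen_biomech_cohort(n_healthy = 20, n_md = 16,
                            effect = c(independence = -3), seed = 9)
  res <- compare_groups(coh)
  expect_s3_class(res, "asymmetry_comparison")
  expect_identical(nrow(res), 6L)
  ind <- res[res$fn == "independence", ]
  expect_lt(ind$p_adj, 0.05)
  expect_gt(ind$median_md, ind$median_healthy)
  # per-subject asymmetries are exposed via tidy()
  asym <- tidy(res)
  expect_identical(nrow(asym), 6L * 36L)
  expect_true(all(asym$assym >= 0))

  one <- dplyr::filter(coh, group == "healthy" | subject == "P01")
  expect_error(compare_groups(one), class = "dscreen_empty_group")
})
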