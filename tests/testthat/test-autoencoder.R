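# Training mechanics of the convolutional autoencoder.  Unit tests run
# on short (21 x 3 x 32) tensors and a narrow channel schedule; the
# full-size model is exercised by the acceptance suite.

small_cfg <- function(...) {
  conv_ae_config(channels = c(4L, 6L, 8L), latent_channels = 8L, ...)
}

test_that("training memorizes a degenerate single-tensor set", {
  tn <- make_random_tensor(n = 32, seed = 5)
  train <- rep(list(tn), 50)
  m <- train_autoencoder(train, small_cfg(max_epochs = 30L, patience = 30L),
                         seed = 1)
  expect_lt(reconstruction_error(m, tn), 1e-3)
})

test_that("training reduces the loss on a heterogeneous set", {
  train <- lapply(1:20, function(i) make_smooth_tensor(n = 32, seed = i))
  m <- train_autoencoder(train,
                         small_cfg(batch_size = 4L, max_epochs = 100L,
                                   patience = 100L),
                         seed = 3)
  lh <- m$loss_history
  expect_lt(lh[length(lh)], 0.5 * lh[1])
  # smoothed training loss is non-increasing over the run
  ma <- stats::filter(lh, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-6))
})

test_that("training is deterministic given data and seed", {
  train <- lapply(1:6, function(i) make_random_tensor(n = 32, seed = i))
  m1 <- train_autoencoder(train, small_cfg(max_epochs = 3L), seed = 11)
  m2 <- train_autoencoder(train, small_cfg(max_epochs = 3L), seed = 11)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("the error metric equals the mean squared residual of reconstruct()", {
  train <- lapply(1:6, function(i) make_random_tensor(n = 32, seed = i))
  m <- train_autoencoder(train, small_cfg(max_epochs = 2L), seed = 2)
  tn <- make_random_tensor(n = 32, seed = 99)
  rec <- reconstruct(m, tn)
  expect_equal(reconstruction_error(m, tn),
               mean((unclass(rec) - unclass(tn))^2), tolerance = 1e-12)
  expect_gte(reconstruction_error(m, tn), 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(train_autoencoder(list(), small_cfg()),
               class = "dscreen_empty_group")
  train <- lapply(1:4, function(i) make_random_tensor(n = 32, seed = i))
  m <- train_autoencoder(train, small_cfg(max_epochs = 1L), seed = 1)
  expect_error(reconstruction_errors(m, list(make_random_tensor(n = 64))),
               class = "dscreen_shape_mismatch")
  expect_error(conv_ae_config(latent_channels = 200L),
               class = "dscreen_bad_config")
})
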