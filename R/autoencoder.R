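# The convolutional autoencoder: configuration, training on healthy
# trial tensors, and reconstruction error.

#' Autoencoder configuration
#'
#' Hyperparameters of the 7-layer convolutional encoder + 7-layer
#' convolutional decoder.  The encoder applies 3x3 convolutions over the
#' landmark x time grid with the three coordinates as input channels,
#' halving the time axis at layers 2, 4 and 6 and contracting the
#' landmark axis at layer 7, so the bottleneck is a 7 x 8 feature map
#' with `latent_channels` channels; the decoder mirrors it with
#' nearest-neighbour resize + convolution and a linear output layer.
#'
#' @param channels channel schedule of the three encoder stages
#'   (default `c(8, 16, 32)`, sized to train comfortably on one CPU).
#' @param latent_channels bottleneck channels (default 32; total latent
#'   size 7 * 8 * 32 = 1792, well under the 21 * 3 * 128 = 8064 input).
#' @param kernel convolution kernel size (default 3).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs training-epoch cap (default 40).
#' @param patience epochs without improvement beyond `tol` before
#'   training stops (default 6).
#' @param tol minimum decrease of the epoch-mean reconstruction error
#'   that counts as improvement (default 1e-6).
#' @return A list of class `conv_ae_config`.
#' @export
conv_ae_config <- function(channels = c(8L, 16L, 32L), latent_channels = 32L,
                           kernel = 3L, learning_rate = 1e-3,
                           batch_size = 32L, max_epochs = 40L,
                           patience = 6L, tol = 1e-6) {
  stopifnot(length(channels) == 3L, all(channels >= 1),
            latent_channels >= 1, kernel %% 2 == 1)
  latent_dim <- 7L * 8L * as.integer(latent_channels)
  if (latent_dim >= 21L * 3L * 128L) {
    abort_dscreen("latent dimension must be smaller than the input",
                  "dscreen_bad_config")
  }
  structure(list(
    n_encoder_layers = 7L, n_decoder_layers = 7L,
    channels = as.integer(channels),
    latent_channels = as.integer(latent_channels),
    latent_dim = latent_dim,
    kernel = as.integer(kernel), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), tol = tol
  ), class = "conv_ae_config")
}

#' Train the convolutional autoencoder on healthy trial tensors
#'
#' Minimizes the mean-squared reconstruction error with Adam.  Training
#' stops when the epoch-mean reconstruction error has not improved by
#' more than `config$tol` for `config$patience` consecutive epochs, or
#' at `config$max_epochs`.  Deterministic given `seed` (weight
#' initialization and minibatch shuffling both derive from it).
#'
#' @param train list of `trial_tensor`s (healthy performances only).
#' @param config a [conv_ae_config()].
#' @param seed integer seed.
#' @param verbose print the loss every 10 epochs.
#' Inputs are standardized against the training set (centred on the
#' mean tensor, scaled to unit variance; both stored with the model) so
#' the network spends its capacity on deviations from the average
#' performance and the optimizer sees well-scaled gradients; reported
#' reconstruction errors are always in the original coordinate units.
#'
#' @return A `conv_autoencoder`: list with `params`, `arch`, `config`,
#'   `center`, `scale`, `loss_history`, `n_train`, `seed`.
#' @export
train_autoencoder <- function(train, config = conv_ae_config(), seed = 1L,
                              verbose = FALSE) {
  if (length(train) == 0) {
    abort_dscreen("training set is empty", "dscreen_empty_group")
  }
  stopifnot(inherits(config, "conv_ae_config"))
  arch <- .conv_ae_arch(config)
  X_all <- .stack_tensors(train)
  n <- dim(X_all)[4]
  numel <- prod(dim(X_all)[1:3])
  # standardize on the training set: centre on the mean tensor so the
  # network models deviations from the average performance rather than
  # the static hand pose, and scale to unit variance so gradient
  # magnitudes are well inside Adam's working range.  Reconstruction
  # errors are reported in the original coordinate units.
  center <- array(rowMeans(matrix(X_all, numel, n)), dim(X_all)[1:3])
  X_all <- X_all - as.vector(center)
  scale <- stats::sd(X_all)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  X_all <- X_all / scale

  with_seed(seed, {
    params <- .init_params(arch)
    state <- .adam_init(params)
    best <- Inf
    stall <- 0L
    t_step <- 0L
    loss_hist <- numeric(0)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        ids <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        X <- X_all[, , , ids, drop = FALSE]
        fw <- .net_forward(X, arch, params, keep_cache = TRUE)
        resid <- fw$out - X
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          abort_dscreen("training loss became non-finite",
                        "dscreen_non_finite_loss")
        }
        ep_loss <- ep_loss + loss * length(ids)
        dY <- resid * (2 / (numel * length(ids)))
        grads <- .net_backward(dY, arch, params, fw$caches)
        t_step <- t_step + 1L
        upd <- .adam_step(params, grads, state, config$learning_rate, t_step)
        params <- upd$params
        state <- upd$state
      }
      ep_loss <- ep_loss / n
      loss_hist <- c(loss_hist, ep_loss)
      if (verbose && epoch %% 10 == 0) {
        message(sprintf("epoch %3d  mse %.3e", epoch, ep_loss))
      }
      if (best - ep_loss > config$tol) {
        best <- ep_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    structure(list(params = params, arch = arch, config = config,
                   center = center, scale = scale,
                   loss_history = loss_hist, n_train = n, seed = seed),
              class = "conv_autoencoder")
  })
}

#' @export
print.conv_autoencoder <- function(x, ...) {
  cat(sprintf(
    "<conv_autoencoder> 7+7 conv layers, channels %s, latent %d; %d epochs, final mse %.3e\n",
    paste(x$config$channels, collapse = "-"), x$config$latent_dim,
    length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Reconstruct trial tensors with a trained autoencoder
#'
#' @param model a `conv_autoencoder`.
#' @param tensor a `trial_tensor` of the shape the model was trained on.
#' @return A `trial_tensor` of the same shape.
#' @export
reconstruct <- function(model, tensor) {
  stopifnot(inherits(model, "conv_autoencoder"),
            inherits(tensor, "trial_tensor"))
  X <- (.stack_tensors(list(tensor)) - as.vector(model$center)) / model$scale
  Y <- .net_forward(X, model$arch, model$params)$out * model$scale +
    as.vector(model$center)
  trial_tensor(aperm(Y[, , , 1], c(2, 1, 3)), meta = attr(tensor, "meta"),
               time_range = attr(tensor, "time_range"))
}

#' Mean-squared reconstruction error
#'
#' The anomaly score: the mean over all 21 x 3 x 128 tensor elements of
#' the squared difference between the input and its reconstruction.
#'
#' @param model a `conv_autoencoder`.
#' @param tensor a `trial_tensor`.
#' @return Non-negative numeric scalar.
#' @export
reconstruction_error <- function(model, tensor) {
  reconstruction_errors(model, list(tensor))
}

#' @rdname reconstruction_error
#' @param tensors list of `trial_tensor`s.
#' @return `reconstruction_errors()`: numeric vector of per-tensor MSEs.
#' @export
reconstruction_errors <- function(model, tensors) {
  stopifnot(inherits(model, "conv_autoencoder"))
  d1 <- dim(tensors[[1]])
  ok <- vapply(tensors, function(tn) identical(dim(tn), d1), logical(1))
  if (!all(ok) || d1[1] != 21L || d1[2] != 3L ||
      d1[3] != dim(model$center)[3]) {
    abort_dscreen("tensor shape does not match the model input",
                  "dscreen_shape_mismatch")
  }
  out <- numeric(length(tensors))
  bs <- model$config$batch_size
  for (b0 in seq(1L, length(tensors), by = bs)) {
    ids <- b0:min(b0 + bs - 1L, length(tensors))
    X <- (.stack_tensors(tensors[ids]) - as.vector(model$center)) / model$scale
    Y <- .net_forward(X, model$arch, model$params)$out
    se <- (Y - X)^2 * model$scale^2
    out[ids] <- apply(se, 4, mean)
  }
  out
}
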