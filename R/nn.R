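# Minimal convolutional-network engine used by the autoencoder.
# Convolutions are computed as a sum over the k x k kernel offsets of
# strided array slices times weight blocks (BLAS matrix products), which
# keeps all heavy work in C; batches are channels-first arrays
# (C, H, W, N).  Only what the autoencoder needs is implemented.

.same_pad <- function(n, k, s) {
  out <- ceiling(n / s)
  pt <- max(0L, (out - 1L) * s + k - n)
  c(beg = pt %/% 2L, end = pt - pt %/% 2L, out = out)
}

.pad_input <- function(X, ph, pw) {
  d <- dim(X)
  if (ph[["beg"]] + ph[["end"]] == 0L && pw[["beg"]] + pw[["end"]] == 0L) {
    return(X)
  }
  Xp <- array(0, c(d[1], d[2] + ph[["beg"]] + ph[["end"]],
                   d[3] + pw[["beg"]] + pw[["end"]], d[4]))
  Xp[, ph[["beg"]] + seq_len(d[2]), pw[["beg"]] + seq_len(d[3]), ] <- X
  Xp
}

# weight layout: W is (Cout, C*k*k) with column blocks ordered channel-
# fastest, then kernel row offset dr, then kernel column offset dc, so
# block (dr, dc) spans columns (dc*k + dr)*C + 1:C.  The strided
# gather / GEMM / scatter kernels live in src/conv.cpp.
.conv_forward <- function(X, W, b, k, sh, sw, relu, keep_cache = FALSE) {
  d <- dim(X); C <- d[1]
  ph <- .same_pad(d[2], k, sh); pw <- .same_pad(d[3], k, sw)
  Xp <- .pad_input(X, ph, pw)
  Hout <- ph[["out"]]; Wout <- pw[["out"]]
  Y <- .conv_fwd_cpp(as.vector(Xp), dim(Xp), W, b,
                     as.integer(k), as.integer(sh), as.integer(sw),
                     Hout, Wout)
  mask <- NULL
  if (relu) {
    mask <- Y > 0
    Y <- Y * mask
  }
  out <- array(Y, c(nrow(W), Hout, Wout, d[4]))
  cache <- NULL
  if (keep_cache) {
    cache <- list(Xp = Xp, mask = mask, in_dim = d,
                  Hout = Hout, Wout = Wout, ph = ph, pw = pw)
  }
  list(out = out, cache = cache)
}

.conv_backward <- function(dY, W, cache, k, sh, sw) {
  Cout <- nrow(W)
  dYm <- matrix(dY, nrow = Cout)
  if (!is.null(cache$mask)) dYm <- dYm * cache$mask
  db <- rowSums(dYm)
  Xp <- cache$Xp
  dp <- dim(Xp)
  g <- .conv_bwd_cpp(as.vector(Xp), dp, W, dYm,
                     as.integer(k), as.integer(sh), as.integer(sw),
                     cache$Hout, cache$Wout)
  dXp <- array(g$dXp, dp)
  d <- cache$in_dim
  dX <- dXp[, cache$ph[["beg"]] + seq_len(d[2]),
            cache$pw[["beg"]] + seq_len(d[3]), , drop = FALSE]
  list(dX = dX, dW = g$dW, db = db)
}

.upsample_forward <- function(X, fh, fw) {
  d <- dim(X)
  X[, rep(seq_len(d[2]), each = fh), rep(seq_len(d[3]), each = fw), ,
    drop = FALSE]
}

.upsample_backward <- function(dY, fh, fw) {
  d <- dim(dY)
  H <- d[2] %/% fh; W <- d[3] %/% fw
  dX <- array(0, c(d[1], H, W, d[4]))
  for (a in seq_len(fh)) {
    for (b in seq_len(fw)) {
      dX <- dX + dY[, seq(a, d[2], by = fh), seq(b, d[3], by = fw), ,
                    drop = FALSE]
    }
  }
  dX
}

# ---- architecture ----------------------------------------------------------

# Layer descriptors for the 7-layer encoder + 7-layer decoder.  Strides
# halve the time axis at encoder layers 2, 4 and 6; layer 7 contracts
# the landmark axis (21 -> 7) and time once more, giving a 7 x 8
# bottleneck map with `latent_channels` channels.  The decoder mirrors
# the encoder with nearest-neighbour resize + convolution.
.conv_ae_arch <- function(config) {
  ch <- config$channels          # length 3, e.g. c(8, 16, 32)
  lc <- config$latent_channels
  k <- config$kernel
  enc <- list(
    list(type = "conv", cin = 3L,    cout = ch[1], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "conv", cin = ch[1], cout = ch[1], k = k, sh = 1L, sw = 2L, relu = TRUE),
    list(type = "conv", cin = ch[1], cout = ch[2], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "conv", cin = ch[2], cout = ch[2], k = k, sh = 1L, sw = 2L, relu = TRUE),
    list(type = "conv", cin = ch[2], cout = ch[3], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "conv", cin = ch[3], cout = ch[3], k = k, sh = 1L, sw = 2L, relu = TRUE),
    list(type = "conv", cin = ch[3], cout = lc,    k = k, sh = 3L, sw = 2L, relu = TRUE)
  )
  dec <- list(
    list(type = "upsample", fh = 3L, fw = 2L),
    list(type = "conv", cin = lc,    cout = ch[3], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "conv", cin = ch[3], cout = ch[2], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "upsample", fh = 1L, fw = 2L),
    list(type = "conv", cin = ch[2], cout = ch[2], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "conv", cin = ch[2], cout = ch[1], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "upsample", fh = 1L, fw = 2L),
    list(type = "conv", cin = ch[1], cout = ch[1], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "upsample", fh = 1L, fw = 2L),
    list(type = "conv", cin = ch[1], cout = ch[1], k = k, sh = 1L, sw = 1L, relu = TRUE),
    list(type = "conv", cin = ch[1], cout = 3L,   k = k, sh = 1L, sw = 1L, relu = FALSE)
  )
  c(enc, dec)
}

.init_params <- function(arch) {
  lapply(arch, function(ly) {
    if (ly$type != "conv") return(NULL)
    fan_in <- ly$cin * ly$k * ly$k
    list(W = matrix(stats::rnorm(ly$cout * fan_in, sd = sqrt(2 / fan_in)),
                    nrow = ly$cout),
         b = rep(0, ly$cout))
  })
}

.net_forward <- function(X, arch, params, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(arch)) else NULL
  for (i in seq_along(arch)) {
    ly <- arch[[i]]
    if (ly$type == "conv") {
      p <- params[[i]]
      r <- .conv_forward(X, p$W, p$b, ly$k, ly$sh, ly$sw, ly$relu, keep_cache)
      X <- r$out
      if (keep_cache) caches[[i]] <- r$cache
    } else {
      X <- .upsample_forward(X, ly$fh, ly$fw)
    }
  }
  list(out = X, caches = caches)
}

.net_backward <- function(dY, arch, params, caches) {
  grads <- vector("list", length(arch))
  for (i in rev(seq_along(arch))) {
    ly <- arch[[i]]
    if (ly$type == "conv") {
      g <- .conv_backward(dY, params[[i]]$W, caches[[i]], ly$k, ly$sh, ly$sw)
      grads[[i]] <- list(W = g$dW, b = g$db)
      dY <- g$dX
    } else {
      dY <- .upsample_backward(dY, ly$fh, ly$fw)
    }
  }
  grads
}

.adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    s <- state[[i]]; g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

# stack a list of trial tensors (21 x 3 x T) into the network layout
# (C = 3 coords, H = 21 landmarks, W = T, N)
.stack_tensors <- function(tensors) {
  n <- length(tensors)
  d <- dim(tensors[[1]])
  X <- array(0, c(3L, 21L, d[3], n))
  for (i in seq_len(n)) X[, , , i] <- aperm(unclass(tensors[[i]]), c(2, 1, 3))
  X
}
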