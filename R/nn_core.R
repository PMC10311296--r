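# Minimal 3D convolutional network engine.
#
# Activations between convolutional layers are stored as a C x (S*N)
# matrix: C channels, S = d^3 voxels, N samples; column (n-1)*S + v holds
# the channel vector of voxel v in sample n. Convolutions are evaluated as
# im2col gathers followed by one BLAS matrix product, which is what makes
# training tractable on a single CPU. Backward passes are exact gradients
# (checked against numerical differentiation in the test suite).

# ---- geometry -------------------------------------------------------------

conv_out_dim <- function(d_in, k, stride, pad) {
  (d_in + 2L * pad - k) %/% stride + 1L
}

# Spatial gather map: K x S_out matrix of input voxel linear indices
# (0 = zero padding) for a cubic conv/pool window.
conv_index_map <- function(d_in, k, stride, pad) {
  d_out <- conv_out_dim(d_in, k, stride, pad)
  o <- seq_len(d_out)
  base <- (o - 1L) * stride - pad  # 0-indexed start per axis
  off <- seq_len(k) - 1L
  ax <- outer(off, base, "+")  # k x d_out, 0-indexed input coords
  valid <- ax >= 0L & ax < d_in
  K <- k^3L
  S_out <- d_out^3L
  M <- matrix(0L, K, S_out)
  # kernel offset order: kx fastest, then ky, kz; output voxel order:
  # ox fastest, oy, oz (matches the column-major flattening of the grid)
  for (kz in seq_len(k)) for (ky in seq_len(k)) for (kx in seq_len(k)) {
    j <- kx + (ky - 1L) * k + (kz - 1L) * k^2L
    ix <- ax[kx, ]; iy <- ax[ky, ]; iz <- ax[kz, ]
    vx <- valid[kx, ]; vy <- valid[ky, ]; vz <- valid[kz, ]
    lin <- outer(outer(ix + 1L, iy * d_in, "+"), iz * d_in^2L, "+")
    ok <- outer(outer(vx, vy, "&"), vz, "&")
    lin[!ok] <- 0L
    M[j, ] <- as.integer(lin)
  }
  list(map = M, d_out = d_out, S_out = S_out, K = K)
}

# Global column indices for a batch of N samples: for gather j, the column
# in the (zero-padded) activation matrix feeding each output column.
.batch_cols <- function(map_row, S_in, N, zero_col) {
  idx <- rep(map_row, N) + rep((seq_len(N) - 1L) * S_in, each = length(map_row))
  idx[rep(map_row, N) == 0L] <- zero_col
  idx
}

# ---- layers ---------------------------------------------------------------

nn_conv3d <- function(c_in, c_out, k, stride, pad, d_in) {
  geom <- conv_index_map(d_in, k, stride, pad)
  fan_in <- c_in * geom$K
  W <- matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
              c_out, fan_in)
  list(type = "conv3d", W = W, b = numeric(c_out),
       c_in = c_in, c_out = c_out, k = k, stride = stride, pad = pad,
       d_in = d_in, d_out = geom$d_out, S_in = d_in^3L,
       S_out = geom$S_out, K = geom$K, map = geom$map)
}

nn_batchnorm <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

nn_relu <- function() list(type = "relu")

nn_avgpool <- function(d_in, p) {
  stopifnot(d_in %% p == 0L)
  geom <- conv_index_map(d_in, p, p, 0L)
  list(type = "avgpool", p = p, d_in = d_in, d_out = geom$d_out,
       S_in = d_in^3L, S_out = geom$S_out, K = geom$K, map = geom$map)
}

nn_flatten <- function(c, s) list(type = "flatten", c = c, s = s)

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

nn_dense <- function(n_in, n_out, zero_init = FALSE) {
  W <- if (zero_init) matrix(0, n_out, n_in)
  else matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
  list(type = "dense", W = W, b = numeric(n_out))
}

# ---- forward / backward ---------------------------------------------------

.gather_cols <- function(layer, A, N) {
  # (C*K) x (S_out*N) im2col matrix; row block j holds kernel offset j
  cpp_im2col(A, layer$map, N, layer$S_in)
}

layer_forward <- function(layer, A, N, train) {
  switch(
    layer$type,
    conv3d = {
      X <- if (layer$K == 1L && layer$stride == 1L && layer$pad == 0L) A
      else .gather_cols(layer, A, N)
      out <- layer$W %*% X + layer$b
      list(out = out, cache = list(X = X))
    },
    batchnorm = {
      if (train) {
        mu <- rowMeans(A)
        xc <- A - mu
        va <- rowMeans(xc * xc)
        isd <- 1 / sqrt(va + layer$eps)
        xhat <- xc * isd
        out <- xhat * layer$gamma + layer$beta
        list(out = out,
             cache = list(xhat = xhat, isd = isd, mu = mu, va = va),
             state = list(
               run_mean = (1 - layer$momentum) * layer$run_mean +
                 layer$momentum * mu,
               run_var = (1 - layer$momentum) * layer$run_var +
                 layer$momentum * va))
      } else {
        isd <- 1 / sqrt(layer$run_var + layer$eps)
        out <- (A - layer$run_mean) * isd * layer$gamma + layer$beta
        list(out = out, cache = NULL)
      }
    },
    relu = {
      out <- pmax(A, 0)
      list(out = out, cache = list(mask = A > 0))
    },
    avgpool = {
      X <- .gather_cols(layer, A, N)
      C <- nrow(A)
      M <- layer$S_out * N
      out <- matrix(0, C, M)
      for (j in seq_len(layer$K))
        out <- out + X[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
      list(out = out / layer$K, cache = NULL)
    },
    flatten = {
      out <- A
      dim(out) <- c(layer$c * layer$s, N)
      list(out = out, cache = NULL)
    },
    dropout = {
      if (train && layer$rate > 0) {
        mask <- matrix(stats::runif(length(A)) >= layer$rate,
                       nrow(A), ncol(A))
        list(out = A * mask / (1 - layer$rate), cache = list(mask = mask))
      } else list(out = A, cache = NULL)
    },
    dense = {
      list(out = layer$W %*% A + layer$b, cache = list(X = A))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, A_in, cache, dY, N) {
  switch(
    layer$type,
    conv3d = {
      dW <- tcrossprod(dY, cache$X)
      db <- rowSums(dY)
      dXcol <- crossprod(layer$W, dY)
      dA <- if (layer$K == 1L && layer$stride == 1L && layer$pad == 0L)
        dXcol else cpp_col2im(dXcol, layer$map, N, layer$S_in)
      list(dA = dA, grads = list(W = dW, b = db))
    },
    batchnorm = {
      if (is.null(cache)) stop("batchnorm backward requires train mode")
      M <- ncol(dY)
      dgamma <- rowSums(dY * cache$xhat)
      dbeta <- rowSums(dY)
      dxhat <- dY * layer$gamma
      dA <- cache$isd / M *
        (M * dxhat - rowSums(dxhat) -
           cache$xhat * rowSums(dxhat * cache$xhat))
      list(dA = dA, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dA = dY * cache$mask, grads = NULL),
    avgpool = {
      C <- nrow(dY)
      dXcol <- (dY / layer$K)[rep(seq_len(C), layer$K), , drop = FALSE]
      list(dA = cpp_col2im(dXcol, layer$map, N, layer$S_in), grads = NULL)
    },
    flatten = {
      dA <- dY
      dim(dA) <- c(layer$c, layer$s * N)
      list(dA = dA, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dA = dY, grads = NULL)
      else list(dA = dY * cache$mask / (1 - layer$rate), grads = NULL)
    },
    dense = {
      list(dA = crossprod(layer$W, dY),
           grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Forward through a list of layers. Returns the output, per-layer caches
# and inputs (for backward), and updated layers (batchnorm running stats).
net_forward <- function(layers, A, N, train) {
  caches <- vector("list", length(layers))
  inputs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    inputs[[i]] <- A
    fw <- layer_forward(layers[[i]], A, N, train)
    A <- fw$out
    caches[[i]] <- fw$cache
    if (!is.null(fw$state))
      layers[[i]][names(fw$state)] <- fw$state
  }
  list(out = A, caches = caches, inputs = inputs, layers = layers)
}

# Backward through the layers; returns input gradient and per-layer grads.
net_backward <- function(layers, fw, dY, N_per_layer) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], fw$inputs[[i]], fw$caches[[i]], dY,
                         N_per_layer[i])
    dY <- bw$dA
    grads[i] <- list(bw$grads)  # [[<- would drop NULL entries
  }
  list(dA = dY, grads = grads)
}

# Number of samples N is constant; spatial S varies by layer but only N is
# needed for the scatter ops.
rep_n <- function(layers, N) rep(N, length(layers))

# ---- losses ---------------------------------------------------------------

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max), "-")
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# Weighted categorical cross-entropy. labels: integer class per column.
# weights: per-class loss weights (mean ~ 1).
ce_loss_grad <- function(Z, labels, weights = NULL) {
  N <- ncol(Z)
  P <- softmax_cols(Z)
  if (is.null(weights)) weights <- rep(1, nrow(Z))
  w <- weights[labels]
  pick <- cbind(labels, seq_len(N))
  loss <- -sum(w * log(pmax(P[pick], 1e-12))) / N
  dZ <- P
  dZ[pick] <- dZ[pick] - 1
  dZ <- sweep(dZ, 2, w / N, "*")
  list(loss = loss, dZ = dZ, probs = P)
}

mse_loss_grad <- function(pred, target) {
  N <- length(target)
  r <- as.numeric(pred) - as.numeric(target)
  list(loss = mean(r^2), dZ = matrix(2 * r / N, 1, N))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    pn <- intersect(names(l), c("W", "b", "gamma", "beta"))
    if (length(pn) == 0) return(NULL)
    stats::setNames(lapply(pn, function(p)
      list(m = l[[p]] * 0, v = l[[p]] * 0)), pn)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}
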