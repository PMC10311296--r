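# Network architectures and training.
#
# A shared convolutional "trunk" (per-voxel channel projector, three 3D
# convolutions with batch normalization, average pooling, flatten) feeds
# two heads:
#  * the masked-residue model: three fully connected layers (200, 20, 20)
#    with softmax over the 20 amino acids, trained with weighted
#    categorical cross-entropy to recover the identity of the masked
#    central residue (self-supervision);
#  * the Siamese ddG model: two weight-sharing branches (trunk + FC 200 +
#    FC 20) applied to the wild-type and mutant cubes, merged by
#    subtraction, concatenated with the auxiliary features, and mapped by
#    one linear unit to the predicted binding free-energy change.

AA_LEVELS <- sort(unname(aa_three_to_one()))

#' Trunk configuration
#'
#' The default mirrors the documented architecture: 167 (or 4) input
#' channels projected to 20 per voxel, three 3x3x3 convolutions
#' (32, 64, 128 filters, stride 1) with batch normalization, average
#' pooling of the 24-voxel grid down to 3x3x3, and dropout rates
#' (0.40, 0.20, 0.10) on the fully connected subnetwork. All fields are
#' free hyperparameters; reduced settings (fewer filters, stride-2
#' convolutions, `pool = 1`) give a desk-scale trunk that trains in
#' minutes on one CPU and is used throughout the test suite.
#'
#' @param n_channels_in Input channels (167 for `full167`, 4 for
#'   `element4`).
#' @param projector_dim Per-voxel projection dimension (default 20).
#' @param conv_filters Filter counts of the three convolutions.
#' @param conv_strides Strides of the three convolutions.
#' @param kernel Convolution kernel size (cubic; default 3).
#' @param pool Average-pooling factor applied after the convolutions.
#' @param n_voxels Input grid side (default 24).
#' @param embed_dim Size of the first fully connected layer whose
#'   activation is the residue embedding (default 200).
#' @param fc2_dim Size of the second fully connected layer (default 20).
#' @param dropout Dropout rates for (input of FC subnetwork, after FC1,
#'   after FC2).
#' @return A `trunk_config` list, with the derived spatial dimensions.
#' @export
trunk_config <- function(n_channels_in,
                         projector_dim = 20,
                         conv_filters = c(32, 64, 128),
                         conv_strides = c(1, 1, 1),
                         kernel = 3,
                         pool = 8,
                         n_voxels = 24,
                         embed_dim = 200,
                         fc2_dim = 20,
                         dropout = c(0.40, 0.20, 0.10)) {
  stopifnot(length(conv_filters) == 3, length(conv_strides) == 3,
            length(dropout) == 3)
  d <- n_voxels
  dims <- integer(3)
  for (i in 1:3) {
    d <- conv_out_dim(d, kernel, conv_strides[i], 1L)
    dims[i] <- d
  }
  if (d %% pool != 0)
    stop("pooling factor ", pool, " does not divide the final grid side ", d)
  d_pool <- d %/% pool
  structure(list(n_channels_in = n_channels_in,
                 projector_dim = projector_dim,
                 conv_filters = conv_filters,
                 conv_strides = conv_strides,
                 kernel = kernel, pool = pool, n_voxels = n_voxels,
                 conv_dims = dims, d_pool = d_pool,
                 trunk_dim = conv_filters[3] * d_pool^3,
                 embed_dim = embed_dim, fc2_dim = fc2_dim,
                 dropout = dropout),
            class = "trunk_config")
}

# Desk-scale default used by fixtures-driven examples and tests.
#' @rdname trunk_config
#' @param ... Overrides passed to [trunk_config()].
#' @export
small_trunk_config <- function(n_channels_in = 4, ...) {
  args <- list(n_channels_in = n_channels_in,
               projector_dim = 8,
               conv_filters = c(8, 12, 16),
               conv_strides = c(2, 2, 2),
               pool = 1,
               embed_dim = 200,
               fc2_dim = 20)
  over <- list(...)
  args[names(over)] <- over
  do.call(trunk_config, args)
}

build_trunk_layers <- function(cfg) {
  d <- cfg$n_voxels
  layers <- list(
    nn_conv3d(cfg$n_channels_in, cfg$projector_dim, 1L, 1L, 0L, d),
    nn_batchnorm(cfg$projector_dim),
    nn_relu()
  )
  c_prev <- cfg$projector_dim
  for (i in 1:3) {
    layers <- c(layers, list(
      nn_conv3d(c_prev, cfg$conv_filters[i], cfg$kernel,
                cfg$conv_strides[i], 1L, d),
      nn_batchnorm(cfg$conv_filters[i]),
      nn_relu()
    ))
    d <- conv_out_dim(d, cfg$kernel, cfg$conv_strides[i], 1L)
    c_prev <- cfg$conv_filters[i]
  }
  if (cfg$pool > 1)
    layers <- c(layers, list(nn_avgpool(d, cfg$pool)))
  c(layers, list(nn_flatten(c_prev, cfg$d_pool^3)))
}

# Convert one cube_map (or a list of them) to the C x (S*N) batch matrix.
cubes_to_batch <- function(cubes) {
  if (inherits(cubes, "cube_map")) cubes <- list(cubes)
  mats <- lapply(cubes, function(cm) {
    g <- cm$grid
    S <- cm$n_voxels^3
    t(matrix(g, S, cm$n_channels))
  })
  list(A = do.call(cbind, mats), N = length(cubes),
       S = cubes[[1]]$n_voxels^3)
}

# ---- masked-residue (self-supervised) model -------------------------------

#' Build the masked-residue recovery model
#'
#' Trunk plus a fully connected subnetwork of sizes (`embed_dim`, 20, 20)
#' with dropout (0.40, 0.20, 0.10) and a 20-way softmax over the amino
#' acids (alphabetical 1-letter order). The output layer is
#' zero-initialized, so an untrained model predicts the uniform
#' distribution.
#'
#' @param config A [trunk_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ssdla_model`.
#' @export
ssdla_model <- function(config, seed = 1L) {
  set.seed(seed)
  trunk <- build_trunk_layers(config)
  layers <- c(trunk, list(
    nn_dropout(config$dropout[1]),
    nn_dense(config$trunk_dim, config$embed_dim),
    nn_relu(),
    nn_dropout(config$dropout[2]),
    nn_dense(config$embed_dim, config$fc2_dim),
    nn_relu(),
    nn_dropout(config$dropout[3]),
    nn_dense(config$fc2_dim, 20, zero_init = TRUE)
  ))
  structure(list(layers = layers, config = config,
                 n_trunk = length(trunk),
                 embed_index = length(trunk) + 3L,  # after FC1 + relu
                 classes = AA_LEVELS),
            class = "ssdla_model")
}

#' Forward pass of the masked-residue model
#'
#' @param model An [ssdla_model()].
#' @param cubes A `cube_map` or list of them.
#' @param train Logical; `TRUE` enables dropout and batch statistics
#'   (training mode). Evaluation mode is deterministic.
#' @return Matrix of class probabilities (20 x N), rows named by amino
#'   acid; columns sum to 1.
#' @export
ssdla_forward <- function(model, cubes, train = FALSE) {
  batch <- cubes_to_batch(cubes)
  if (nrow(batch$A) != model$config$n_channels_in)
    stop("cube has ", nrow(batch$A), " channels but the model expects ",
         model$config$n_channels_in)
  fw <- net_forward(model$layers, batch$A, batch$N, train)
  P <- softmax_cols(fw$out)
  rownames(P) <- model$classes
  P
}

#' Residue embedding of a cube
#'
#' The activation of the first fully connected layer (length
#' `config$embed_dim`, default 200), computed in evaluation mode.
#'
#' @param model An [ssdla_model()] (or `siamese_ddg_model`, whose branch
#'   FC1 is used).
#' @param cubes A `cube_map` or list of them.
#' @return Numeric matrix `embed_dim x N` (a vector for a single cube).
#' @export
embed_cube <- function(model, cubes) {
  batch <- cubes_to_batch(cubes)
  layers <- model$layers[seq_len(model$embed_index)]
  fw <- net_forward(layers, batch$A, batch$N, train = FALSE)
  if (batch$N == 1) as.numeric(fw$out) else fw$out
}

#' Inverse-frequency class weights for the masked-residue loss
#'
#' `w_a` proportional to `1 / f_a`, normalized to mean 1, penalizing
#' errors on rare amino acids more.
#'
#' @param freqs Named (or 20-long) vector of amino-acid frequencies; all
#'   must be positive.
#' @return Numeric weight vector on the same names/order.
#' @export
#' @examples
#' class_weights(c(A = 0.5, C = 0.25, G = 0.25))
class_weights <- function(freqs) {
  if (any(freqs <= 0))
    stop("zero/negative amino-acid frequency: degenerate training set")
  w <- 1 / freqs
  w / mean(w)
}

#' Train the masked-residue model
#'
#' Minimizes the class-weighted categorical cross-entropy between the
#' softmax output and the true central-residue identity, with Adam.
#'
#' @param cubes List of masked `cube_map` objects.
#' @param labels True central-residue identities (1-letter codes, or a
#'   factor over [AA_LEVELS]).
#' @param config A [trunk_config()]; must match the cubes' channel count.
#' @param epochs Training epochs (default 50).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 64).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param weights Optional per-class loss weights from [class_weights()];
#'   default: estimated from `labels`.
#' @param model Optional pre-built model to continue training.
#' @param verbose Print the loss each epoch.
#' @return List with `model` (trained `ssdla_model`) and `history`
#'   (per-epoch mean loss).
#' @export
train_ssdla <- function(cubes, labels, config, epochs = 50, lr = 1e-4,
                        batch_size = 64, seed = 1L, weights = NULL,
                        model = NULL, verbose = FALSE) {
  if (length(cubes) == 0) stop("empty training set")
  y <- label_index(labels)
  stopifnot(length(y) == length(cubes))
  if (is.null(weights)) {
    f <- table(factor(AA_LEVELS[y], levels = AA_LEVELS))
    present <- f > 0
    w <- rep(0, 20)
    w[present] <- 1 / as.numeric(f[present])
    w <- w / mean(w[present])  # absent classes never contribute to the loss
    weights <- w
  }
  if (is.null(model)) model <- ssdla_model(config, seed = seed)
  set.seed(seed + 1L)
  batch <- cubes_to_batch(cubes)
  S <- batch$S
  n <- batch$N
  state <- adam_init(model$layers)
  history <- numeric(epochs)
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      cols <- as.vector(outer(seq_len(S), (idx - 1L) * S, "+"))
      A <- batch$A[, cols, drop = FALSE]
      fw <- net_forward(model$layers, A, length(idx), train = TRUE)
      model$layers <- fw$layers
      lg <- ce_loss_grad(fw$out, y[idx], weights)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", ep, "; lower the learning rate")
      bw <- net_backward(model$layers, fw, lg$dZ,
                         rep(length(idx), length(model$layers)))
      t_step <- t_step + 1L
      up <- adam_step(model$layers, bw$grads, state, lr, t_step)
      model$layers <- up$layers
      state <- up$state
      losses <- c(losses, lg$loss)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, history[ep]))
  }
  list(model = model, history = history)
}

label_index <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  y <- match(toupper(labels), AA_LEVELS)
  if (anyNA(y))
    stop("unknown amino-acid label(s): ",
         paste(unique(labels[is.na(y)]), collapse = ", "))
  y
}

# ---- Siamese ddG model ----------------------------------------------------

#' Build the Siamese ddG model
#'
#' Two branches with strictly shared weights (one parameter set) process
#' the wild-type and mutant cubes through the trunk and two fully
#' connected layers (`embed_dim`, then `fc2_dim`). The branch outputs are
#' merged by subtraction (wild-type minus mutant, a frozen convention),
#' the auxiliary feature vector is concatenated, and a single
#' zero-initialized linear unit outputs the predicted ddG in kcal/mol.
#'
#' @param config A [trunk_config()].
#' @param aux_dim Length of the encoded auxiliary vector (default 9).
#' @param seed Seed for weight initialization.
#' @param init_from Optional trained [ssdla_model()]; its trunk and first
#'   fully connected layer are copied into the branch (pre-trained
#'   initialization), the rest is fresh.
#' @return An object of class `siamese_ddg_model`.
#' @export
siamese_ddg_model <- function(config, aux_dim = 9, seed = 1L,
                              init_from = NULL) {
  set.seed(seed)
  trunk <- build_trunk_layers(config)
  branch <- c(trunk, list(
    nn_dropout(config$dropout[1]),
    nn_dense(config$trunk_dim, config$embed_dim),
    nn_relu(),
    nn_dropout(config$dropout[2]),
    nn_dense(config$embed_dim, config$fc2_dim),
    nn_relu(),
    nn_dropout(config$dropout[3])
  ))
  if (!is.null(init_from)) {
    stopifnot(inherits(init_from, "ssdla_model"))
    # trunk + first FC transferred from the pre-trained model
    n_copy <- init_from$n_trunk + 2L  # trunk, dropout, dense(embed)
    for (i in seq_len(n_copy)) {
      src <- init_from$layers[[i]]
      for (p in intersect(names(src),
                          c("W", "b", "gamma", "beta",
                            "run_mean", "run_var")))
        branch[[i]][[p]] <- src[[p]]
    }
  }
  head <- nn_dense(config$fc2_dim + aux_dim, 1, zero_init = TRUE)
  structure(list(branch = branch, head = head, config = config,
                 aux_dim = aux_dim,
                 n_trunk = length(trunk),
                 embed_index = length(trunk) + 3L,
                 layers = branch),  # alias so embed_cube() works
            class = "siamese_ddg_model")
}

branch_forward <- function(model, cubes, train) {
  batch <- cubes_to_batch(cubes)
  if (nrow(batch$A) != model$config$n_channels_in)
    stop("cube channel count does not match the model configuration")
  fw <- net_forward(model$branch, batch$A, batch$N, train)
  fw$N <- batch$N
  fw
}

#' Predict ddG for wild-type / mutant cube pairs
#'
#' `pred = w . (branch(wt) - branch(mu)) + v . aux + c`: because the two
#' branches share one weight set, identical cubes contribute exactly zero
#' and the prediction reduces to the auxiliary-only value.
#'
#' @param model A [siamese_ddg_model()].
#' @param wt_cubes,mu_cubes `cube_map` objects or equal-length lists.
#' @param aux Auxiliary vectors: length-`aux_dim` vector or N x `aux_dim`
#'   matrix.
#' @param train Training mode flag (dropout + batch statistics).
#' @return Numeric vector of predicted ddG values (kcal/mol).
#' @export
ddg_forward <- function(model, wt_cubes, mu_cubes, aux, train = FALSE) {
  if (inherits(wt_cubes, "cube_map")) wt_cubes <- list(wt_cubes)
  if (inherits(mu_cubes, "cube_map")) mu_cubes <- list(mu_cubes)
  stopifnot(length(wt_cubes) == length(mu_cubes))
  if (wt_cubes[[1]]$scheme_mode != mu_cubes[[1]]$scheme_mode)
    stop("wild-type and mutant cubes use different channel schemes")
  aux <- to_aux_matrix(aux, length(wt_cubes), model$aux_dim)
  fw_wt <- branch_forward(model, wt_cubes, train)
  fw_mu <- branch_forward(model, mu_cubes, train)
  diff <- fw_wt$out - fw_mu$out
  Z <- rbind(diff, t(aux))
  out <- layer_forward(model$head, Z, ncol(Z), train)$out
  as.numeric(out)
}

to_aux_matrix <- function(aux, n, aux_dim) {
  if (is.null(dim(aux))) aux <- matrix(aux, nrow = n, ncol = length(aux),
                                       byrow = TRUE)
  aux <- as.matrix(aux)
  if (ncol(aux) != aux_dim)
    stop("auxiliary vector length ", ncol(aux),
         " does not match the model (", aux_dim, ")")
  aux
}

#' Train the Siamese ddG model
#'
#' Minimizes the mean squared error between predicted and ground-truth
#' ddG with Adam. Supports pre-trained or random initialization and the
#' auxiliary ablation configurations (via the `aux` matrix the caller
#' assembled).
#'
#' @param wt_cubes,mu_cubes Lists of cubes (equal length N).
#' @param aux N x `aux_dim` matrix of encoded auxiliary features.
#' @param targets Ground-truth ddG values (length N, kcal/mol).
#' @param config A [trunk_config()].
#' @param init `"random"` or a trained [ssdla_model()] for pre-trained
#'   initialization.
#' @param epochs,lr,batch_size,seed Training hyperparameters (defaults:
#'   fine-tuning learning rate 1e-3).
#' @param model Optional existing model to continue training (overrides
#'   `init`). With `epochs = 0` the initialized model is returned
#'   unchanged.
#' @param verbose Print the loss each epoch.
#' @return List with `model` and `history` (per-epoch mean MSE).
#' @export
train_ddg <- function(wt_cubes, mu_cubes, aux, targets, config,
                      init = "random", epochs = 100, lr = 1e-3,
                      batch_size = 32, seed = 1L, model = NULL,
                      verbose = FALSE) {
  n <- length(targets)
  stopifnot(length(wt_cubes) == n, length(mu_cubes) == n)
  aux <- to_aux_matrix(aux, n, ncol(as.matrix(aux)))
  if (is.null(model)) {
    init_model <- if (inherits(init, "ssdla_model")) init else NULL
    model <- siamese_ddg_model(config, aux_dim = ncol(aux), seed = seed,
                               init_from = init_model)
  }
  if (epochs == 0) return(list(model = model, history = numeric(0)))
  set.seed(seed + 1L)
  wt_batch <- cubes_to_batch(wt_cubes)
  mu_batch <- cubes_to_batch(mu_cubes)
  S <- wt_batch$S
  state_b <- adam_init(model$branch)
  state_h <- adam_init(list(model$head))
  history <- numeric(epochs)
  t_step <- 0L
  nb <- length(model$branch)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      m <- length(idx)
      cols <- as.vector(outer(seq_len(S), (idx - 1L) * S, "+"))
      fw_wt <- net_forward(model$branch, wt_batch$A[, cols, drop = FALSE],
                           m, train = TRUE)
      model$branch <- fw_wt$layers
      fw_mu <- net_forward(model$branch, mu_batch$A[, cols, drop = FALSE],
                           m, train = TRUE)
      model$branch <- fw_mu$layers
      diff <- fw_wt$out - fw_mu$out
      Z <- rbind(diff, t(aux[idx, , drop = FALSE]))
      hw <- layer_forward(model$head, Z, m, train = TRUE)
      lg <- mse_loss_grad(hw$out, targets[idx])
      if (!is.finite(lg$loss))
        stop("non-finite ddG training loss at epoch ", ep,
             " (step ", t_step + 1L, "): inspect targets/learning rate")
      hb <- layer_backward(model$head, Z, hw$cache, lg$dZ, m)
      ddiff <- hb$dA[seq_len(model$config$fc2_dim), , drop = FALSE]
      bw_wt <- net_backward(model$branch, fw_wt, ddiff, rep(m, nb))
      bw_mu <- net_backward(model$branch, fw_mu, -ddiff, rep(m, nb))
      grads <- grads_add(bw_wt$grads, bw_mu$grads)
      t_step <- t_step + 1L
      up <- adam_step(model$branch, grads, state_b, lr, t_step)
      model$branch <- up$layers
      state_b <- up$state
      uph <- adam_step(list(model$head), list(hb$grads), state_h, lr, t_step)
      model$head <- uph$layers[[1]]
      state_h <- uph$state
      losses <- c(losses, lg$loss)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d  mse %.4f", ep, history[ep]))
  }
  model$layers <- model$branch
  list(model = model, history = history)
}

grads_add <- function(g1, g2) {
  for (i in seq_along(g1)) {
    if (is.null(g1[[i]])) next
    for (p in names(g1[[i]]))
      g1[[i]][[p]] <- g1[[i]][[p]] + g2[[i]][[p]]
  }
  g1
}

# ---- downstream embedding classifiers -------------------------------------

#' Classifier from residue embeddings to categorical properties
#'
#' One hidden layer of size 20 on top of the (mean) embedding, softmax
#' output, categorical cross-entropy: used to map single-cube embeddings
#' to the seven physicochemical classes, or interface-averaged embeddings
#' to functional classes.
#'
#' @param n_classes Number of output classes.
#' @param embed_dim Embedding length (default 200).
#' @param seed Seed for initialization.
#' @return An `embedding_classifier` model.
#' @export
embedding_classifier <- function(n_classes, embed_dim = 200, seed = 1L) {
  set.seed(seed)
  layers <- list(
    nn_dense(embed_dim, 20),
    nn_relu(),
    nn_dense(20, n_classes, zero_init = TRUE)
  )
  structure(list(layers = layers, n_classes = n_classes,
                 embed_dim = embed_dim),
            class = "embedding_classifier")
}

#' @rdname embedding_classifier
#' @param model An `embedding_classifier`.
#' @param embeddings Vector (one sample) or N x `embed_dim` matrix.
#' @return `downstream_classify()`: matrix of class probabilities
#'   (`n_classes` x N), columns summing to 1.
#' @export
downstream_classify <- function(model, embeddings) {
  X <- if (is.null(dim(embeddings))) matrix(embeddings, ncol = 1)
  else t(as.matrix(embeddings))
  if (nrow(X) != model$embed_dim)
    stop("embedding length does not match the classifier")
  fw <- net_forward(model$layers, X, ncol(X), train = FALSE)
  softmax_cols(fw$out)
}

#' @rdname embedding_classifier
#' @param labels Integer class labels (1..n_classes) or factor.
#' @param epochs,lr,seed2 Training hyperparameters.
#' @export
train_embedding_classifier <- function(model, embeddings, labels,
                                       epochs = 200, lr = 1e-3,
                                       seed2 = 1L) {
  X <- t(as.matrix(embeddings))
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  set.seed(seed2)
  state <- adam_init(model$layers)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- net_forward(model$layers, X, ncol(X), train = TRUE)
    lg <- ce_loss_grad(fw$out, y)
    bw <- net_backward(model$layers, fw, lg$dZ,
                       rep(ncol(X), length(model$layers)))
    up <- adam_step(model$layers, bw$grads, state, lr, ep)
    model$layers <- up$layers
    state <- up$state
    history[ep] <- lg$loss
  }
  list(model = model, history = history)
}

#' Mean embedding of an interface
#'
#' @param embeddings `embed_dim` x N matrix of per-cube embeddings.
#' @return The arithmetic mean embedding (length `embed_dim`).
#' @export
mean_interface_embedding <- function(embeddings) {
  if (is.null(dim(embeddings))) return(as.numeric(embeddings))
  rowMeans(embeddings)
}
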