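# Network engine and model contracts: exact gradients, softmax contracts,
# weight sharing, Siamese identities, training determinism.

test_that("analytic gradients match numerical differentiation everywhere", {
  cfg <- tiny_trunk()
  m <- ssdla_model(cfg, seed = 2)
  set.seed(9)
  nl <- length(m$layers)
  m$layers[[nl]]$W <- matrix(rnorm(length(m$layers[[nl]]$W), sd = 0.3),
                             nrow(m$layers[[nl]]$W))
  N <- 3; S <- cfg$n_voxels^3
  A <- matrix(abs(rnorm(4 * S * N, sd = 0.5)), 4)
  y <- c(1L, 5L, 20L)
  w <- rep(1, 20)
  loss_of <- function(layers) {
    fw <- voxddg:::net_forward(layers, A, N, train = TRUE)
    voxddg:::ce_loss_grad(fw$out, y, w)$loss
  }
  fw <- voxddg:::net_forward(m$layers, A, N, train = TRUE)
  lg <- voxddg:::ce_loss_grad(fw$out, y, w)
  bw <- voxddg:::net_backward(m$layers, fw, lg$dZ, rep(N, length(m$layers)))
  eps <- 1e-5
  worst <- 0
  for (i in seq_along(m$layers)) {
    g <- bw$grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      th <- m$layers[[i]][[p]]
      for (j in sample(length(th), min(4, length(th)))) {
        L2 <- m$layers; L2[[i]][[p]][j] <- th[j] + eps
        L1 <- m$layers; L1[[i]][[p]][j] <- th[j] - eps
        num <- (loss_of(L2) - loss_of(L1)) / (2 * eps)
        worst <- max(worst, abs(num - g[[p]][j]) /
                       max(1e-6, abs(num) + abs(g[[p]][j])))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("masked-residue probabilities are a deterministic distribution", {
  cfg <- small_trunk_config(4)
  m <- ssdla_model(cfg, seed = 1)
  cm <- toy_cube(1, masked = TRUE)
  P1 <- ssdla_forward(m, cm)
  P2 <- ssdla_forward(m, cm)
  expect_identical(P1, P2)              # eval mode has no randomness
  expect_equal(sum(P1), 1, tolerance = 1e-5)
  expect_true(all(P1 >= 0))
  # zero-initialized output layer: exactly uniform over the 20 classes
  expect_equal(unname(P1[, 1]), rep(0.05, 20))
  expect_equal(rownames(P1), sort(unname(aa_three_to_one())))
})

test_that("channel mismatches are rejected", {
  cfg <- small_trunk_config(4)
  m <- ssdla_model(cfg, seed = 1)
  st <- toy_complex(1)
  cm167 <- voxelize(extract_cube_atoms(st, attr(st, "patch_keys")[1]),
                    build_channel_scheme("full167"))
  expect_error(ssdla_forward(m, cm167), "channels")
})

test_that("class weights are inverse-frequency with mean one", {
  expect_equal(unname(class_weights(rep(0.05, 20))), rep(1, 20))
  w <- class_weights(c(A = 0.5, C = 0.25, G = 0.25))
  expect_equal(unname(w), c(0.6, 1.2, 1.2))
  # weights are inverse-proportional: doubly frequent -> half the weight
  expect_equal(w[["A"]] / w[["C"]], 0.5)
  expect_error(class_weights(c(0.5, 0, 0.5)), "degenerate")
})

test_that("embeddings have the configured size and respond to input", {
  cfg <- small_trunk_config(4)
  m <- ssdla_model(cfg, seed = 3)
  cm1 <- toy_cube(1)
  e1 <- embed_cube(m, cm1)
  expect_length(e1, 200)
  # rigid motion of the source structure leaves the embedding unchanged
  st <- toy_complex(1)
  key <- attr(st, "patch_keys")[1]
  st2 <- transform_structure(st, random_rotation(12), c(4, 4, -2))
  cmr <- voxelize(extract_cube_atoms(st2, key),
                  build_channel_scheme("element4"))
  expect_equal(embed_cube(m, cmr), e1, tolerance = 1e-4)
  # a different environment gives a different embedding
  e2 <- embed_cube(m, toy_cube(1, masked = TRUE))
  expect_gt(max(abs(e1 - e2)), 1e-6)
})

test_that("the Siamese head satisfies its algebraic identities", {
  cfg <- small_trunk_config(4)
  m <- siamese_ddg_model(cfg, seed = 2)
  set.seed(4)
  m$head$W <- matrix(rnorm(length(m$head$W), sd = 0.3), 1)
  dd <- make_synthetic_ddg(20, noise_sd = 0, seed = 3)
  for (i in c(1, 7, 13)) {
    x <- dd$wt_cubes[[i]]; y <- dd$mu_cubes[[i]]; aux <- dd$aux[i, ]
    pxx <- ddg_forward(m, x, x, aux)
    pxy <- ddg_forward(m, x, y, aux)
    pyx <- ddg_forward(m, y, x, aux)
    expect_equal(pxy + pyx, 2 * pxx, tolerance = 1e-5)
    # identical cubes: prediction reduces to the auxiliary-only value
    aux_only <- sum(m$head$W[1, cfg$fc2_dim + seq_len(9)] * aux) + m$head$b
    expect_equal(pxx, unname(aux_only), tolerance = 1e-10)
  }
})

test_that("the two branches are one parameter object", {
  cfg <- small_trunk_config(4)
  m <- siamese_ddg_model(cfg, seed = 2)
  # the model holds a single branch; both inputs pass through it
  expect_identical(m$layers, m$branch)
  dd <- make_synthetic_ddg(20, noise_sd = 0.1, seed = 5)
  tr <- train_ddg(dd$wt_cubes, dd$mu_cubes, dd$aux, dd$targets, cfg,
                  epochs = 1, lr = 1e-3, batch_size = 20, seed = 6)
  expect_identical(tr$model$layers, tr$model$branch)
})

test_that("training is seeded and reproducible to the bit", {
  sc <- build_channel_scheme("element4")
  fx <- make_labeled_cubes(20, sc, seed = 2)
  cfg <- small_trunk_config(4)
  t1 <- train_ssdla(fx$cubes, fx$labels, cfg, epochs = 2, lr = 1e-3,
                    batch_size = 10, seed = 9)
  t2 <- train_ssdla(fx$cubes, fx$labels, cfg, epochs = 2, lr = 1e-3,
                    batch_size = 10, seed = 9)
  expect_identical(t1$history, t2$history)
  expect_true(all(is.finite(t1$history)))
})

test_that("ddG training supports both initializations and a no-op run", {
  sc <- build_channel_scheme("element4")
  cfg <- small_trunk_config(4)
  dd <- make_synthetic_ddg(20, noise_sd = 0.1, seed = 5)
  z <- train_ddg(dd$wt_cubes, dd$mu_cubes, dd$aux, dd$targets, cfg,
                 epochs = 0, seed = 5)
  expect_length(z$history, 0)
  r1 <- train_ddg(dd$wt_cubes, dd$mu_cubes, dd$aux, dd$targets, cfg,
                  init = "random", epochs = 2, batch_size = 20, seed = 5)
  fx <- make_labeled_cubes(20, sc, seed = 2)
  pre <- train_ssdla(fx$cubes, fx$labels, cfg, epochs = 1, batch_size = 20,
                     seed = 3)
  r2 <- train_ddg(dd$wt_cubes, dd$mu_cubes, dd$aux, dd$targets, cfg,
                  init = pre$model, epochs = 2, batch_size = 20, seed = 5)
  expect_false(identical(r1$history, r2$history))
})

test_that("embedding classifiers expose the documented output shapes", {
  cl7 <- embedding_classifier(7, seed = 1)
  e <- rnorm(200)
  p7 <- downstream_classify(cl7, e)
  expect_equal(dim(p7), c(7, 1))
  expect_equal(sum(p7), 1, tolerance = 1e-8)
  cl3 <- embedding_classifier(3, seed = 1)
  expect_equal(nrow(downstream_classify(cl3, e)), 3)
  # averaging identical embeddings is the identity
  E <- cbind(e, e, e)
  expect_equal(mean_interface_embedding(E), e, ignore_attr = TRUE)
})
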