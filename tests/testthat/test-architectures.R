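test_that("the baseline MLP has a 399-unit hidden layer and 160,841 parameters", {
  # hand tally: embedding 21*21 = 441; hidden 399*399 + 399 = 159,600 + 399;
  # head 399*2 + 2 = 800; total 160,841
  m <- build_model(model_config(), "smlp", seed = 1)
  expect_equal(dim(m$params$fc1_w), c(399L, 399L))
  expect_equal(count_parameters(m), 441L + 399L * 399L + 399L + 399L * 2L + 2L)
  expect_equal(count_parameters(m), 160841L)
})

test_that("every variant emits (n x 2) finite scores for any batch size", {
  cfg <- model_config()
  d <- tibble::tibble(window = random_windows(7, seed = 2))
  one <- tibble::tibble(window = random_windows(1, seed = 3))
  for (v in c("ssmfn_merged", "ssmfn_cnn_only", "ssmfn_lstm_only", "smlp")) {
    m <- build_model(cfg, v, seed = 4)
    s <- forward(m, d)
    expect_identical(dim(s), c(7L, 2L))
    expect_true(all(is.finite(s)))
    expect_identical(dim(forward(m, one)), c(1L, 2L))
  }
})

test_that("both branch latents have length 32 under the default configuration", {
  m <- build_model(model_config(), "ssmfn_merged", seed = 5)
  lat <- forward_latent(m, tibble::tibble(window = random_windows(4, seed = 5)))
  expect_identical(ncol(lat$latent_cnn), 32L)
  expect_identical(ncol(lat$latent_lstm), 32L)
  expect_identical(ncol(lat$fused), 32L)
  # vocabulary and recurrent width as configured
  expect_identical(nrow(m$params$embedding), 21L)
  expect_identical(ncol(m$params$lstm1_wh), 4L * 64L)
  expect_identical(nrow(m$params$lstm1_wh), 64L)
})

test_that("fuse is commutative element-wise addition with the zero identity", {
  withr::with_seed(6, {
    a <- stats::rnorm(32)
    b <- stats::rnorm(32)
    expect_equal(fuse(a, b), a + b)
    expect_equal(fuse(a, b), fuse(b, a))
    expect_equal(fuse(a, rep(0, 32)), a)
    expect_error(fuse(a, stats::rnorm(16)), class = "ssmfn_fusion_error")
  })
})

test_that("fusion is exact: latents sum to the fused vector, and zeroing one
           branch reproduces the surviving single-branch computation", {
  cfg <- model_config()
  d <- tibble::tibble(window = random_windows(6, seed = 7))
  merged <- build_model(cfg, "ssmfn_merged", seed = 8)
  lat <- forward_latent(merged, d)
  expect_equal(lat$fused, lat$latent_cnn + lat$latent_lstm, tolerance = 1e-6)

  # zero the CNN latent pathway in the merged model; copy the shared and
  # LSTM weights into an lstm_only model: the forwards must agree
  dead_cnn <- merged
  dead_cnn$params$cnn_latent_w[] <- 0
  dead_cnn$params$cnn_latent_b[] <- 0
  lstm_only <- build_model(cfg, "ssmfn_lstm_only", seed = 99)
  for (nm in names(lstm_only$params)) {
    lstm_only$params[[nm]] <- merged$params[[nm]]
  }
  expect_equal(forward(dead_cnn, d), forward(lstm_only, d), tolerance = 1e-6)

  # and symmetrically for the LSTM pathway
  dead_lstm <- merged
  dead_lstm$params$lstm_latent_w[] <- 0
  dead_lstm$params$lstm_latent_b[] <- 0
  cnn_only <- build_model(cfg, "ssmfn_cnn_only", seed = 98)
  for (nm in names(cnn_only$params)) {
    cnn_only$params[[nm]] <- merged$params[[nm]]
  }
  expect_equal(forward(dead_lstm, d), forward(cnn_only, d), tolerance = 1e-6)
})

test_that("parameter counts decompose: merged = cnn + lstm - shared parts", {
  cfg <- model_config()
  shared <- 21 * 21 + (32 * 2 + 2)  # embedding + head, counted once
  n_merged <- count_parameters(build_model(cfg, "ssmfn_merged"))
  n_cnn <- count_parameters(build_model(cfg, "ssmfn_cnn_only"))
  n_lstm <- count_parameters(build_model(cfg, "ssmfn_lstm_only"))
  expect_equal(n_merged, n_cnn + n_lstm - shared)
  expect_lt(n_cnn, n_merged)
  expect_lt(n_lstm, n_merged)
  # monotone in the latent width
  big <- count_parameters(build_model(model_config(latent_dim = 64),
                                      "ssmfn_merged"))
  expect_gt(big, n_merged)
  # stable across rebuilds with different init seeds
  expect_equal(count_parameters(build_model(cfg, "ssmfn_merged", seed = 77)),
               n_merged)
})

test_that("eval-mode forward is bit-identical across calls; probabilities sum to 1", {
  m <- build_model(model_config(), "ssmfn_merged", seed = 9)
  d <- tibble::tibble(window = random_windows(5, seed = 9))
  s1 <- forward(m, d)
  s2 <- forward(m, d)
  expect_identical(s1, s2)
  p <- ssmfn:::softmax_rows(s1)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  # train-mode with a fixed dropout seed is reproducible too
  t1 <- forward(m, d, mode = "train", dropout_seed = 3)
  t2 <- forward(m, d, mode = "train", dropout_seed = 3)
  expect_identical(t1, t2)
})

test_that("the embedding is shared: perturbing it moves both branch latents", {
  m <- build_model(model_config(), "ssmfn_merged", seed = 10)
  d <- tibble::tibble(window = random_windows(4, seed = 10))
  before <- forward_latent(m, d)
  m$params$embedding[1, ] <- m$params$embedding[1, ] + 1
  after <- forward_latent(m, d)
  expect_false(isTRUE(all.equal(before$latent_cnn, after$latent_cnn)))
  expect_false(isTRUE(all.equal(before$latent_lstm, after$latent_lstm)))
})

test_that("out-of-range encoded indices are rejected by the forward pass", {
  m <- build_model(model_config(), "smlp", seed = 1)
  batch <- encode_windows(tibble::tibble(window = random_windows(2, seed = 1)))
  batch$indices[1, 1] <- 21L
  expect_error(
    ssmfn:::cpp_forward(m$params, m$variant, unclass(m$config),
                        batch$indices, FALSE, 0L),
    "out of range"
  )
})

test_that("the core's loss and gradients match an independent double-precision
           reference (CNN branch) and finite differences (LSTM branch)", {
  cfg <- model_config(embedding_dim = 8, cnn_channels = 6, cnn_blocks = 3,
                      latent_dim = 5, dropout_rate = 0)
  d <- random_labeled(3, 2, seed = 44)
  b <- encode_windows(d)
  params <- ssmfn:::cpp_init("ssmfn_cnn_only", unclass(cfg), 3L)
  lg <- ssmfn:::cpp_loss_grad(params, "ssmfn_cnn_only", unclass(cfg),
                              b$indices, b$labels, 99L)
  ref <- reference_cnn_loss(params, b$indices, b$labels, cfg)
  expect_equal(lg$loss, ref, tolerance = 1e-5)
  # double-precision finite differences on the reference, random coordinates
  withr::with_seed(45, {
    for (nm in c("embedding", "conv1_w", "conv2_w", "conv3_w", "bn1_gamma",
                 "bn2_beta", "cnn_latent_w", "head_w")) {
      g <- lg$grads[[nm]]
      for (i in sample(length(g), min(4, length(g)))) {
        eps <- 1e-5
        p2 <- params
        p2[[nm]][i] <- p2[[nm]][i] + eps
        lp <- reference_cnn_loss(p2, b$indices, b$labels, cfg)
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        lm <- reference_cnn_loss(p2, b$indices, b$labels, cfg)
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(g[i] - fd) / max(1e-3, abs(fd), abs(g[i])), 5e-3)
      }
    }
  })
  # LSTM branch: float-precision central differences (smooth activations)
  cfg2 <- model_config(lstm_hidden = 8, latent_dim = 5, dropout_rate = 0)
  p0 <- ssmfn:::cpp_init("ssmfn_lstm_only", unclass(cfg2), 3L)
  lg2 <- ssmfn:::cpp_loss_grad(p0, "ssmfn_lstm_only", unclass(cfg2),
                               b$indices, b$labels, 99L)
  withr::with_seed(46, {
    for (nm in c("lstm1_wx", "lstm2_wh", "lstm_latent_w", "embedding")) {
      g <- lg2$grads[[nm]]
      for (i in sample(length(g), min(4, length(g)))) {
        eps <- 1e-2
        p2 <- p0
        p2[[nm]][i] <- p2[[nm]][i] + eps
        lp <- ssmfn:::cpp_loss_grad(p2, "ssmfn_lstm_only", unclass(cfg2),
                                    b$indices, b$labels, 99L)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        lm <- ssmfn:::cpp_loss_grad(p2, "ssmfn_lstm_only", unclass(cfg2),
                                    b$indices, b$labels, 99L)$loss
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(g[i] - fd) / max(1e-2, abs(fd), abs(g[i])), 2e-2)
      }
    }
  })
})
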