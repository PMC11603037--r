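test_that("focal loss reproduces closed-form hand values", {
  # gamma = 0, alpha = 1: plain cross-entropy; p_t = 0.5 -> -ln(0.5)
  expect_equal(focal_loss(0.5, 1, gamma = 0, alpha = 1, alpha_neg = 1),
               0.693147, tolerance = 1e-6)
  # perfect prediction -> zero loss
  expect_equal(focal_loss(1, 1, gamma = 2, alpha = 0.25), 0)
  # gamma = 2, alpha = 0.25, p_t = 0.9 -> 0.25 * 0.01 * (-ln 0.9)
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 0.25),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 0.25), 2.634e-4,
               tolerance = 1e-3)
})

test_that("focal loss at gamma 0 reduces exactly to weighted cross-entropy", {
  set.seed(1)
  p <- runif(20, 0.05, 0.95)
  y <- rbinom(20, 1, 0.5)
  w <- 7.3
  expect_equal(focal_loss(p, y, gamma = 0, alpha = w, alpha_neg = 1),
               weighted_ce(p, y, pos_weight = w), tolerance = 1e-12)
  expect_equal(weighted_ce(p, y, pos_weight = 1),
               mean(-(y * log(p) + (1 - y) * log(1 - p))), tolerance = 1e-12)
  # two-sample batch by hand
  expect_equal(weighted_ce(c(0.8, 0.3), c(1, 0), pos_weight = 2),
               mean(c(-2 * log(0.8), -log(0.7))), tolerance = 1e-12)
})

test_that("loss gradients match numerical differentiation", {
  z <- c(-1.2, 0.3, 2.0, -0.5)
  y <- c(1, 0, 1, 0)
  for (args in list(list(loss = "weighted_ce", pos_weight = 4),
                    list(loss = "focal", gamma = 2, alpha = 0.25),
                    list(loss = "focal", gamma = 0.5, alpha = 0.6,
                         alpha_neg = 0.4))) {
    f <- function(zz) do.call(periopod:::loss_and_grad,
                              c(list(z = zz, y = y), args))$value
    gnum <- vapply(seq_along(z), function(i) {
      e <- 1e-6; zp <- z; zm <- z
      zp[i] <- zp[i] + e; zm[i] <- zm[i] - e
      (f(zp) - f(zm)) / (2 * e)
    }, numeric(1))
    gan <- do.call(periopod:::loss_and_grad, c(list(z = z, y = y), args))$grad
    expect_equal(gan, gnum, tolerance = 1e-6)
  }
})

test_that("backpropagation matches finite differences for every architecture", {
  set.seed(42)
  B <- 3; n <- 4; k <- 2
  y <- c(1, 0, 1)
  Xs <- array(rnorm(B * n * k), c(B, n, k))
  Xt <- matrix(rnorm(B * 5), B, 5)
  shapes <- list(
    MLP_TAB_P = list(p = 5),
    LSTM_SEQ = list(k = k, n = n),
    TRAN_SEQ = list(k = k, n = n)
  )
  for (v in names(shapes)) {
    cfg <- model_config(v, mlp_neurons_per_layer = c(4, 3),
                        lstm_hidden = 3, lstm_layers = 2,
                        tran_linear_dim = 6, tran_encoder_layers = 2,
                        tran_ff_dim = 8, head_neurons = 4,
                        pos_encoding = "learnable", seed = 5)
    model <- build_model(cfg, shapes[[v]])
    batch <- list(seq = Xs, tab = Xt)
    f <- function(params) {
      m <- model; m$params <- params
      fw <- periopod:::forward_pod(m, batch)
      periopod:::loss_and_grad(fw$logit, y, loss = "focal",
                               gamma = 2, alpha = 0.3)$value
    }
    fw <- periopod:::forward_pod(model, batch)
    lg <- periopod:::loss_and_grad(fw$logit, y, loss = "focal",
                                   gamma = 2, alpha = 0.3)
    an <- periopod:::backward_pod(model, batch, fw$cache, lg$grad)
    ng <- nn_num_grad(f, model$params)
    rel <- max(abs(nn_flatten(an, ng$idx) - ng$g)) /
      max(1e-8, max(abs(ng$g)))
    expect_lt(rel, 1e-6)
  }
})

test_that("hybrid backprop matches finite differences and reaches both branches", {
  set.seed(43)
  B <- 3; n <- 4; k <- 2
  y <- c(0, 1, 0)
  batch <- list(seq = array(rnorm(B * n * k), c(B, n, k)),
                tab = matrix(rnorm(B * 3), B, 3))
  seq_cfg <- model_config("LSTM_SEQ", lstm_hidden = 3, head_neurons = 3,
                          seed = 2)
  mlp_cfg <- model_config("MLP_TAB_P", mlp_neurons_per_layer = 4, seed = 2)
  model <- build_hybrid(seq_cfg, mlp_cfg, list(k = k, n = n, p = 3))
  f <- function(params) {
    m <- model; m$params <- params
    fw <- periopod:::forward_pod(m, batch)
    periopod:::loss_and_grad(fw$logit, y, loss = "weighted_ce",
                             pos_weight = 2)$value
  }
  fw <- periopod:::forward_pod(model, batch)
  lg <- periopod:::loss_and_grad(fw$logit, y, loss = "weighted_ce",
                                 pos_weight = 2)
  an <- periopod:::backward_pod(model, batch, fw$cache, lg$grad)
  ng <- nn_num_grad(f, model$params)
  av <- nn_flatten(an, ng$idx)
  expect_lt(max(abs(av - ng$g)) / max(abs(ng$g)), 1e-6)
  # gradient flows into both branches
  count_nonzero <- function(g) sum(abs(nn_flatten(g, nn_flat_idx(g))) > 1e-12)
  expect_gt(count_nonzero(an$seq_branch), 0)
  expect_gt(count_nonzero(an$tab_branch), 0)
})

test_that("hybrid combiner projections isolate each branch", {
  set.seed(44)
  B <- 4; n <- 4; k <- 2
  batch <- list(seq = array(rnorm(B * n * k), c(B, n, k)),
                tab = matrix(rnorm(B * 3), B, 3))
  seq_cfg <- model_config("TRAN_SEQ", tran_linear_dim = 6, tran_ff_dim = 8,
                          head_neurons = 3, seed = 2)
  mlp_cfg <- model_config("MLP_TAB_P", mlp_neurons_per_layer = 4, seed = 2)
  model <- build_hybrid(seq_cfg, mlp_cfg, list(k = k, n = n, p = 3))
  fw <- periopod:::forward_pod(model, batch)
  m1 <- model; m1$params$comb <- list(w = c(1, 0), b = 0)
  expect_equal(predict(m1, batch),
               periopod:::sigmoid(fw$cache$seq$logit), tolerance = 1e-12)
  m2 <- model; m2$params$comb <- list(w = c(0, 1), b = 0)
  expect_equal(predict(m2, batch),
               periopod:::sigmoid(fw$cache$tab$logit), tolerance = 1e-12)
})

test_that("models emit one in-range score per surgery, deterministically", {
  td <- toy_seq_data(m = 8)
  for (v in c("MLP_TAB_P", "LSTM_SEQ", "TRAN_SEQ")) {
    cfg <- model_config(v, tran_linear_dim = 8, tran_ff_dim = 8,
                        lstm_hidden = 4, mlp_neurons_per_layer = 4,
                        head_neurons = 3, seed = 1)
    shape <- if (v == "MLP_TAB_P") list(p = 6) else list(k = 2, n = 6)
    model <- build_model(cfg, shape)
    x <- if (v == "MLP_TAB_P") matrix(rnorm(8 * 6), 8, 6) else td$X
    s1 <- predict(model, x)
    expect_length(s1, 8)
    expect_true(all(s1 >= 0 & s1 <= 1))
    expect_identical(predict(model, x), s1)
  }
})

test_that("shape mismatches are reported with the offending channel count", {
  model <- build_model(model_config("LSTM_SEQ", seed = 1), list(k = 3, n = 5))
  bad <- array(0, c(2, 5, 4))
  expect_error(predict(model, list(seq = bad)), "4 channels.*expects 3")
})

test_that("attention rows are softmax-normalized and saliency behaves", {
  td <- toy_seq_data(m = 6)
  cfg <- model_config("TRAN_SEQ", tran_linear_dim = 8, tran_ff_dim = 8,
                      head_neurons = 3, seed = 2)
  model <- build_model(cfg, list(k = 2, n = 6))
  tens <- seq_tensor(aperm(td$X, c(1, 3, 2)), array(0, c(6, 2, 6)),
                     c("a", "b"), paste0("s", 1:6), 3)
  fw <- periopod:::forward_pod(model, list(seq = td$X), keep_attention = TRUE)
  for (b in 1:6) {
    expect_equal(rowSums(matrix(fw$attention[b, , ], 6, 6)), rep(1, 6),
                 tolerance = 1e-6)
  }
  am <- extract_attention(model, tens)
  expect_true(all(am$saliency >= 0))
  expect_equal(sum(am$time_profile), 1, tolerance = 1e-6)
  # jointly permuting input channels and projection rows leaves the network
  # unchanged, so the saliency rows permute with the channels
  m2 <- model
  m2$params$tran$proj$W <- model$params$tran$proj$W[c(2, 1), ]
  tens2 <- seq_tensor(tens$values[, c(2, 1), , drop = FALSE],
                      tens$mask[, c(2, 1), , drop = FALSE],
                      c("b", "a"), tens$surgery_ids, 3)
  am2 <- extract_attention(m2, tens2)
  expect_equal(unname(am2$saliency), unname(am$saliency[c(2, 1), ]),
               tolerance = 1e-9)
  expect_error(extract_attention(build_model(model_config("MLP_TAB_P"),
                                             list(p = 3)), tens),
               "transformer")
})

test_that("parameter counts are pure functions of the configuration", {
  cfg <- model_config("TRAN_SEQ", tran_linear_dim = 8, tran_ff_dim = 16,
                      tran_encoder_layers = 2, head_neurons = c(4, 2),
                      seed = 1)
  m1 <- build_model(cfg, list(k = 3, n = 5))
  cfg2 <- cfg; cfg2$seed <- 99L
  m2 <- build_model(cfg2, list(k = 3, n = 5))
  expect_identical(describe_model(m1), describe_model(m2))
  d <- 8
  expect_equal(unname(describe_model(m1)["tran"]),
               (3 * d + d) + 2 * (4 * (d * d + d) + 2 * d +
                                    d * 16 + 16 + 16 * d + d + 2 * d))
})

test_that("every variant can overfit a small separable set", {
  td <- toy_seq_data(m = 50, n = 6, k = 2)
  tens_vals <- aperm(td$X, c(1, 3, 2))
  tens <- seq_tensor(tens_vals, array(0, dim(tens_vals)), c("a", "b"),
                     paste0("s", 1:50), 3)
  for (v in c("MLP_TAB_P", "LSTM_SEQ", "TRAN_SEQ")) {
    cfg <- model_config(v, learning_rate = 3e-2, batch_size = 16,
                        max_epochs = 200, patience = 200,
                        tran_linear_dim = 8, tran_ff_dim = 8,
                        lstm_hidden = 6, mlp_neurons_per_layer = c(8, 4),
                        head_neurons = 4, seed = 3)
    x <- if (v == "MLP_TAB_P") tab_p(tens) else td$X
    model <- build_model(cfg, if (v == "MLP_TAB_P") list(p = ncol(x))
                         else list(k = 2, n = 6))
    fit <- train_with_early_stopping(model, x, td$y, x, td$y)
    expect_gt(auroc(predict(fit, x), td$y), 0.95)
  }
})
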