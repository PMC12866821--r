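test_that("conv layer parameter counts match the closed form", {
  m <- build_model(model_config(), input_dim = 32)
  counts <- count_parameters(m)
  convs <- which(names(counts) == "conv")
  expect_identical(unname(counts[convs[1]]), 3L * 1L * 32L + 32L)    # 128
  expect_identical(unname(counts[convs[2]]), 3L * 32L * 64L + 64L)   # 6208
  # dense head is 10-wide
  last <- m$layers[[length(m$layers)]]
  expect_identical(last$nout, 10L)
  # total equals the closed-form sum over the stack
  len <- 32 - 3 + 1; len <- len %/% 2; len <- len - 3 + 1; len <- len %/% 2
  flat <- len * 64
  expect_equal(sum(counts),
               128 + 6208 + (flat * 128 + 128) + (128 * 10 + 10))
})

test_that("inputs shorter than the kernel are rejected", {
  expect_error(build_model(model_config(), input_dim = 2), "kernel")
  # long enough for conv1 but not conv2 after pooling
  expect_error(build_model(model_config(), input_dim = 4), "kernel")
})

test_that("joint loss collapses to MSE at alpha = 1", {
  P <- withr::with_seed(2, matrix(rnorm(50), 5))
  T_ <- withr::with_seed(3, matrix(rnorm(50), 5))
  expect_identical(joint_loss(P, T_, alpha = 1), mean((P - T_)^2))
})

test_that("joint loss closed forms: perfect null and perfect ideal", {
  null <- matrix(0, 1, 10)
  expect_equal(joint_loss(null, null, alpha = 0.7), 0.15, tolerance = 1e-12)
  # perfect ideal profile: score 100, term 1 - sigma(1)
  ideal <- matrix(ideal_delta(1), 1)
  got <- joint_loss(ideal, ideal, alpha = 0.7)
  expect_lt(abs(got - 0.3 * (1 - 1 / (1 + exp(-1)))), 1e-9)
  # the soft training surrogate converges to the hard loss on zero-free
  # profiles as the temperature grows
  P <- withr::with_seed(9, matrix(runif(30, -2, -0.1) * sample(c(-1, 1), 30, TRUE), 3))
  T_ <- matrix(0, 3, 10)
  expect_equal(joint_loss(P, T_, score = "soft", temperature = 1e5),
               joint_loss(P, T_, score = "hard"), tolerance = 1e-6)
  # where they must disagree: the all-zero profile (surrogate sits at 50)
  expect_equal(joint_loss(null, null, score = "soft"),
               0.7 * 0 + 0.3 * (1 - 1 / (1 + exp(-0.5))), tolerance = 1e-12)
})

test_that("joint loss is nonnegative and decreases with soft score at fixed MSE", {
  T_ <- matrix(0, 4, 10)
  a <- 0.8
  low <- matrix(rep(c(-a, a), each = 5), 4, 10, byrow = TRUE)   # worst directions
  high <- matrix(ideal_delta(a), 4, 10, byrow = TRUE)           # best directions
  expect_equal(mean((low - T_)^2), mean((high - T_)^2))
  expect_lt(joint_loss(high, T_), joint_loss(low, T_))
  for (i in 1:10) {
    P <- withr::with_seed(i, matrix(rnorm(40, sd = 2), 4))
    expect_gte(joint_loss(P, T_), 0)
  }
  expect_error(joint_loss(matrix(0, 2, 10), matrix(0, 3, 10)), "shapes")
})

test_that("analytic joint gradient agrees with finite differences", {
  P <- withr::with_seed(5, matrix(rnorm(30), 3))
  T_ <- withr::with_seed(6, matrix(rnorm(30), 3))
  g <- vdlin:::joint_grad(P, T_, 0.7, 10, default_panel())
  for (k in c(1, 7, 15, 30)) {
    e <- P * 0; e[k] <- 1e-6
    fd <- (joint_loss(P + e, T_, score = "soft") -
             joint_loss(P - e, T_, score = "soft")) / 2e-6
    expect_equal(g[k], fd, tolerance = 1e-5)
  }
})

test_that("training reduces the loss on the planted task and is deterministic", {
  lib <- make_library(n = 150, seed = 41)
  prof <- profile_library(lib, min_replicates = 1)
  # cheap structural features: rule-frequency counts
  g <- smiles_grammar()
  X <- t(vapply(lib_smiles(lib), function(s) {
    tabulate(parse_to_rule_sequence(s, g), nbins = g$vocabulary_size)
  }, integer(g$vocabulary_size)))
  cfg <- model_config(epochs = 15, batch_size = 32, seed = 7)
  m1 <- train_model(build_model(cfg, ncol(X)), X, prof$delta)
  expect_lt(utils::tail(m1$history$loss, 1), m1$history$loss[1])
  expect_identical(names(m1$history), c("epoch", "loss", "mse_term", "score_term"))
  m2 <- train_model(build_model(cfg, ncol(X)), X, prof$delta)
  expect_identical(m1$params, m2$params)
})

test_that("prediction is deterministic with the documented classification view", {
  lib <- make_library(n = 80, seed = 43)
  prof <- profile_library(lib, min_replicates = 1)
  g <- smiles_grammar()
  X <- t(vapply(lib_smiles(lib), function(s) {
    tabulate(parse_to_rule_sequence(s, g), nbins = g$vocabulary_size)
  }, integer(g$vocabulary_size)))
  cfg <- model_config(epochs = 8, batch_size = 32, seed = 2)
  m <- train_model(build_model(cfg, ncol(X)), X, prof$delta)
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1$predicted_delta, p2$predicted_delta)
  expect_true(all(p1$desired_effect_prob > 0 & p1$desired_effect_prob < 1))
  # independent re-application of sigma(beta * dir * delta)
  dir <- matrix(as.numeric(panel_directions(default_panel())), nrow(X), 10,
                byrow = TRUE)
  manual <- 1 / (1 + exp(-10 * dir * p1$predicted_delta))
  expect_equal(unname(p1$desired_effect_prob), unname(manual), tolerance = 1e-12)
  expect_error(predict(m, X[, 1:5]), "features")
  expect_error(predict(build_model(cfg, ncol(X)), X), "trained")
})

test_that("train_model validates shapes and batch size", {
  X <- matrix(rnorm(40), 4)
  expect_error(train_model(build_model(model_config(), 10), X, matrix(0, 3, 10)),
               "\\|X\\| != \\|Y\\|")
  expect_error(train_model(build_model(model_config(), 12), X, matrix(0, 4, 10)),
               "features|expects")
})

test_that("spherical-latent variant trains and predicts deterministically", {
  lib <- make_library(n = 60, seed = 47)
  prof <- profile_library(lib, min_replicates = 1)
  X <- withr::with_seed(1, matrix(rnorm(60 * 24), 60))
  cfg <- model_config(architecture_variant = "spherical_latent", epochs = 5,
                      batch_size = 32, seed = 9)
  m <- build_model(cfg, 24)
  expect_identical(sum(vapply(m$layers, function(l) l$type == "conv", logical(1))), 3L)
  expect_identical(sum(vapply(m$layers, function(l) l$type == "gauss", logical(1))), 1L)
  m <- train_model(m, X, prof$delta[1:60, ])
  expect_lt(utils::tail(m$history$loss, 1), Inf)
  expect_identical(predict(m, X)$predicted_delta, predict(m, X)$predicted_delta)
})

test_that("bce loss mode trains", {
  lib <- make_library(n = 60, seed = 49)
  prof <- profile_library(lib, min_replicates = 1)
  X <- withr::with_seed(2, matrix(rnorm(60 * 16), 60))
  cfg <- model_config(loss_mode = "bce", epochs = 6, batch_size = 32, seed = 3)
  m <- train_model(build_model(cfg, 16), X, prof$delta)
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
})

test_that("models round-trip through the text save format", {
  lib <- make_library(n = 50, seed = 53)
  prof <- profile_library(lib, min_replicates = 1)
  X <- withr::with_seed(3, matrix(rnorm(50 * 16), 50))
  cfg <- model_config(epochs = 4, batch_size = 25, seed = 5)
  m <- train_model(build_model(cfg, 16), X, prof$delta)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(predict(m2, X)$predicted_delta, predict(m, X)$predicted_delta,
               tolerance = 1e-12)
})
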