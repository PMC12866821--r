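# VAE fitting and latent encoding

small_vae_cfg <- function(...) {
  args <- utils::modifyList(
    list(latent_dim = 8, hidden = 32, epochs = 25, batch_size = 16, seed = 5),
    list(...))
  do.call(vae_config, args)
}

test_that("reconstruction improves on a tiny dataset with ample capacity", {
  g <- smiles_grammar(max_sequence_length = 24)
  oh <- one_hot_matrix(c("CCO", "c1ccccc1", "CC(C)Cl"), g)
  vae <- fit_vae(oh, vae_config(latent_dim = 16, hidden = 64, kl_weight = 0,
                                epochs = 40, batch_size = 3, seed = 1))
  expect_lt(tail(vae$history$recon, 1), vae$history$recon[1])
})

test_that("fitting is deterministic under a fixed seed", {
  g <- smiles_grammar(max_sequence_length = 24)
  oh <- one_hot_matrix(c("CCO", "c1ccccc1", "CC(C)Cl", "CCCN"), g)
  v1 <- fit_vae(oh, small_vae_cfg())
  v2 <- fit_vae(oh, small_vae_cfg())
  expect_identical(v1$params, v2$params)
  expect_identical(encode_latent(v1, oh), encode_latent(v2, oh))
})

test_that("latent vectors are the mean head: repeatable, right length", {
  g <- smiles_grammar(max_sequence_length = 24)
  oh <- one_hot_matrix(c("CCO", "c1ccccc1", "CCCN"), g)
  vae <- fit_vae(oh, small_vae_cfg())
  z1 <- encode_latent(vae, oh)
  expect_identical(dim(z1), c(3L, 8L))
  expect_identical(z1, encode_latent(vae, oh))
  # single one-hot matrix in, vector out
  single <- one_hot(parse_to_rule_sequence("CCO", g), g)
  zv <- encode_latent(vae, single)
  expect_length(zv, 8)
  expect_equal(zv, unname(z1[1, ]))
  # identical molecules -> identical latents
  expect_equal(encode_latent(vae, one_hot_matrix(c("CCO", "CCO"), g))[1, ],
               encode_latent(vae, one_hot_matrix(c("CCO", "CCO"), g))[2, ])
})

test_that("latents match a manual forward-pass oracle", {
  g <- smiles_grammar(max_sequence_length = 24)
  oh <- one_hot_matrix(c("CCO", "c1ccccc1", "CCCN"), g)
  vae <- fit_vae(oh, small_vae_cfg())
  p <- vae$params
  manual <- pmax(oh %*% p$W1 + matrix(p$b1, 3, length(p$b1), byrow = TRUE), 0)
  manual <- manual %*% p$Wmu + matrix(p$bmu, 3, length(p$bmu), byrow = TRUE)
  expect_equal(unname(encode_latent(vae, oh)), unname(manual), tolerance = 1e-12)
})

test_that("errors: unfitted encoder, shape mismatch, too-few encodings", {
  g <- smiles_grammar(max_sequence_length = 24)
  oh <- one_hot_matrix(c("CCO", "CCCN"), g)
  vae <- fit_vae(oh, small_vae_cfg(epochs = 2))
  fake <- unclass(vae)
  expect_error(encode_latent(fake, oh), "fitted")
  expect_error(encode_latent(vae, oh[, 1:10]), "features")
  expect_error(fit_vae(oh[1, , drop = FALSE], small_vae_cfg()), "at least 2")
  g2 <- smiles_grammar(max_sequence_length = 30)
  mixed <- list(one_hot(parse_to_rule_sequence("C", g), g),
                one_hot(parse_to_rule_sequence("C", g2), g2))
  expect_error(fit_vae(mixed, small_vae_cfg()), "shape")
})

test_that("a linear probe on the latents recovers the planted marker", {
  lib <- make_library(n = 200, seed = 23)
  g <- smiles_grammar()
  oh <- one_hot_matrix(lib_smiles(lib), g)
  vae <- fit_vae(oh, vae_config(latent_dim = 16, hidden = 64, epochs = 15,
                                seed = 3))
  z <- encode_latent(vae, oh)
  act <- lib_active(lib)
  # train the probe on half, evaluate on the other half
  tr <- seq_len(100)
  fit <- glmnet::glmnet(z[tr, ], factor(act[tr]), family = "binomial",
                        lambda = 0.01)
  pred <- as.numeric(predict(fit, z[-tr, ], type = "response")) > 0.5
  expect_gt(mean(pred == act[-tr]), 0.8)
})
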