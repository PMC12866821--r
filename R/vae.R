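#' Variational autoencoder configuration
#'
#' The VAE compresses flattened grammar one-hot arrays into fixed-length
#' latent vectors, the model input X. Architecture: a symmetric dense
#' encoder/decoder over the flattened one-hot (encoder hidden ReLU layer,
#' Gaussian latent with diagonal covariance, decoder hidden ReLU layer,
#' Bernoulli output), trained with Adam on reconstruction cross-entropy
#' plus a KL term whose weight is linearly annealed from 0 over
#' `kl_anneal_epochs`.
#'
#' @param latent_dim latent dimensionality (default 64).
#' @param hidden width of the encoder/decoder hidden layer (default 128).
#' @param kl_weight final KL weight after annealing (>= 0, default 1e-3; the
#'   small default keeps the latent informative for downstream regression
#'   rather than strongly regularized).
#' @param kl_anneal_epochs epochs over which the KL weight ramps up.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed integer seed; fitting is deterministic given the seed.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 64L, hidden = 128L, kl_weight = 1e-3,
                       kl_anneal_epochs = 10L, epochs = 30L, batch_size = 64L,
                       learning_rate = 1e-3, seed = 1L) {
  latent_dim <- check_scalar_count(latent_dim, "latent_dim")
  hidden <- check_scalar_count(hidden, "hidden")
  if (!is.numeric(kl_weight) || kl_weight < 0) {
    stop("vae_config: `kl_weight` must be >= 0", call. = FALSE)
  }
  structure(list(latent_dim = latent_dim, hidden = hidden,
                 kl_weight = kl_weight,
                 kl_anneal_epochs = check_scalar_count(kl_anneal_epochs, "kl_anneal_epochs", 0L),
                 epochs = check_scalar_count(epochs, "epochs"),
                 batch_size = check_scalar_count(batch_size, "batch_size"),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "vae_config")
}

# accept a list of one-hot matrices or an already-flattened numeric matrix
flatten_encodings <- function(encodings) {
  if (is.matrix(encodings) && is.numeric(encodings)) return(encodings)
  if (!is.list(encodings) || length(encodings) == 0L) {
    stop("fit_vae: `encodings` must be a non-empty list of one-hot matrices or a numeric matrix",
         call. = FALSE)
  }
  dims <- unique(lapply(encodings, dim))
  if (length(dims) != 1L) {
    stop("fit_vae: all encodings must share the same shape", call. = FALSE)
  }
  t(vapply(encodings, function(m) as.numeric(m), numeric(prod(dims[[1L]]))))
}

#' Fit the variational autoencoder
#'
#' @param encodings list of one-hot matrices (from [one_hot()]) or a
#'   flattened `n x D` numeric matrix (from [one_hot_matrix()]); at least 2
#'   rows.
#' @param config a [vae_config()].
#' @return object of class `vdlin_vae`: fitted weights, config, `input_dim`
#'   and a training `history` data.frame (`epoch`, `recon`, `kl`, `loss`).
#' @export
fit_vae <- function(encodings, config = vae_config()) {
  x <- flatten_encodings(encodings)
  if (nrow(x) < 2L) stop("fit_vae: at least 2 encodings required", call. = FALSE)
  D <- ncol(x)
  H <- config$hidden
  Z <- config$latent_dim
  n <- nrow(x)
  bs <- min(config$batch_size, n)

  with_seed(config$seed, {
    params <- list(
      W1 = he_init(D, H), b1 = numeric(H),
      Wmu = he_init(H, Z), bmu = numeric(Z),
      Wlv = he_init(H, Z) * 0.01, blv = numeric(Z),
      W3 = he_init(Z, H), b3 = numeric(H),
      W4 = he_init(H, D), b4 = numeric(D)
    )
    opt <- adam_new(params)
    history <- data.frame(epoch = integer(0), recon = numeric(0),
                          kl = numeric(0), loss = numeric(0))

    for (epoch in seq_len(config$epochs)) {
      kl_w <- if (config$kl_anneal_epochs > 0L) {
        config$kl_weight * min(1, epoch / config$kl_anneal_epochs)
      } else config$kl_weight
      ord <- sample.int(n)
      ep_recon <- 0; ep_kl <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        m <- nrow(xb)

        h <- relu(dense_forward(xb, params$W1, params$b1))
        mu <- dense_forward(h, params$Wmu, params$bmu)
        lv <- dense_forward(h, params$Wlv, params$blv)
        lv <- pmin(pmax(lv, -10), 10)
        eps <- matrix(stats::rnorm(m * Z), m, Z)
        z <- mu + exp(lv / 2) * eps
        h2 <- relu(dense_forward(z, params$W3, params$b3))
        logits <- dense_forward(h2, params$W4, params$b4)
        p <- logistic(logits)

        # per-sample summed BCE, averaged over the batch
        recon <- -sum(xb * log(p + 1e-12) + (1 - xb) * log(1 - p + 1e-12)) / m
        kl <- 0.5 * sum(exp(lv) + mu^2 - 1 - lv) / m
        ep_recon <- ep_recon + recon * m
        ep_kl <- ep_kl + kl * m

        g_logits <- (p - xb) / m
        d4 <- dense_backward(g_logits, h2, params$W4)
        g_h2 <- d4$grad_in * (h2 > 0)
        d3 <- dense_backward(g_h2, z, params$W3)
        g_z <- d3$grad_in
        g_mu <- g_z + kl_w * mu / m
        g_lv <- g_z * eps * exp(lv / 2) / 2 + kl_w * 0.5 * (exp(lv) - 1) / m
        dmu <- dense_backward(g_mu, h, params$Wmu)
        dlv <- dense_backward(g_lv, h, params$Wlv)
        g_h <- (dmu$grad_in + dlv$grad_in) * (h > 0)
        d1 <- dense_backward(g_h, xb, params$W1)

        grads <- list(W1 = d1$gW, b1 = d1$gb,
                      Wmu = dmu$gW, bmu = dmu$gb,
                      Wlv = dlv$gW, blv = dlv$gb,
                      W3 = d3$gW, b3 = d3$gb,
                      W4 = d4$gW, b4 = d4$gb)
        upd <- adam_step(opt, params, grads, config$learning_rate)
        opt <- upd$state
        params <- upd$params
      }
      history <- rbind(history, data.frame(
        epoch = epoch, recon = ep_recon / n, kl = ep_kl / n,
        loss = ep_recon / n + kl_w * ep_kl / n))
    }
    structure(list(params = params, config = config, input_dim = D,
                   history = history, fitted = TRUE),
              class = "vdlin_vae")
  })
}

#' @export
print.vdlin_vae <- function(x, ...) {
  cat(sprintf("<vdlin_vae> %d -> %d -> %d latent, %d epochs (final recon %.2f)\n",
              x$input_dim, x$config$hidden, x$config$latent_dim,
              nrow(x$history), utils::tail(x$history$recon, 1)))
  invisible(x)
}

#' Encode one-hot arrays to latent vectors
#'
#' Returns the latent *mean* vector (never a sample), so downstream
#' screening is reproducible: encoding the same molecule twice gives the
#' identical vector.
#'
#' @param encoder a fitted [fit_vae()] object.
#' @param encoding a single one-hot matrix, or an `n x D` flattened matrix.
#' @return a latent vector (single input) or an `n x latent_dim` matrix.
#' @export
encode_latent <- function(encoder, encoding) {
  if (!inherits(encoder, "vdlin_vae") || !isTRUE(encoder$fitted)) {
    stop("encode_latent: `encoder` is not a fitted vdlin_vae", call. = FALSE)
  }
  if (!is.matrix(encoding)) encoding <- matrix(as.numeric(encoding), 1L)
  single <- ncol(encoding) != encoder$input_dim || nrow(encoding) == 1L
  x <- if (ncol(encoding) != encoder$input_dim) {
    matrix(as.numeric(encoding), 1L)
  } else encoding
  if (ncol(x) != encoder$input_dim) {
    stop(sprintf("encode_latent: input has %d features, encoder expects %d",
                 ncol(x), encoder$input_dim), call. = FALSE)
  }
  h <- relu(dense_forward(x, encoder$params$W1, encoder$params$b1))
  mu <- dense_forward(h, encoder$params$Wmu, encoder$params$bmu)
  if (single) as.numeric(mu) else mu
}

#' Encode a set of SMILES end-to-end
#'
#' Parse + one-hot + latent-mean encode in one call.
#'
#' @param encoder a fitted [fit_vae()] object.
#' @param smiles character vector of SMILES.
#' @param grammar the [smiles_grammar()] the encoder was trained on.
#' @return `n x latent_dim` latent matrix.
#' @export
encode_smiles <- function(encoder, smiles, grammar = smiles_grammar()) {
  encode_latent(encoder, one_hot_matrix(smiles, grammar))
}
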