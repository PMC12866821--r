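# Internal neural-network primitives: layer forward/backward passes and the
# Adam optimizer. Everything operates on plain base-R matrices/arrays; 1D
# convolutions are reduced to GEMM via im2col so the heavy lifting stays in
# BLAS.

relu <- function(x) pmax(x, 0)

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# He-scaled Gaussian init (draws from the current RNG stream)
he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# ---- conv1d (valid padding, stride 1) --------------------------------------

# x: n x L x Cin array -> im2col matrix (n*Lout) x (k*Cin)
im2col <- function(x, k) {
  d <- dim(x)
  n <- d[1L]; L <- d[2L]; cin <- d[3L]
  lout <- L - k + 1L
  m <- matrix(0, n * lout, k * cin)
  for (j in seq_len(k)) {
    slab <- x[, j:(j + lout - 1L), , drop = FALSE]
    m[, ((j - 1L) * cin + 1L):(j * cin)] <- matrix(slab, n * lout, cin)
  }
  m
}

# W: (k*Cin) x Cout, b: Cout
conv1d_forward <- function(x, W, b, k) {
  d <- dim(x)
  n <- d[1L]; L <- d[2L]; cin <- d[3L]
  lout <- L - k + 1L
  m <- im2col(x, k)
  out <- sweep(m %*% W, 2L, b, `+`)
  list(out = array(out, c(n, lout, ncol(W))), cache = list(m = m, dims = d, k = k))
}

conv1d_backward <- function(grad_out, W, cache) {
  d <- cache$dims
  n <- d[1L]; L <- d[2L]; cin <- d[3L]
  k <- cache$k
  lout <- L - k + 1L
  G <- matrix(grad_out, n * lout, dim(grad_out)[3L])
  gW <- crossprod(cache$m, G)
  gb <- colSums(G)
  gM <- tcrossprod(G, W)   # (n*lout) x (k*cin)
  gx <- array(0, d)
  for (j in seq_len(k)) {
    gx[, j:(j + lout - 1L), ] <- gx[, j:(j + lout - 1L), , drop = FALSE] +
      array(gM[, ((j - 1L) * cin + 1L):(j * cin)], c(n, lout, cin))
  }
  list(grad_in = gx, gW = gW, gb = gb)
}

# ---- max pooling (size 2, stride 2; odd tail dropped) ----------------------

maxpool_forward <- function(x) {
  d <- dim(x)
  lout <- d[2L] %/% 2L
  a <- x[, seq(1L, 2L * lout, by = 2L), , drop = FALSE]
  b <- x[, seq(2L, 2L * lout, by = 2L), , drop = FALSE]
  first <- a >= b
  list(out = ifelse(first, a, b), cache = list(first = first, dims = d, lout = lout))
}

maxpool_backward <- function(grad_out, cache) {
  d <- cache$dims
  lout <- cache$lout
  gx <- array(0, d)
  gx[, seq(1L, 2L * lout, by = 2L), ] <- grad_out * cache$first
  gx[, seq(2L, 2L * lout, by = 2L), ] <- grad_out * !cache$first
  gx
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(x, W, b) sweep(x %*% W, 2L, b, `+`)

dense_backward <- function(grad_out, x, W) {
  list(grad_in = tcrossprod(grad_out, W),
       gW = crossprod(x, grad_out),
       gb = colSums(grad_out))
}
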