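# Five conventional ML baselines behind a single fit/predict API. The tree
# ensembles are backed by a small CART regression-tree builder (variance
# splitting, which for 0/1 targets coincides with Gini); kNN supports both
# euclidean and manhattan metrics; the RBF/linear SVM is trained with the
# Pegasos stochastic subgradient method on the precomputed kernel matrix;
# logistic regression is delegated to glmnet (penalty l1/l2 <-> alpha 1/0,
# C <-> 1/(n*lambda)).

#' Baseline model families and their hyperparameter search spaces
#'
#' Returns the family name plus the search space used by [tune_model()]:
#' random forest `n_estimators` 50-200, `max_depth` 2-15,
#' `min_samples_split` 2-10; gradient boosting `learning_rate` 0.01-0.3,
#' `max_depth` 2-8, `subsample` 0.6-1.0; logistic `C` 0.01-10 (log-uniform),
#' `penalty` l1/l2; kNN `n_neighbors` 1-15, `metric`
#' euclidean/manhattan; SVM `C` 0.1-10, `gamma` 0.01-1, `kernel`
#' linear/rbf.
#'
#' @param family one of `"svm_rbf"`, `"knn"`, `"logistic"`,
#'   `"random_forest"`, `"gradient_boosting"`.
#' @return object of class `baseline_spec` with `family` and `search_space`
#'   (see [param_real()] etc.).
#' @export
baseline_spec <- function(family = c("svm_rbf", "knn", "logistic",
                                     "random_forest", "gradient_boosting")) {
  family <- match.arg(family)
  space <- switch(family,
    random_forest = list(
      param_integer("n_estimators", 50L, 200L),
      param_integer("max_depth", 2L, 15L),
      param_integer("min_samples_split", 2L, 10L)),
    gradient_boosting = list(
      param_real("learning_rate", 0.01, 0.3, log = TRUE),
      param_integer("max_depth", 2L, 8L),
      param_real("subsample", 0.6, 1.0)),
    logistic = list(
      param_real("C", 0.01, 10, log = TRUE),
      param_categorical("penalty", c("l1", "l2"))),
    knn = list(
      param_integer("n_neighbors", 1L, 15L),
      param_categorical("metric", c("euclidean", "manhattan"))),
    svm_rbf = list(
      param_real("C", 0.1, 10),
      param_real("gamma", 0.01, 1),
      param_categorical("kernel", c("linear", "rbf")))
  )
  structure(list(family = family, search_space = space), class = "baseline_spec")
}

baseline_default_params <- function(family, p = NULL) {
  switch(family,
    random_forest = list(n_estimators = 25L, max_depth = 6L, min_samples_split = 2L),
    gradient_boosting = list(learning_rate = 0.1, max_depth = 2L, subsample = 0.8,
                             n_rounds = 40L),
    logistic = list(C = 1, penalty = "l2"),
    knn = list(n_neighbors = 5L, metric = "euclidean"),
    svm_rbf = list(C = 1, gamma = if (is.null(p)) 0.1 else 1 / p, kernel = "rbf"),
    stop(sprintf("unknown baseline family '%s'", family), call. = FALSE)
  )
}

#' Fit / score a baseline classifier
#'
#' @param family baseline family (see [baseline_spec()]).
#' @param X numeric feature matrix (n x p).
#' @param y binary labels (0/1), length n.
#' @param params named list of hyperparameters (missing entries take
#'   defaults).
#' @param seed integer seed for the stochastic families.
#' @return object of class `baseline_fit`; score new data with
#'   [predict_baseline()] (returns probability-like scores in `[0, 1]`).
#' @export
fit_baseline <- function(family, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  defaults <- baseline_default_params(family, ncol(X))
  params <- utils::modifyList(defaults, params)
  if (length(unique(y)) < 2L) {
    return(structure(list(family = family, constant = mean(y)), class = "baseline_fit"))
  }
  fit <- with_seed(seed, switch(family,
    random_forest = fit_rf(X, y, params),
    gradient_boosting = fit_gb(X, y, params),
    logistic = fit_logistic(X, y, params),
    knn = list(X = X, y = y, params = params),
    svm_rbf = fit_svm(X, y, params)
  ))
  structure(c(fit, list(family = family)), class = "baseline_fit")
}

#' @rdname fit_baseline
#' @param object a `baseline_fit`.
#' @export
predict_baseline <- function(object, X) {
  X <- as.matrix(X)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(X)))
  switch(object$family,
    random_forest = predict_rf(object, X),
    gradient_boosting = predict_gb(object, X),
    logistic = predict_logistic(object, X),
    knn = knn_score(object$X, object$y, X, object$params$n_neighbors,
                    object$params$metric),
    svm_rbf = predict_svm(object, X)
  )
}

# ---- CART regression tree (variance splitting) -----------------------------

# returns a flat data.frame of nodes: feature (0 = leaf), threshold, left,
# right (node ids), value (leaf mean)
cart_tree <- function(X, y, max_depth = 6L, min_samples_split = 2L, mtry = ncol(X)) {
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(feature = 0L, threshold = NA_real_, left = 0L,
                         right = 0L, value = mean(y[idx]))
    if (depth >= max_depth || length(idx) < min_samples_split ||
        length(unique(y[idx])) < 2L) {
      return(id)
    }
    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- list(gain = 0)
    ytot <- sum(y[idx]); n <- length(idx)
    base <- ytot^2 / n
    for (j in feats) {
      xj <- X[idx, j]
      ord <- order(xj)
      xs <- xj[ord]; ys <- y[idx][ord]
      cs <- cumsum(ys)
      nl <- seq_len(n - 1L)
      valid <- xs[-n] != xs[-1L]
      if (!any(valid)) next
      gain <- cs[nl]^2 / nl + (ytot - cs[nl])^2 / (n - nl) - base
      gain[!valid] <- -Inf
      k <- which.max(gain)
      if (gain[k] > best$gain + 1e-12) {
        best <- list(gain = gain[k], feature = j,
                     threshold = (xs[k] + xs[k + 1L]) / 2)
      }
    }
    if (best$gain <= 0) return(id)
    mask <- X[idx, best$feature] <= best$threshold
    l <- grow(idx[mask], depth + 1L)
    r <- grow(idx[!mask], depth + 1L)
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- r
    id
  }
  grow(seq_along(y), 0L)
  nodes
}

predict_cart <- function(nodes, X) {
  out <- numeric(nrow(X))
  descend <- function(id, idx) {
    nd <- nodes[[id]]
    if (nd$feature == 0L) {
      out[idx] <<- nd$value
      return(invisible(NULL))
    }
    mask <- X[idx, nd$feature] <= nd$threshold
    if (any(mask)) descend(nd$left, idx[mask])
    if (any(!mask)) descend(nd$right, idx[!mask])
  }
  if (nrow(X) > 0L) descend(1L, seq_len(nrow(X)))
  out
}

# ---- random forest ---------------------------------------------------------

fit_rf <- function(X, y, params) {
  n <- nrow(X)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(params$n_estimators), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    cart_tree(X[idx, , drop = FALSE], y[idx], max_depth = params$max_depth,
              min_samples_split = params$min_samples_split, mtry = mtry)
  })
  list(trees = trees)
}

predict_rf <- function(object, X) {
  preds <- vapply(object$trees, function(tr) predict_cart(tr, X), numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowMeans(preds)
}

# ---- gradient boosting (logistic loss, pseudo-residual fitting) ------------

fit_gb <- function(X, y, params) {
  n <- nrow(X)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  Fhat <- rep(f0, n)
  trees <- vector("list", params$n_rounds)
  for (t in seq_len(params$n_rounds)) {
    r <- y - logistic(Fhat)
    idx <- if (params$subsample < 1) {
      sample.int(n, max(2L, floor(params$subsample * n)))
    } else seq_len(n)
    tr <- cart_tree(X[idx, , drop = FALSE], r[idx], max_depth = params$max_depth)
    trees[[t]] <- tr
    Fhat <- Fhat + params$learning_rate * predict_cart(tr, X)
  }
  list(f0 = f0, trees = trees, learning_rate = params$learning_rate)
}

predict_gb <- function(object, X) {
  Fhat <- rep(object$f0, nrow(X))
  for (tr in object$trees) {
    Fhat <- Fhat + object$learning_rate * predict_cart(tr, X)
  }
  logistic(Fhat)
}

# ---- logistic regression (glmnet) ------------------------------------------

fit_logistic <- function(X, y, params) {
  lambda <- 1 / (max(params$C, 1e-8) * nrow(X))
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = if (params$penalty == "l1") 1 else 0,
                        lambda = lambda, standardize = TRUE)
  list(fit = fit, lambda = lambda)
}

predict_logistic <- function(object, X) {
  as.numeric(stats::predict(object$fit, X, s = object$lambda, type = "response"))
}

# ---- kNN -------------------------------------------------------------------

knn_score <- function(Xtr, ytr, Xte, k, metric = "euclidean") {
  k <- min(k, nrow(Xtr))
  if (metric == "euclidean") {
    d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), `+`) - 2 * tcrossprod(Xte, Xtr)
    D <- sqrt(pmax(d2, 0))
  } else {
    D <- t(apply(Xte, 1L, function(x) colSums(abs(t(Xtr) - x))))
    if (nrow(Xte) == 1L) D <- matrix(D, 1L)
  }
  apply(D, 1L, function(dr) mean(ytr[order(dr)[seq_len(k)]]))
}

# ---- kernel SVM (Pegasos) --------------------------------------------------

svm_kernel <- function(A, B, params) {
  if (params$kernel == "linear") {
    tcrossprod(A, B)
  } else {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    exp(-params$gamma * pmax(d2, 0))
  }
}

fit_svm <- function(X, y, params, n_epochs = 15L) {
  n <- nrow(X)
  ypm <- ifelse(y > 0.5, 1, -1)
  lambda <- 1 / (max(params$C, 1e-8) * n)
  K <- svm_kernel(X, X, params)
  alpha <- numeric(n)
  T_ <- n_epochs * n
  picks <- sample.int(n, T_, replace = TRUE)
  for (t in seq_len(T_)) {
    i <- picks[t]
    margin <- ypm[i] * sum(alpha * ypm * K[, i]) / (lambda * t)
    if (margin < 1) alpha[i] <- alpha[i] + 1
  }
  list(X = X, ypm = ypm, alpha = alpha, lambda = lambda, T_ = T_, params = params)
}

predict_svm <- function(object, X) {
  Kte <- svm_kernel(X, object$X, object$params)
  f <- Kte %*% (object$alpha * object$ypm) / (object$lambda * object$T_)
  logistic(as.numeric(f))
}
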