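#' Hyperparameter search-space primitives
#'
#' Declare one dimension of a search space: a real interval (optionally
#' log-uniform), an integer range, or a categorical set.
#'
#' @param name parameter name.
#' @param lower,upper interval bounds.
#' @param log if `TRUE`, the dimension is explored on the log scale.
#' @param values categorical levels.
#' @return a `tune_param` list.
#' @export
param_real <- function(name, lower, upper, log = FALSE) {
  stopifnot(upper >= lower, !log || lower > 0)
  structure(list(name = name, type = "real", lower = lower, upper = upper,
                 log = log), class = "tune_param")
}

#' @rdname param_real
#' @export
param_integer <- function(name, lower, upper) {
  stopifnot(upper >= lower)
  structure(list(name = name, type = "integer", lower = as.integer(lower),
                 upper = as.integer(upper), log = FALSE), class = "tune_param")
}

#' @rdname param_real
#' @export
param_categorical <- function(name, values) {
  stopifnot(length(values) >= 1L)
  structure(list(name = name, type = "categorical", values = values),
            class = "tune_param")
}

#' Optimization protocol
#'
#' Budget and evaluation rules of the Bayesian tuner: at most
#' `max_iterations` objective evaluations, early stop after
#' `early_stop_patience` consecutive non-improving evaluations, objective
#' assessed by `cv_folds`-fold cross-validated micro AUC-ROC (early
#' stopping monitors the same scalar, as `1 - AUC` loss).
#'
#' @param max_iterations evaluation budget, default 100.
#' @param early_stop_patience consecutive non-improving evaluations before
#'   stopping, default 20 (must be < `max_iterations`).
#' @param cv_folds cross-validation folds, default 3 (>= 2).
#' @param validation_fraction stratified validation hold-out fraction
#'   recorded in the manifest, default 0.2.
#' @param n_init random evaluations before the GP model kicks in.
#' @param seed integer seed.
#' @return object of class `optimizer_protocol`.
#' @export
optimizer_protocol <- function(max_iterations = 100L, early_stop_patience = 20L,
                               cv_folds = 3L, validation_fraction = 0.2,
                               n_init = 8L, seed = 1L) {
  max_iterations <- check_scalar_count(max_iterations, "max_iterations")
  early_stop_patience <- check_scalar_count(early_stop_patience, "early_stop_patience")
  if (early_stop_patience >= max_iterations) {
    stop("optimizer_protocol: `early_stop_patience` must be < `max_iterations`",
         call. = FALSE)
  }
  cv_folds <- check_scalar_count(cv_folds, "cv_folds", min = 2L)
  structure(list(max_iterations = max_iterations,
                 early_stop_patience = early_stop_patience,
                 cv_folds = cv_folds,
                 validation_fraction = check_proportion(validation_fraction,
                                                        "validation_fraction"),
                 n_init = check_scalar_count(n_init, "n_init"),
                 seed = as.integer(seed)),
            class = "optimizer_protocol")
}

# ---- parameter encoding ----------------------------------------------------

# encode a named param list to the GP's [0,1]^d representation
encode_point <- function(params, space) {
  unlist(lapply(space, function(pm) {
    v <- params[[pm$name]]
    if (pm$type == "categorical") {
      as.numeric(pm$values == v)
    } else {
      lo <- pm$lower; hi <- pm$upper
      if (hi == lo) return(0.5)
      if (isTRUE(pm$log)) (log(v) - log(lo)) / (log(hi) - log(lo))
      else (v - lo) / (hi - lo)
    }
  }))
}

sample_point <- function(space) {
  out <- list()
  for (pm in space) {
    out[[pm$name]] <- switch(pm$type,
      real = {
        u <- stats::runif(1)
        if (isTRUE(pm$log)) exp(log(pm$lower) + u * (log(pm$upper) - log(pm$lower)))
        else pm$lower + u * (pm$upper - pm$lower)
      },
      integer = sample(seq(pm$lower, pm$upper), 1L),
      categorical = sample(pm$values, 1L)
    )
  }
  out
}

space_is_degenerate <- function(space) {
  all(vapply(space, function(pm) {
    if (pm$type == "categorical") length(pm$values) == 1L else pm$upper == pm$lower
  }, logical(1)))
}

#' Gaussian-process Bayesian optimization
#'
#' Maximizes `objective(params)` over the declared space: a short random
#' design, then a Gaussian-process surrogate (RBF kernel on the encoded
#' unit cube) with expected-improvement acquisition maximized over random
#' candidates. Evaluation budget and patience follow the protocol exactly;
#' a degenerate (single-point) space is evaluated once and returned. Every
#' evaluated point lies inside the declared space. Fully seeded.
#'
#' @param space list of [param_real()] / [param_integer()] /
#'   [param_categorical()] dimensions.
#' @param objective function taking a named parameter list, returning a
#'   finite scalar to maximize.
#' @param protocol an [optimizer_protocol()].
#' @return list: `best_params`, `best_value`, `trace` (data.frame with one
#'   row per evaluation: iteration, value, best_so_far, and the parameter
#'   values), `n_evaluations`, `stopped_early`.
#' @export
bayes_optimize <- function(space, objective, protocol = optimizer_protocol()) {
  if (length(space) == 0L) stop("bayes_optimize: empty search space", call. = FALSE)
  with_seed(protocol$seed, {
    evals <- list()
    values <- numeric(0)
    best <- -Inf
    since_improve <- 0L
    stopped_early <- FALSE

    degenerate <- space_is_degenerate(space)
    record <- function(params) {
      v <- objective(params)
      if (!is.finite(v)) v <- -Inf
      evals[[length(evals) + 1L]] <<- params
      values <<- c(values, v)
      if (v > best + 1e-12) {
        best <<- v
        since_improve <<- 0L
      } else {
        since_improve <<- since_improve + 1L
      }
    }

    record(sample_point(space))
    if (!degenerate) {
      while (length(values) < protocol$max_iterations) {
        if (since_improve >= protocol$early_stop_patience) {
          stopped_early <- TRUE
          break
        }
        params <- if (length(values) < protocol$n_init) {
          sample_point(space)
        } else {
          propose_ei(space, evals, values)
        }
        record(params)
      }
      if (!stopped_early && since_improve >= protocol$early_stop_patience) {
        stopped_early <- TRUE
      }
    }

    k <- which.max(values)
    trace <- data.frame(iteration = seq_along(values), value = values,
                        best_so_far = cummax(values))
    for (pm in space) {
      col <- vapply(evals, function(e) as.character(e[[pm$name]]), character(1))
      trace[[pm$name]] <- utils::type.convert(col, as.is = TRUE)
    }
    list(best_params = evals[[k]], best_value = values[k], trace = trace,
         n_evaluations = length(values), stopped_early = stopped_early)
  })
}

# expected-improvement proposal from a simple fixed-hyperparameter GP
propose_ei <- function(space, evals, values, n_candidates = 256L) {
  X <- do.call(rbind, lapply(evals, encode_point, space = space))
  y <- values
  finite <- is.finite(y)
  if (sum(finite) < 2L) return(sample_point(space))
  X <- X[finite, , drop = FALSE]
  y <- y[finite]
  mu0 <- mean(y)
  s2 <- stats::var(y)
  if (!is.finite(s2) || s2 < 1e-12) return(sample_point(space))
  l <- 0.3 * sqrt(ncol(X))
  kfun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    s2 * exp(-pmax(d2, 0) / (2 * l^2))
  }
  K <- kfun(X, X) + diag(1e-6 * s2 + 1e-10, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(sample_point(space))
  a <- backsolve(L, forwardsolve(t(L), y - mu0))
  cand <- replicate(n_candidates, sample_point(space), simplify = FALSE)
  Xc <- do.call(rbind, lapply(cand, encode_point, space = space))
  Ks <- kfun(Xc, X)
  mu <- mu0 + Ks %*% a
  V <- forwardsolve(t(L), t(Ks))   # L^{-1} k*, columns per candidate
  sig2 <- pmax(s2 - colSums(V^2), 1e-12)
  sig <- sqrt(sig2)
  z <- (mu - max(y)) / sig
  ei <- sig * (z * stats::pnorm(z) + stats::dnorm(z))
  cand[[which.max(ei)]]
}

#' Tune a model family by cross-validated micro AUC
#'
#' Bayesian GP optimization of a baseline family (or the CNN's schedule)
#' against seeded `cv_folds`-fold cross-validation on `(X, y)`; the
#' objective is the mean fold AUC of the held-out scores.
#'
#' @param spec a [baseline_spec()], or a list with `family = "vdlin"` and a
#'   `search_space`.
#' @param protocol an [optimizer_protocol()].
#' @param X feature matrix.
#' @param y binary labels (vector) or `n x g` label matrix (micro-pooled).
#' @return as [bayes_optimize()].
#' @export
tune_model <- function(spec, protocol = optimizer_protocol(), X, y) {
  X <- as.matrix(X)
  y <- as.matrix(y)
  n <- nrow(X)
  folds <- with_seed(protocol$seed + 1L,
                     sample(rep_len(seq_len(protocol$cv_folds), n)))
  objective <- function(params) {
    aucs <- vapply(seq_len(protocol$cv_folds), function(f) {
      tr <- folds != f
      scores <- vapply(seq_len(ncol(y)), function(g) {
        fit <- fit_baseline(spec$family, X[tr, , drop = FALSE], y[tr, g],
                            params = params, seed = protocol$seed)
        predict_baseline(fit, X[!tr, , drop = FALSE])
      }, numeric(sum(!tr)))
      ev <- suppressWarnings(
        evaluate_scores(as.numeric(y[!tr, , drop = FALSE]), as.numeric(scores)))
      if (is.na(ev$auc)) 0.5 else ev$auc
    }, numeric(1))
    mean(aucs)
  }
  bayes_optimize(spec$search_space, objective, protocol)
}
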