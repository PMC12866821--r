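#' Label-noise protocol
#'
#' Noise levels for the robustness study; at each level the whole 10-gene
#' label vectors of a randomly selected proportion of *training* samples
#' are permuted among themselves (the test partition is untouched).
#'
#' @param noise_levels proportions in `[0, 1]`, default
#'   `c(0.10, 0.20, 0.30)`. Level 0 (the noise-free reference) is always
#'   included by [run_benchmark()].
#' @param n_seeds replicate seeds per condition, default 5.
#' @param permute_scope `"whole_label_vector"` (default) or `"per_entry"`
#'   (independent flips).
#' @return object of class `noise_protocol`.
#' @export
noise_protocol <- function(noise_levels = c(0.10, 0.20, 0.30), n_seeds = 5L,
                           permute_scope = c("whole_label_vector", "per_entry")) {
  permute_scope <- match.arg(permute_scope)
  for (v in noise_levels) check_proportion(v, "noise_levels")
  structure(list(noise_levels = sort(unique(c(0, noise_levels))),
                 n_seeds = check_scalar_count(n_seeds, "n_seeds"),
                 permute_scope = permute_scope),
            class = "noise_protocol")
}

benchmark_model_names <- function() {
  c("vdlin", "svm_rbf", "knn", "logistic", "random_forest", "gradient_boosting")
}

#' Benchmark the CNN against the five conventional baselines
#'
#' Every model sees identical features `X` and the identical train/test
#' split; the split indices are recorded in the report manifest. Targets
#' are the continuous delta profiles `Y`; baselines consume the binary
#' per-gene desired-effect reduction (`dir * delta > tau`, i.e. the gene
#' moved significantly in the desired direction, with `tau` the ternary
#' dead-zone threshold), one binary problem per gene with shared features,
#' metrics micro-pooled. At each
#' noise level and seed the *rows* of the training delta matrix are
#' permuted for the selected fraction of compounds (which induces exactly
#' the whole-label-vector permutation on the binary view), all models are
#' retrained, and AUC / F1 / TPR / precision / recall are measured on the
#' untouched test set. F1 degradation is computed per model and seed
#' relative to that model's own noise-free F1.
#'
#' @param X feature matrix (n x p), e.g. VAE latents.
#' @param Y continuous delta target matrix (n x 10), canonical panel order.
#' @param panel a [gene_panel()].
#' @param train_idx integer indices of the training rows; default is a
#'   seeded 70% split.
#' @param noise a [noise_protocol()].
#' @param models character subset of
#'   `c("vdlin", "svm_rbf", "knn", "logistic", "random_forest",
#'   "gradient_boosting")`; unknown names are an error.
#' @param vdlin_config [model_config()] used for the CNN entries.
#' @param baseline_params named list of per-family hyperparameter lists
#'   (defaults otherwise).
#' @param tau dead-zone threshold defining the binary desired-effect
#'   labels, default 0.5 (matches [ternarize()]).
#' @param split_seed seed for the default split.
#' @return object of class `benchmark_report`: `results` (tidy data.frame:
#'   model, noise_level, seed, metric, value), `degradation` (model,
#'   noise_level, seed, f1, f1_clean, relative_degradation), `manifest`.
#' @export
run_benchmark <- function(X, Y, panel = default_panel(), train_idx = NULL,
                          noise = noise_protocol(), models = benchmark_model_names(),
                          vdlin_config = model_config(epochs = 15L, batch_size = 32L),
                          baseline_params = list(), tau = 0.5, split_seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(Y) == 10L)
  unknown <- setdiff(models, benchmark_model_names())
  if (length(unknown) > 0L) {
    stop(sprintf("run_benchmark: unknown model(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(X)
  if (is.null(train_idx)) {
    train_idx <- with_seed(split_seed, sample.int(n)[seq_len(floor(0.7 * n))])
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  dir <- matrix(as.numeric(panel_directions(panel)), n, 10L, byrow = TRUE)
  B <- (dir * Y > tau) * 1        # significant desired-direction move
  B_test <- B[test_idx, , drop = FALSE]

  rows <- list()
  for (s in seq_len(noise$n_seeds)) {
    for (level in noise$noise_levels) {
      noise_seed <- stage_seed(s, paste0("noise", level))
      Yn_train <- permute_training_rows(Y[train_idx, , drop = FALSE], level,
                                        noise_seed, noise$permute_scope, dir[1L, ])
      Bn_train <- (matrix(dir[1L, ], length(train_idx), 10L, byrow = TRUE) *
                     Yn_train > tau) * 1
      for (model in models) {
        scores <- if (model == "vdlin") {
          cfg <- vdlin_config
          cfg$seed <- stage_seed(s, "vdlin")
          m <- build_model(cfg, ncol(X), panel)
          m <- train_model(m, X[train_idx, , drop = FALSE], Yn_train)
          pd <- predict(m, X[test_idx, , drop = FALSE])$predicted_delta
          # probability of a *significant* desired move, matching the
          # tau-based label definition the baselines are trained on
          logistic(cfg$soft_score_temperature *
                     (pd * dir[test_idx, , drop = FALSE] - tau))
        } else {
          params <- baseline_params[[model]] %||% list()
          vapply(seq_len(10L), function(g) {
            fit <- fit_baseline(model, X[train_idx, , drop = FALSE],
                                Bn_train[, g], params = params,
                                seed = stage_seed(s, model))
            predict_baseline(fit, X[test_idx, , drop = FALSE])
          }, numeric(length(test_idx)))
        }
        ev <- suppressWarnings(
          evaluate_scores(as.numeric(B_test), as.numeric(scores)))
        for (metric in c("auc", "f1", "tpr", "precision", "recall")) {
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, noise_level = level, seed = s, metric = metric,
            value = ev[[metric]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)

  f1 <- results[results$metric == "f1", ]
  clean <- f1[f1$noise_level == 0, c("model", "seed", "value")]
  names(clean)[3L] <- "f1_clean"
  degradation <- merge(f1, clean, by = c("model", "seed"))
  degradation$relative_degradation <- ifelse(
    degradation$f1_clean > 0,
    (degradation$f1_clean - degradation$value) / degradation$f1_clean, 0)
  degradation <- degradation[order(degradation$model, degradation$noise_level,
                                   degradation$seed),
                             c("model", "noise_level", "seed", "value",
                               "f1_clean", "relative_degradation")]
  names(degradation)[4L] <- "f1"

  structure(list(
    results = results,
    degradation = degradation,
    manifest = list(
      n = n, train_idx = train_idx, test_idx = test_idx,
      models = models, noise_levels = noise$noise_levels,
      n_seeds = noise$n_seeds, permute_scope = noise$permute_scope,
      tau = tau, feature_dim = ncol(X)
    )
  ), class = "benchmark_report")
}

# permute whole rows of the training delta matrix for a selected fraction
# of samples (or flip per-entry signs of the desired-effect view)
permute_training_rows <- function(Y_train, fraction, seed, scope, dir_row) {
  n <- nrow(Y_train)
  k <- round(fraction * n)
  if (k == 0L) return(Y_train)
  with_seed(seed, {
    rows <- sample.int(n, k)
    if (scope == "whole_label_vector") {
      Y_train[rows, ] <- Y_train[rows[sample.int(k)], , drop = FALSE]
    } else {
      # flipping the desired-effect label of an entry = flipping its delta sign
      Y_train[rows, ] <- -Y_train[rows, , drop = FALSE]
    }
    Y_train
  })
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d models x %d noise levels x %d seeds (n = %d)\n",
              length(x$manifest$models), length(x$manifest$noise_levels),
              x$manifest$n_seeds, x$manifest$n))
  f1 <- x$results[x$results$metric == "f1", ]
  agg <- stats::aggregate(value ~ model + noise_level, f1, stats::median)
  print(utils::head(stats::reshape(agg, idvar = "model", timevar = "noise_level",
                                   direction = "wide"), 10))
  invisible(x)
}

#' Write the benchmark report
#'
#' Tidy metrics CSV, degradation CSV and a JSON manifest.
#'
#' @param report a [run_benchmark()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "benchmark_metrics.csv")
  p2 <- file.path(dir, "benchmark_degradation.csv")
  p3 <- file.path(dir, "benchmark_manifest.json")
  utils::write.csv(report$results, p1, row.names = FALSE)
  utils::write.csv(report$degradation, p2, row.names = FALSE)
  jsonlite::write_json(report$manifest, p3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(metrics = p1, degradation = p2, manifest = p3))
}
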