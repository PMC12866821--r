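quadratic_objective <- function(p) -(p$x - 3)^2

test_that("a degenerate single-point space is returned after one evaluation", {
  res <- bayes_optimize(list(param_categorical("k", "only"),
                             param_real("x", 2, 2)),
                        function(p) 42, optimizer_protocol(seed = 1))
  expect_identical(res$n_evaluations, 1L)
  expect_identical(res$best_params$k, "only")
  expect_identical(res$best_value, 42)
})

test_that("the 1-D quadratic optimum is found within 0.5", {
  for (seed in 1:3) {
    res <- bayes_optimize(list(param_real("x", 0, 10)), quadratic_objective,
                          optimizer_protocol(seed = seed))
    expect_lt(abs(res$best_params$x - 3), 0.5)
    expect_lte(res$n_evaluations, 100)
  }
})

test_that("iteration and patience budgets are respected exactly", {
  # constant objective: 1 initial + 20 non-improving = 21 evaluations
  res <- bayes_optimize(list(param_real("x", 0, 10)), function(p) 1,
                        optimizer_protocol(seed = 2))
  expect_identical(res$n_evaluations, 21L)
  expect_true(res$stopped_early)
  expect_identical(nrow(res$trace), 21L)
  # strictly improving objective never stops early, exhausts the budget
  counter <- new.env(); counter$i <- 0
  res2 <- bayes_optimize(list(param_real("x", 0, 10)),
                         function(p) { counter$i <- counter$i + 1; counter$i },
                         optimizer_protocol(max_iterations = 30,
                                            early_stop_patience = 20, seed = 3))
  expect_identical(res2$n_evaluations, 30L)
  expect_false(res2$stopped_early)
  expect_error(optimizer_protocol(max_iterations = 10, early_stop_patience = 10),
               "early_stop_patience")
})

test_that("every evaluated point stays inside the declared space", {
  space <- list(param_real("lr", 0.01, 0.3, log = TRUE),
                param_integer("depth", 2, 8),
                param_categorical("kind", c("a", "b")))
  res <- bayes_optimize(space, function(p) p$lr * p$depth,
                        optimizer_protocol(max_iterations = 40,
                                           early_stop_patience = 20, seed = 4))
  expect_true(all(res$trace$lr >= 0.01 & res$trace$lr <= 0.3))
  expect_true(all(res$trace$depth >= 2 & res$trace$depth <= 8))
  expect_true(all(res$trace$depth == floor(res$trace$depth)))
  expect_true(all(res$trace$kind %in% c("a", "b")))
  expect_identical(res$trace$best_so_far, cummax(res$trace$value))
})

test_that("optimization is deterministic under a fixed protocol seed", {
  r1 <- bayes_optimize(list(param_real("x", 0, 10)), quadratic_objective,
                       optimizer_protocol(seed = 11))
  r2 <- bayes_optimize(list(param_real("x", 0, 10)), quadratic_objective,
                       optimizer_protocol(seed = 11))
  expect_identical(r1$trace, r2$trace)
})

test_that("baseline specs carry the printed search ranges", {
  rf <- baseline_spec("random_forest")
  n_est <- rf$search_space[[1]]
  expect_identical(c(n_est$lower, n_est$upper), c(50L, 200L))
  lg <- baseline_spec("logistic")
  expect_true(lg$search_space[[1]]$log)
  expect_identical(baseline_spec("knn")$search_space[[2]]$values,
                   c("euclidean", "manhattan"))
  gb <- baseline_spec("gradient_boosting")
  expect_identical(c(gb$search_space[[3]]$lower, gb$search_space[[3]]$upper),
                   c(0.6, 1.0))
  expect_error(baseline_spec("nonsense"))
})

test_that("tune_model improves a kNN baseline on separable data", {
  X <- withr::with_seed(1, matrix(rnorm(90 * 6), 90))
  y <- (X[, 1] > 0) * 1
  res <- tune_model(baseline_spec("knn"),
                    optimizer_protocol(max_iterations = 10,
                                       early_stop_patience = 8, seed = 5),
                    X, y)
  expect_gt(res$best_value, 0.7)
  expect_true(res$best_params$metric %in% c("euclidean", "manhattan"))
})
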