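test_that("AUC matches hand-computed and degenerate cases", {
  ev <- evaluate_scores(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(ev$auc, 0.75)
  expect_equal(evaluate_scores(c(1, 1, 0), c(0.9, 0.8, 0.1))$auc, 1)
  expect_equal(evaluate_scores(c(0, 0, 1), c(0.9, 0.8, 0.1))$auc, 0)
  # ties get half credit
  expect_equal(evaluate_scores(c(1, 0), c(0.5, 0.5))$auc, 0.5)
})

test_that("AUC equals the all-pairs concordance oracle on random instances", {
  for (trial in 1:20) {
    n <- withr::with_seed(trial, sample(5:50, 1))
    y <- withr::with_seed(trial * 7 + 1, rbinom(n, 1, 0.5))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- withr::with_seed(trial * 13 + 2, round(runif(n), 2))  # induce ties
    got <- evaluate_scores(y, s)$auc
    num <- 0; den <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      den <- den + 1
      if (s[i] > s[j]) num <- num + 1 else if (s[i] == s[j]) num <- num + 0.5
    }
    expect_equal(got, num / den)
  }
})

test_that("threshold metrics: confusion, precision, recall, F1", {
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.7, 0.3, 0.1)
  ev <- evaluate_scores(y, s)
  expect_equal(unname(ev$confusion["1", "1"]), 2)   # TP
  expect_equal(unname(ev$confusion["0", "1"]), 1)   # FP
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$tpr, ev$recall)
  expect_equal(ev$f1, 2 / 3)
  expect_equal(ev$accuracy, 4 / 6)
})

test_that("single-class labels: AUC is NA with warning, other metrics remain", {
  expect_warning(ev <- evaluate_scores(c(1, 1), c(0.4, 0.9)), "undefined")
  expect_true(is.na(ev$auc))
  expect_equal(ev$recall, 0.5)
  expect_error(evaluate_scores(c(1, 2), c(0.1, 0.2)), "binary")
  expect_error(evaluate_scores(1, c(0.1, 0.2)), "equal length")
})

test_that("matrix inputs are micro-averaged by flattening", {
  y <- matrix(c(1, 0, 0, 1), 2)
  s <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)
  expect_equal(evaluate_scores(y, s)$auc,
               evaluate_scores(as.numeric(y), as.numeric(s))$auc)
})

test_that("curve points are monotone and complete", {
  y <- c(1, 1, 0, 1, 0, 0)
  s <- c(0.9, 0.7, 0.6, 0.5, 0.4, 0.2)
  cp <- curve_points(y, s)
  expect_true(all(diff(cp$tpr) >= 0))
  expect_true(all(diff(cp$fpr) >= 0))
  expect_equal(utils::tail(cp$tpr, 1), 1)
  expect_equal(utils::tail(cp$fpr, 1), 1)
})

test_that("label-noise injection: exact counts, determinism, multiset preserved", {
  labels <- withr::with_seed(3, matrix(rbinom(100 * 10, 1, 0.4), 100))
  expect_identical(inject_label_noise(labels, 0, seed = 1), labels)
  noisy <- inject_label_noise(labels, 0.3, seed = 9)
  expect_identical(inject_label_noise(labels, 0.3, seed = 9), noisy)
  # exactly round(0.3 * 100) = 30 rows selected; permutation preserves the
  # multiset of label vectors
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  expect_identical(key(noisy), key(labels))
  changed <- rowSums(noisy != labels) > 0
  expect_lte(sum(changed), 30)
  expect_gt(sum(changed), 0)
  # flip mode changes exactly the selected rows, everywhere
  flipped <- inject_label_noise(labels, 0.3, seed = 9, mode = "flip")
  expect_identical(sum(rowSums(flipped != labels) > 0), 30L)
  # vector input round-trips
  v <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  expect_identical(sort(inject_label_noise(v, 0.5, seed = 2)), sort(v))
  expect_error(inject_label_noise(v, 1.5), "fraction")
})
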