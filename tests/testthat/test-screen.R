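test_that("primary screen: threshold-only mode follows >= 70", {
  crit <- primary_criteria(sd_multiplier = 0, background = "none")
  expect_identical(primary_screen(c(100, 80, 60), crit), c(TRUE, TRUE, FALSE))
  expect_identical(primary_screen(c(70, 69.9), crit), c(TRUE, FALSE))
  expect_false(any(primary_screen(rep(0, 5), crit)))
  expect_error(primary_screen(numeric(0), crit), "empty")
})

test_that("primary screen: the 3.5-SD background clause uses strict > and population SD", {
  crit <- primary_criteria(score_threshold = 70, sd_multiplier = 3.5)
  # background mean 50, population sd 10 -> cut = 85: a score of 80 fails
  bg <- rep(c(40, 60), 50)                      # mean 50, population sd 10
  expect_equal(vdlin:::pop_sd(bg), 10, tolerance = 1e-12)
  expect_identical(primary_screen(c(80, 90), crit, background_scores = bg),
                   c(FALSE, TRUE))
  # boundary: exactly mean + 3.5 sd fails the strict inequality
  expect_false(primary_screen(85, crit, background_scores = bg))
})

test_that("primary screen defaults to the library itself as background", {
  crit <- primary_criteria()
  scores <- c(rep(50, 99), 100)
  # mean ~50.5, sd ~4.97 -> cut ~67.9; the 100 passes, the 50s fail
  flags <- primary_screen(scores, crit)
  expect_identical(flags, c(rep(FALSE, 99), TRUE))
})

test_that("secondary screen needs >= 3 desired moves in each class", {
  expect_true(secondary_screen(c(1, 1, 1, 0, 0, -1, -1, -1, 0, 0)))
  expect_true(secondary_screen(ideal_delta()))
  # 5 inflammatory down + 2 IFN up scores 70 but fails the IFN clause
  d <- c(1, 1, 0, 0, 0, rep(-1, 5))
  expect_identical(hard_score(d)$total_score, 70L)
  expect_false(secondary_screen(d))
  # matrix input, custom threshold
  m <- rbind(ideal_delta(), null_delta())
  expect_identical(secondary_screen(m), c(TRUE, FALSE))
  expect_true(secondary_screen(d, min_per_class = 2))
})

test_that("screens are monotone: adding a satisfied indicator never flips pass to fail", {
  patterns <- withr::with_seed(6, all_sign_patterns()[sample(3^10, 300), ])
  crit <- primary_criteria(sd_multiplier = 0, background = "none")
  for (i in seq_len(nrow(patterns))) {
    d <- patterns[i, ]
    unsat <- c(which(d[1:5] <= 0), 5 + which(d[6:10] >= 0))
    if (length(unsat) == 0) next
    j <- unsat[1]
    d2 <- d
    d2[j] <- if (j <= 5) 1 else -1
    expect_gte(hard_score(d2)$total_score, hard_score(d)$total_score)
    if (secondary_screen(d)) expect_true(secondary_screen(d2))
    if (primary_screen(hard_score(d)$total_score, crit)) {
      expect_true(primary_screen(hard_score(d2)$total_score, crit))
    }
  }
})

test_that("rank_candidates ranks only dual-pass compounds, densely, ties by id", {
  res <- data.frame(
    compound_id = c("A", "B", "C", "D", "E"),
    total_score = c(100, 80, 90, 90, 40),
    passes_primary = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    passes_secondary = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  ranked <- rank_candidates(res)
  expect_identical(ranked$compound_id[1:3], c("A", "D", "B"))
  expect_identical(ranked$rank[1:3], 1:3)
  expect_true(all(is.na(ranked$rank[4:5])))

  # tie broken lexicographically
  tie <- data.frame(compound_id = c("Z", "Y"), total_score = c(90, 90),
                    passes_primary = TRUE, passes_secondary = TRUE)
  expect_identical(rank_candidates(tie)$compound_id, c("Y", "Z"))

  none <- data.frame(compound_id = "A", total_score = 100,
                     passes_primary = FALSE, passes_secondary = TRUE)
  expect_true(all(is.na(rank_candidates(none)$rank)))
  expect_error(rank_candidates(data.frame(a = 1)), "must contain")
})

test_that("screen_library composes scoring and both screens end-to-end", {
  delta <- rbind(
    A = ideal_delta(),
    B = c(1, 1, 1, 0, 0, -1, -1, -1, -1, 0),   # score 70, passes both
    C = c(1, 1, 0, 0, 0, rep(-1, 5)),          # score 70, fails secondary
    D = null_delta())
  out <- screen_library(delta, criteria = primary_criteria(sd_multiplier = 0,
                                                           background = "none"))
  expect_identical(out$results$compound_id[1:2], c("A", "B"))
  expect_identical(out$results$rank[1:2], 1:2)
  expect_identical(out$summary$n_ranked, 2L)
  expect_identical(out$summary$n_pass_primary, 3L)
  # permutation-null background is seeded and reported
  out2 <- screen_library(delta, criteria = primary_criteria(background = "permutation_null"),
                         seed = 3)
  expect_false(is.na(out2$summary$background_mean))
  out3 <- screen_library(delta, criteria = primary_criteria(background = "permutation_null"),
                         seed = 3)
  expect_identical(out2$results, out3$results)
})

test_that("screen report files are written", {
  delta <- rbind(A = ideal_delta(), B = null_delta())
  out <- screen_library(delta, criteria = primary_criteria(sd_multiplier = 0,
                                                           background = "none"))
  dir <- withr::local_tempdir()
  paths <- write_screen_report(out, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["results"]])
  expect_identical(nrow(back), 2L)
})
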