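test_that("replicate filter keeps >= 7 and removes < 7, preserving order", {
  recs <- list(make_record("A", 6), make_record("B", 7), make_record("C", 12),
               make_record("D", 1))
  kept <- clean_library(recs)
  expect_identical(vapply(kept, `[[`, character(1), "compound_id"), c("B", "C"))
  expect_identical(clean_library(list()), list())
  # idempotence
  expect_identical(clean_library(kept), kept)
  # configurable threshold
  expect_length(clean_library(recs, min_replicates = 1), 4)
})

test_that("profile averaging is a plain arithmetic mean over replicates", {
  r <- make_record("A", 8, n_genes = 11)
  r$replicates[, "IL6"] <- 0:7
  expect_equal(average_profile(r)[["IL6"]], 3.5)

  r2 <- make_record("B", 2)
  r2$replicates[, 1] <- c(1, 3)
  expect_equal(average_profile(r2)[[1]], 2)

  single <- make_record("C", 1)
  expect_equal(average_profile(single), single$replicates[1, ])

  r$replicates <- r$replicates[0, , drop = FALSE]
  expect_error(average_profile(r), "replicate")
})

test_that("averaging is invariant to replicate order", {
  r <- make_record("A", 9, seed = 4)
  shuffled <- r
  shuffled$replicates <- r$replicates[sample(9), , drop = FALSE]
  expect_equal(average_profile(r), average_profile(shuffled))
})

test_that("ternarize applies a strict dead zone and matches a brute-force oracle", {
  expect_identical(ternarize(c(0, 1, -1), tau = 0.5), c(0L, 1L, -1L))
  expect_identical(ternarize(c(0.5, -0.5), tau = 0.5), c(0L, 0L))  # boundary -> 0
  delta <- withr::with_seed(8, runif(1000, -3, 3))
  got <- ternarize(delta, tau = 0.4)
  oracle <- integer(1000)
  for (i in seq_len(1000)) {
    if (delta[i] > 0.4) oracle[i] <- 1L else if (delta[i] < -0.4) oracle[i] <- -1L
  }
  expect_identical(got, oracle)
  # odd symmetry
  expect_identical(ternarize(-delta, 0.4), -got)
  expect_error(ternarize(delta, tau = -1), "tau")
})

test_that("select_panel reorders to canonical order from any universe", {
  panel <- default_panel()
  shuffled <- withr::with_seed(2, sample(panel_genes(panel)))
  v <- stats::setNames(seq_along(shuffled), shuffled)
  prof <- select_panel(v, panel)
  expect_identical(names(prof$delta), panel_genes(panel))
  expect_equal(unname(prof$delta), unname(v[panel_genes(panel)]))

  # large universe lookup matches a direct dictionary oracle
  genes <- c(sprintf("L%04d", 1:968), panel_genes(panel))
  big <- withr::with_seed(3, stats::setNames(rnorm(978), sample(genes)))
  prof2 <- select_panel(big, panel)
  expect_equal(unname(prof2$delta), unname(big[panel_genes(panel)]))

  missing <- big[setdiff(names(big), "IFNB1")]
  expect_error(select_panel(missing, panel), "IFNB1")
})

test_that("gene matching is case-insensitive", {
  v <- stats::setNames(1:10, tolower(panel_genes(default_panel())))
  prof <- select_panel(v, default_panel())
  expect_equal(unname(prof$delta), 1:10)
})

test_that("profile_library composes filter + average + panel selection", {
  lib <- make_library(n = 40, seed = 6, replicate_count_range = c(4L, 10L))
  prof <- profile_library(lib, min_replicates = 7)
  n_expected <- sum(vapply(lib, function(r) nrow(r$replicates) >= 7, logical(1)))
  expect_identical(nrow(prof$delta), n_expected)
  expect_identical(colnames(prof$delta), panel_genes(default_panel()))
  expect_true(all(prof$ternary %in% c(-1L, 0L, 1L)))
  # ternary consistent with delta
  expect_identical(as.vector(prof$ternary),
                   as.vector(ternarize(prof$delta, 0.5)))
})

test_that("profiles CSV round-trips", {
  lib <- make_library(n = 12, seed = 13)
  prof <- profile_library(lib, min_replicates = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(prof, path)
  back <- read_profiles_csv(path)
  expect_equal(back, prof$delta, tolerance = 1e-12)
})
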