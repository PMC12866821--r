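test_that("generation is seeded and byte-identical across runs", {
  cfg <- synthetic_config(n_compounds = 100, seed = 7)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(serialize(lib1, NULL), serialize(lib2, NULL))
  expect_length(lib1, 100)
})

test_that("degenerate active fractions behave", {
  lib0 <- generate_library(synthetic_config(n_compounds = 50, active_fraction = 0, seed = 3))
  expect_false(any(lib_active(lib0)))
  lib1 <- generate_library(synthetic_config(n_compounds = 50, active_fraction = 1, seed = 3))
  expect_true(all(lib_active(lib1)))
})

test_that("active count matches an independent re-draw of the same RNG recipe", {
  lib <- generate_library(synthetic_config(n_compounds = 1000, active_fraction = 0.3, seed = 1))
  # documented recipe: first draw after set.seed is runif(n) < active_fraction
  oracle <- withr::with_seed(1, sum(runif(1000) < 0.3))
  expect_identical(sum(lib_active(lib)), oracle)
})

test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_compounds = 0), "n_compounds")
  expect_error(synthetic_config(active_fraction = 1.2), "active_fraction")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(gene_universe_size = 5), "gene_universe_size")
  expect_error(synthetic_config(replicate_count_range = c(5, 2)), "replicate_count_range")
})

test_that("marker substructure appears iff the compound is a planted active", {
  lib <- make_library(n = 150, seed = 21)
  expect_identical(grepl("P", lib_smiles(lib), fixed = TRUE), lib_active(lib))
})

test_that("planted effect lands on panel genes with the desired signs", {
  lib <- make_library(n = 2000, seed = 5, replicate_count_range = c(4L, 8L))
  prof <- profile_library(lib, min_replicates = 1L)
  act <- lib_active(lib)
  dirs <- as.numeric(panel_directions(default_panel()))
  # per-gene (active mean - inactive mean) should sit within 3 SE of the
  # planted signed effect
  for (g in 1:10) {
    a <- prof$delta[act, g]; i <- prof$delta[!act, g]
    diff <- mean(a) - mean(i)
    se <- sqrt(var(a) / length(a) + var(i) / length(i))
    expect_lt(abs(diff - 2 * dirs[g]), 3 * se + 1e-9)
  }
})

test_that("split respects the floor(train_fraction * n) convention", {
  lib <- as.list(seq_len(7861))
  sp <- split_library(lib, 0.7, seed = 1)
  expect_length(sp$train, 5502)
  expect_length(sp$test, 2359)

  sp10 <- split_library(as.list(1:10), 0.5, seed = 2)
  expect_length(sp10$train, 5)
  sp7 <- split_library(as.list(1:7), 0.7, seed = 2)
  expect_length(sp7$train, 4)
  expect_length(sp7$test, 3)
})

test_that("split partitions are disjoint, exhaustive and seeded", {
  lib <- make_library(n = 60, seed = 9)
  sp <- split_library(lib, 0.7, seed = 4)
  ids <- function(x) sort(vapply(x, `[[`, character(1), "compound_id"))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_identical(sort(c(ids(sp$train), ids(sp$test))), ids(lib))
  sp2 <- split_library(lib, 0.7, seed = 4)
  expect_identical(ids(sp$train), ids(sp2$train))
  expect_error(split_library(list(), 0.7), "empty")
  expect_error(split_library(lib, 1.2), "train_fraction")
})

test_that("smi and signature CSV round-trip through files", {
  lib <- make_library(n = 8, seed = 2)
  smi <- withr::local_tempfile(fileext = ".smi")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_smi(lib, smi)
  write_signatures_csv(lib, csv)
  back <- read_signatures_csv(csv, smi_path = smi)
  expect_length(back, 8)
  expect_identical(vapply(back, `[[`, character(1), "smiles"), lib_smiles(lib))
  expect_equal(back[[3]]$replicates, lib[[3]]$replicates, ignore_attr = TRUE,
               tolerance = 1e-12)
})
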