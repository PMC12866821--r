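# shared fixture builders (all programmatic; no stored data)

# small planted library with enough replicates to survive the default filter
make_library <- function(n = 120, seed = 11, active_fraction = 0.3,
                         effect_size = 2, noise_sd = 0.3,
                         replicate_count_range = c(7L, 12L)) {
  generate_library(synthetic_config(
    n_compounds = n, seed = seed, active_fraction = active_fraction,
    effect_size = effect_size, noise_sd = noise_sd,
    replicate_count_range = replicate_count_range))
}

lib_smiles <- function(lib) vapply(lib, `[[`, character(1), "smiles")
lib_active <- function(lib) vapply(lib, `[[`, logical(1), "is_planted_active")

# a compound record with a given replicate count over a 12-gene universe
make_record <- function(id = "C1", n_reps = 7, n_genes = 12, seed = 1) {
  genes <- c(panel_genes(default_panel()),
             sprintf("G%04d", seq_len(max(0, n_genes - 10)) + 10))
  withr::with_seed(seed, compound_record(
    compound_id = id, smiles = "CCO",
    replicates = matrix(rnorm(n_reps * n_genes), n_reps,
                        dimnames = list(NULL, genes))))
}

# ideal / null panel profiles (canonical order: 5 IFN then 5 inflammatory)
ideal_delta <- function(mag = 1) c(rep(mag, 5), rep(-mag, 5))
null_delta <- function() rep(0, 10)

# all 3^10 sign patterns, rows in {-1, 0, 1} (unnamed, canonical order)
all_sign_patterns <- function() {
  m <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 10)))
  dimnames(m) <- NULL
  m
}

# total scores for a sign-pattern matrix
score_matrix_scores <- function(patterns) {
  vdlin:::score_matrix(patterns)$total_score
}
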