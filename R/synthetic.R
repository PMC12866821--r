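#' Configuration for the synthetic compound library
#'
#' Describes a seeded synthetic library with LINCS-like replicate structure
#' and a planted structure-activity rule. A configurable fraction of
#' compounds ("planted actives") carry a marker substructure (a phosphate
#' ester, the only source of the `P` atom token in the fragment vocabulary)
#' and induce the desired dual effect on the gene panel: each IFN gene gets
#' mean `+effect_size`, each inflammatory gene mean `-effect_size`, plus
#' Gaussian replicate noise. Inactive compounds never contain the marker and
#' their signatures are pure zero-mean noise. The marker-iff-active coupling
#' is the learnable signal for the structure-to-signature model.
#'
#' @param n_compounds number of compounds to generate.
#' @param replicate_count_range inclusive integer range of per-compound
#'   replicate counts, default `c(1, 12)` (so the min-replicate filter has
#'   something to remove).
#' @param gene_universe_size total number of genes (>= 10); the 10 panel
#'   genes come first, filler genes (`G0011`, ...) after.
#' @param active_fraction proportion of planted actives in `[0, 1]`.
#' @param effect_size mean absolute delta planted on panel genes of actives.
#' @param noise_sd SD of additive Gaussian noise on every delta value.
#' @param seed integer seed; the same config is bit-identical across runs.
#' @param panel the [gene_panel()] receiving the planted effect.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 1000L,
                             replicate_count_range = c(1L, 12L),
                             gene_universe_size = 50L,
                             active_fraction = 0.3,
                             effect_size = 2,
                             noise_sd = 0.3,
                             seed = 1L,
                             panel = default_panel()) {
  n_compounds <- check_scalar_count(n_compounds, "n_compounds")
  if (length(replicate_count_range) != 2L ||
      any(replicate_count_range != floor(replicate_count_range)) ||
      replicate_count_range[1L] < 1L ||
      replicate_count_range[2L] < replicate_count_range[1L]) {
    stop("synthetic_config: `replicate_count_range` must be an increasing pair of integers >= 1",
         call. = FALSE)
  }
  gene_universe_size <- check_scalar_count(gene_universe_size, "gene_universe_size", min = 10L)
  active_fraction <- check_proportion(active_fraction, "active_fraction")
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0) {
    stop("synthetic_config: `effect_size` must be a nonnegative scalar", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("synthetic_config: `noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(
    n_compounds = n_compounds,
    replicate_count_range = as.integer(replicate_count_range),
    gene_universe_size = gene_universe_size,
    active_fraction = active_fraction,
    effect_size = effect_size,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    panel = panel
  ), class = "synthetic_config")
}

# fragment vocabulary for seeded SMILES assembly; every concatenation of
# scaffold + chain fragments (+ marker) (+ terminal halogen) is a valid
# molecule (checked against RDKit during development)
smiles_fragments <- function() {
  list(
    scaffolds = c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "C1CCOCC1"),
    chains    = c("C", "CC", "CCC", "CO", "CN", "C(C)C", "CC(C)", "C(=O)O", "CCN", "COC"),
    marker    = "OP(=O)(O)O",
    terminals = c("", "Cl", "F", "Br")
  )
}

#' Generate a synthetic compound library
#'
#' Draws a seeded library per the config. The RNG recipe is documented and
#' stable: after `set.seed(config$seed)` the *first* draw is the active
#' flags, `runif(n_compounds) < active_fraction`; replicate counts, SMILES
#' assembly, and replicate noise follow in compound order. Rerunning with
#' the same config reproduces the library byte-for-byte.
#'
#' @param config a [synthetic_config()].
#' @return list of `compound_record` objects; each has `compound_id`,
#'   `smiles`, `replicates` (replicate x gene delta matrix with gene column
#'   names) and `is_planted_active`.
#' @export
generate_library <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("generate_library: `config` must be a synthetic_config", call. = FALSE)
  }
  n <- config$n_compounds
  genes <- universe_genes(config)
  dir <- panel_directions(config$panel)
  frag <- smiles_fragments()
  with_seed(config$seed, {
    is_active <- stats::runif(n) < config$active_fraction
    rep_counts <- sample(seq(config$replicate_count_range[1L],
                             config$replicate_count_range[2L]),
                         n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      smiles <- assemble_smiles(frag, active = is_active[i])
      reps <- matrix(stats::rnorm(rep_counts[i] * length(genes), sd = config$noise_sd),
                     nrow = rep_counts[i],
                     dimnames = list(NULL, genes))
      if (is_active[i]) {
        reps[, 1:10] <- sweep(reps[, 1:10, drop = FALSE], 2L,
                              config$effect_size * as.numeric(dir), `+`)
      }
      compound_record(
        compound_id = sprintf("CPD%05d", i),
        smiles = smiles,
        replicates = reps,
        is_planted_active = is_active[i]
      )
    })
  })
}

# draws within the current RNG stream
assemble_smiles <- function(frag, active) {
  scaffold <- sample(frag$scaffolds, 1L)
  n_chain <- sample(1:3, 1L)
  chains <- sample(frag$chains, n_chain, replace = TRUE)
  if (active) {
    pos <- sample(seq_len(n_chain + 1L), 1L)
    chains <- append(chains, frag$marker, after = pos - 1L)
  }
  terminal <- sample(frag$terminals, 1L)
  tail <- paste(chains, collapse = "")
  # a halogen (valence 1) cannot follow a chain-terminal oxygen of the
  # phosphate marker; attach it before the chain instead in that case
  if (nzchar(terminal) && endsWith(tail, "O")) {
    paste0(scaffold, "C(", terminal, ")", tail)
  } else {
    paste0(scaffold, tail, terminal)
  }
}

universe_genes <- function(config) {
  c(panel_genes(config$panel),
    sprintf("G%04d", seq_len(config$gene_universe_size - 10L) + 10L))
}

#' @rdname generate_library
#' @param compound_id,smiles,replicates,is_planted_active record fields; see
#'   above.
#' @export
compound_record <- function(compound_id, smiles, replicates,
                            is_planted_active = NA) {
  replicates <- as.matrix(replicates)
  if (nrow(replicates) < 1L) {
    stop("compound_record: at least one replicate required", call. = FALSE)
  }
  if (is.null(colnames(replicates)) || anyDuplicated(colnames(replicates))) {
    stop("compound_record: replicate columns must carry unique gene names",
         call. = FALSE)
  }
  structure(list(
    compound_id = as.character(compound_id),
    smiles = as.character(smiles),
    replicates = replicates,
    is_planted_active = is_planted_active
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s  %s  (%d replicates x %d genes%s)\n",
              x$compound_id, x$smiles, nrow(x$replicates), ncol(x$replicates),
              if (isTRUE(x$is_planted_active)) ", planted active" else ""))
  invisible(x)
}

#' Split a library into train and test sets
#'
#' Seeded uniform shuffle followed by a deterministic cut: the train set is
#' the first `floor(train_fraction * n)` compounds of the shuffled order,
#' the test set the remainder. With n = 7861 and fraction 0.7 this yields
#' the 5502 / 2359 partition.
#'
#' @param library list of `compound_record`s (or any list).
#' @param train_fraction proportion in (0, 1).
#' @param seed integer seed for the shuffle.
#' @param stratify_by_active if `TRUE`, shuffle and cut within the active
#'   and inactive strata separately (off by default).
#' @return list with elements `train` and `test` (disjoint, union = input).
#' @export
split_library <- function(library, train_fraction = 0.7, seed = 1L,
                          stratify_by_active = FALSE) {
  n <- length(library)
  if (n == 0L) stop("split_library: empty library", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("split_library: `train_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  idx <- with_seed(seed, {
    if (stratify_by_active) {
      act <- vapply(library, function(r) isTRUE(r$is_planted_active), logical(1))
      take <- function(pool) pool[sample.int(length(pool))][seq_len(floor(train_fraction * length(pool)))]
      sort(c(take(which(act)), take(which(!act))))
    } else {
      sample.int(n)[seq_len(floor(train_fraction * n))]
    }
  })
  train_mask <- logical(n)
  train_mask[idx] <- TRUE
  list(train = library[train_mask], test = library[!train_mask])
}

#' Write / read library files
#'
#' `write_smi()` writes one `SMILES<TAB>compound_id` line per compound;
#' `write_signatures_csv()` writes the replicate signatures in wide form
#' (columns `compound_id`, `replicate_id`, then one column per gene);
#' `read_signatures_csv()` reads that format back into compound records
#' (without ground-truth active flags).
#'
#' @param library list of `compound_record`s.
#' @param path output file path.
#' @return invisibly, the path (writers); list of `compound_record`s
#'   (reader).
#' @export
write_smi <- function(library, path) {
  lines <- vapply(library, function(r) paste(r$smiles, r$compound_id, sep = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_smi
#' @export
write_signatures_csv <- function(library, path) {
  rows <- lapply(library, function(r) {
    data.frame(compound_id = r$compound_id,
               replicate_id = seq_len(nrow(r$replicates)),
               r$replicates, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_smi
#' @param smi_path optional .smi file supplying SMILES per compound id.
#' @export
read_signatures_csv <- function(path, smi_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "replicate_id") %in% names(df))) {
    stop("read_signatures_csv: file must have compound_id and replicate_id columns",
         call. = FALSE)
  }
  smiles_map <- character(0)
  if (!is.null(smi_path)) {
    lines <- strsplit(readLines(smi_path), "\t", fixed = TRUE)
    smiles_map <- stats::setNames(vapply(lines, `[[`, character(1), 1L),
                                  vapply(lines, `[[`, character(1), 2L))
  }
  genes <- setdiff(names(df), c("compound_id", "replicate_id"))
  ids <- unique(df$compound_id)
  lapply(ids, function(id) {
    sub <- df[df$compound_id == id, genes, drop = FALSE]
    compound_record(
      compound_id = id,
      smiles = if (id %in% names(smiles_map)) smiles_map[[id]] else NA_character_,
      replicates = as.matrix(sub)
    )
  })
}
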