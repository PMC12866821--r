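#' Replicate filter
#'
#' Retains exactly the compounds with at least `min_replicates` replicate
#' signatures (default 7, the cleaning rule used for the LINCS-style source
#' data), preserving input order. Idempotent; an empty result is allowed.
#'
#' @param records list of `compound_record`s.
#' @param min_replicates minimum replicate count to keep a compound.
#' @return filtered list of `compound_record`s.
#' @export
clean_library <- function(records, min_replicates = 7L) {
  min_replicates <- check_scalar_count(min_replicates, "min_replicates")
  keep <- vapply(records, function(r) nrow(r$replicates) >= min_replicates, logical(1))
  records[keep]
}

#' Average a compound's replicate signatures
#'
#' Plain arithmetic mean per gene over all replicates, pooling across any
#' covariates (plate, dose, treatment time, cell line are deliberately
#' disregarded).
#'
#' @param record a `compound_record` with at least one replicate.
#' @return named numeric vector of per-gene mean delta.
#' @export
average_profile <- function(record) {
  if (is.null(record$replicates) || nrow(record$replicates) == 0L) {
    stop("average_profile: record has no replicates", call. = FALSE)
  }
  colMeans(record$replicates)
}

#' Ternarize a delta vector
#'
#' Elementwise sign with a dead zone: `+1` where `delta > tau`, `-1` where
#' `delta < -tau`, `0` otherwise. `tau` is the "no significant change"
#' threshold for the ternary labels (+1 upregulated, 0 unchanged, -1
#' downregulated).
#'
#' @param delta numeric vector (any length).
#' @param tau nonnegative dead-zone half-width, default 0.5.
#' @return integer vector in `{-1, 0, 1}`, names preserved.
#' @export
ternarize <- function(delta, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("ternarize: `tau` must be a nonnegative scalar", call. = FALSE)
  }
  out <- integer(length(delta))
  out[delta > tau] <- 1L
  out[delta < -tau] <- -1L
  names(out) <- names(delta)
  out
}

#' Extract the panel profile from a full-universe mean delta vector
#'
#' Looks up the 10 panel genes (case-insensitively) in a named mean-delta
#' vector over any gene universe and returns them in canonical panel order
#' with their ternary labels.
#'
#' @param mean_delta named numeric vector over the gene universe.
#' @param panel a [gene_panel()].
#' @param compound_id identifier carried into the profile.
#' @param tau ternarization threshold (see [ternarize()]).
#' @return a `panel_profile`: list with `compound_id`, `delta` (named
#'   10-vector, canonical order) and `ternary`.
#' @export
select_panel <- function(mean_delta, panel = default_panel(),
                         compound_id = NA_character_, tau = 0.5) {
  if (is.null(names(mean_delta))) {
    stop("select_panel: `mean_delta` must be a named gene vector", call. = FALSE)
  }
  idx <- match_panel(panel, names(mean_delta))
  delta <- stats::setNames(as.numeric(mean_delta[idx]), panel_genes(panel))
  structure(list(
    compound_id = compound_id,
    delta = delta,
    ternary = ternarize(delta, tau)
  ), class = "panel_profile")
}

#' @export
print.panel_profile <- function(x, ...) {
  cat(sprintf("<panel_profile> %s\n", x$compound_id))
  print(round(x$delta, 3))
  invisible(x)
}

#' Full preprocessing: filter, average, panel-select
#'
#' Applies [clean_library()], [average_profile()] and [select_panel()] over
#' a library and returns the per-compound panel profiles as a matrix.
#'
#' @param records list of `compound_record`s.
#' @param panel a [gene_panel()].
#' @param min_replicates replicate filter threshold (default 7).
#' @param tau ternarization threshold.
#' @return list with `delta` (n x 10 matrix, rownames = compound ids),
#'   `ternary` (n x 10 integer matrix), `records` (the retained records).
#' @export
profile_library <- function(records, panel = default_panel(),
                            min_replicates = 7L, tau = 0.5) {
  kept <- clean_library(records, min_replicates)
  profiles <- lapply(kept, function(r) {
    select_panel(average_profile(r), panel, compound_id = r$compound_id, tau = tau)
  })
  delta <- do.call(rbind, lapply(profiles, `[[`, "delta"))
  ternary <- do.call(rbind, lapply(profiles, `[[`, "ternary"))
  ids <- vapply(profiles, `[[`, character(1), "compound_id")
  if (!is.null(delta)) rownames(delta) <- rownames(ternary) <- ids
  list(delta = delta, ternary = ternary, records = kept)
}

#' Write per-compound panel profiles as CSV
#'
#' @param profiles output of [profile_library()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- data.frame(compound_id = rownames(profiles$delta),
                   profiles$delta, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "compound_id"), drop = FALSE])
  rownames(m) <- df$compound_id
  m
}
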