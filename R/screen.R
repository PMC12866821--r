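#' Primary-screen selection criteria
#'
#' Candidates must score at least `score_threshold` *and* lie strictly more
#' than `sd_multiplier` population standard deviations above the mean of a
#' background score distribution. The background is either the empirical
#' score distribution of the screened library (`"library"`), a seeded
#' within-gene permutation null of the delta matrix (`"permutation_null"`),
#' or disabled (`"none"`, equivalent to `sd_multiplier = 0` against a flat
#' zero background, leaving the score threshold alone).
#'
#' @param score_threshold minimum total score, default 70.
#' @param sd_multiplier number of background SDs a passing score must exceed
#'   the background mean by (strict `>`), default 3.5.
#' @param background one of `"library"`, `"permutation_null"`, `"none"`.
#' @return object of class `primary_criteria`.
#' @export
primary_criteria <- function(score_threshold = 70, sd_multiplier = 3.5,
                             background = c("library", "permutation_null", "none")) {
  background <- match.arg(background)
  if (!is.numeric(score_threshold) || score_threshold < 0 || score_threshold > 100) {
    stop("primary_criteria: `score_threshold` must lie in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(sd_multiplier) || sd_multiplier < 0) {
    stop("primary_criteria: `sd_multiplier` must be >= 0", call. = FALSE)
  }
  structure(list(score_threshold = score_threshold,
                 sd_multiplier = sd_multiplier,
                 background = background),
            class = "primary_criteria")
}

# population (n-denominator) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Primary screen: score threshold plus background significance
#'
#' @param scores integer vector of total scores (0-100) for the screened
#'   compounds.
#' @param criteria a [primary_criteria()].
#' @param background_scores numeric vector of background scores. Required
#'   when `criteria$background != "none"`; for `background = "library"` pass
#'   the library's own scores (the default when omitted), for
#'   `"permutation_null"` pass scores of a permuted delta matrix (see
#'   [permutation_null_scores()]).
#' @return logical pass flags, one per score.
#' @export
primary_screen <- function(scores, criteria = primary_criteria(),
                           background_scores = NULL) {
  if (length(scores) == 0L) stop("primary_screen: empty score input", call. = FALSE)
  pass <- scores >= criteria$score_threshold
  if (criteria$background != "none" && criteria$sd_multiplier > 0) {
    if (is.null(background_scores)) {
      if (criteria$background != "library") {
        stop("primary_screen: `background_scores` required for background = '",
             criteria$background, "'", call. = FALSE)
      }
      background_scores <- scores
    }
    cut <- mean(background_scores) + criteria$sd_multiplier * pop_sd(background_scores)
    pass <- pass & (scores > cut)
  }
  pass
}

#' Seeded within-gene permutation null of a delta matrix
#'
#' Independently permutes each gene column across compounds, destroying the
#' per-compound coherence of the profile while preserving every gene's
#' marginal distribution, then scores the permuted profiles.
#'
#' @param delta n x 10 delta matrix in canonical panel order.
#' @param panel a [gene_panel()].
#' @param seed integer seed for the permutation.
#' @return integer vector of n null scores.
#' @export
permutation_null_scores <- function(delta, panel = default_panel(), seed = 1L) {
  delta <- as_panel_delta_matrix(delta, panel)
  permuted <- with_seed(seed, apply(delta, 2L, sample))
  score_matrix(permuted, panel)$total_score
}

#' Secondary screen: per-class robustness
#'
#' A compound passes the secondary screen when at least `min_per_class` of
#' the 5 IFN genes move up *and* at least `min_per_class` of the 5
#' inflammatory genes move down:
#' \deqn{\sum_i I(\Delta G_i^{IFN} > 0) \ge 3,\quad
#'       \sum_j I(\Delta G_j^{Inflame} < 0) \ge 3}
#' Note this is stricter than any score threshold alone: a profile with all
#' 5 inflammatory genes down but only 2 IFN genes up scores 70 yet fails.
#'
#' @param delta n x 10 delta matrix (or 10-vector) in canonical panel order.
#' @param panel a [gene_panel()].
#' @param min_per_class minimum satisfied indicators per gene class, default 3.
#' @return logical pass flags.
#' @export
secondary_screen <- function(delta, panel = default_panel(), min_per_class = 3L) {
  if (is.null(dim(delta))) delta <- matrix(as_panel_delta(delta, panel), nrow = 1L)
  br <- score_matrix(delta, panel)
  br$ifn_up_count >= min_per_class & br$inflame_down_count >= min_per_class
}

#' Rank dual-pass candidates
#'
#' Only compounds passing both screens receive a rank: descending total
#' score, ties broken by `compound_id` lexicographic ascending; ranks are
#' dense (1..k, no gaps). All other compounds get rank `NA`.
#'
#' @param results data.frame with columns `compound_id`, `total_score`,
#'   `passes_primary`, `passes_secondary`.
#' @return the same data.frame with a `rank` column, reordered so ranked
#'   compounds come first in rank order.
#' @export
rank_candidates <- function(results) {
  required <- c("compound_id", "total_score", "passes_primary", "passes_secondary")
  if (!all(required %in% names(results))) {
    stop("rank_candidates: results must contain ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  results$rank <- NA_integer_
  dual <- which(results$passes_primary & results$passes_secondary)
  if (length(dual) > 0L) {
    ord <- dual[order(-results$total_score[dual], results$compound_id[dual])]
    results$rank[ord] <- seq_along(ord)
  }
  results[order(results$rank, results$compound_id, na.last = TRUE), , drop = FALSE]
}

#' Score and screen a library of delta profiles
#'
#' Runs the full scoring + two-stage screening pipeline over an n x 10
#' delta matrix from any source (model predictions or measured profiles).
#'
#' @param delta n x 10 delta matrix, rownames used as compound ids.
#' @param panel a [gene_panel()].
#' @param criteria a [primary_criteria()].
#' @param min_per_class secondary-screen minimum per gene class.
#' @param seed seed for the permutation null (when selected).
#' @return list with `results` (a ranked data.frame: compound_id,
#'   ifn_up_count, inflame_down_count, total_score, passes_primary,
#'   passes_secondary, rank) and `summary` (background mean/sd, thresholds,
#'   pass counts).
#' @export
screen_library <- function(delta, panel = default_panel(),
                           criteria = primary_criteria(),
                           min_per_class = 3L, seed = 1L) {
  delta <- as_panel_delta_matrix(delta, panel)
  br <- score_matrix(delta, panel)
  background <- switch(criteria$background,
    library          = br$total_score,
    permutation_null = permutation_null_scores(delta, panel, seed),
    none             = numeric(0)
  )
  br$passes_primary <- primary_screen(
    br$total_score, criteria,
    background_scores = if (length(background)) background else NULL
  )
  br$passes_secondary <- secondary_screen(delta, panel, min_per_class)
  results <- rank_candidates(br)
  list(
    results = results,
    summary = list(
      n = nrow(delta),
      score_threshold = criteria$score_threshold,
      sd_multiplier = criteria$sd_multiplier,
      background = criteria$background,
      background_mean = if (length(background)) mean(background) else NA_real_,
      background_sd = if (length(background)) pop_sd(background) else NA_real_,
      n_pass_primary = sum(results$passes_primary),
      n_pass_secondary = sum(results$passes_secondary),
      n_ranked = sum(!is.na(results$rank)),
      min_per_class = min_per_class
    )
  )
}

#' Write a screen report
#'
#' Writes the ranked results as CSV and the summary as JSON.
#'
#' @param screen output of [screen_library()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "screen_results.csv")
  js <- file.path(dir, "screen_summary.json")
  utils::write.csv(screen$results, csv, row.names = FALSE)
  jsonlite::write_json(screen$summary, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results = csv, summary = js))
}
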