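#' Indicator-based immunomodulatory score
#'
#' The hard score awards +10 points for every IFN-block gene with strictly
#' positive predicted change and +10 for every inflammatory-block gene with
#' strictly negative change:
#'
#' \deqn{Score = \sum_{i=1}^{5} I(\Delta G_i^{IFN} > 0)\times 10 +
#'               \sum_{j=1}^{5} I(\Delta G_j^{Inflame} < 0)\times 10}
#'
#' A change of exactly zero never scores. The score therefore lives on
#' `{0, 10, ..., 100}`: 0 means no desired regulatory effect, 100 ideal
#' regulation of all ten genes.
#'
#' @param delta numeric vector of length 10 in canonical panel order (IFN
#'   block first), or a named vector containing all panel genes.
#' @param panel a [gene_panel()].
#' @return A `score_breakdown` list: `ifn_up_count` (0-5),
#'   `inflame_down_count` (0-5), `total_score` (0-100).
#' @examples
#' hard_score(c(1, 1, 1, 1, 1, -1, -1, -1, -1, -1))  # 100
#' hard_score(rep(0, 10))                             # 0
#' @export
hard_score <- function(delta, panel = default_panel()) {
  delta <- as_panel_delta(delta, panel)
  ifn_up <- sum(delta[1:5] > 0)
  inf_down <- sum(delta[6:10] < 0)
  structure(
    list(ifn_up_count = ifn_up,
         inflame_down_count = inf_down,
         total_score = 10L * (ifn_up + inf_down)),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score_breakdown> IFN up %d/5, inflammatory down %d/5, score %d\n",
              x$ifn_up_count, x$inflame_down_count, x$total_score))
  invisible(x)
}

#' Differentiable surrogate of the hard score
#'
#' Replaces each indicator of [hard_score()] by a logistic relaxation with
#' temperature `beta`:
#' \deqn{SoftScore = 10\left(\sum_i \sigma(\beta \Delta_i^{IFN}) +
#'                           \sum_j \sigma(-\beta \Delta_j^{Inflame})\right)}
#' As `beta` grows the surrogate converges to the hard score at every delta
#' with no exact zeros; at delta = 0 each term is 1/2, so the all-zero
#' profile scores exactly 50. Used by the joint training loss, never for
#' screening decisions.
#'
#' @inheritParams hard_score
#' @param temperature positive sharpness `beta` of the logistic relaxation.
#' @return numeric scalar in `[0, 100]`.
#' @export
soft_score <- function(delta, panel = default_panel(), temperature = 10) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    stop("soft_score: `temperature` must be a positive scalar", call. = FALSE)
  }
  delta <- as_panel_delta(delta, panel)
  dir <- as.numeric(panel_directions(panel))
  10 * sum(logistic(temperature * dir * delta))
}

# vectorised scoring over an n x 10 delta matrix -> data.frame of breakdowns
score_matrix <- function(delta, panel = default_panel()) {
  delta <- as_panel_delta_matrix(delta, panel)
  ifn_up <- rowSums(delta[, 1:5, drop = FALSE] > 0)
  inf_down <- rowSums(delta[, 6:10, drop = FALSE] < 0)
  data.frame(
    compound_id = rownames_or_index(delta),
    ifn_up_count = as.integer(ifn_up),
    inflame_down_count = as.integer(inf_down),
    total_score = as.integer(10 * (ifn_up + inf_down)),
    stringsAsFactors = FALSE
  )
}

logistic <- function(x) 1 / (1 + exp(-x))

# coerce a delta input to a 10-vector in canonical panel order; named inputs
# are re-ordered (case-insensitively), unnamed inputs must already be ordered
as_panel_delta <- function(delta, panel) {
  if (!is.numeric(delta)) stop("delta must be numeric", call. = FALSE)
  if (!is.null(names(delta))) {
    delta <- delta[match_panel(panel, names(delta))]
  }
  if (length(delta) != 10L) {
    stop(sprintf("delta must have length 10 (got %d)", length(delta)), call. = FALSE)
  }
  as.numeric(delta)
}

as_panel_delta_matrix <- function(delta, panel) {
  delta <- as.matrix(delta)
  if (!is.null(colnames(delta))) {
    delta <- delta[, match_panel(panel, colnames(delta)), drop = FALSE]
  }
  if (ncol(delta) != 10L) {
    stop(sprintf("delta matrix must have 10 columns (got %d)", ncol(delta)),
         call. = FALSE)
  }
  delta
}

rownames_or_index <- function(m) {
  if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m)))
}
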