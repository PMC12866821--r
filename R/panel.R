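#' The ten-gene innate-immunity panel
#'
#' A `gene_panel` holds the ordered gene panel the screen operates on: five
#' IFN-I / early-response genes whose *upregulation* is rewarded, followed by
#' five NF-kB-driven inflammatory genes whose *downregulation* is rewarded.
#' The canonical order is the IFN block (indices 1-5) then the inflammatory
#' block (indices 6-10); every delta vector and prediction matrix in the
#' package uses this order.
#'
#' Gene-symbol matching throughout the package is case-insensitive, because
#' human and mouse casings (e.g. `IFNB1` vs `Ifnb1`) denote the same panel
#' member.
#'
#' @param ifn_genes character vector of exactly 5 gene symbols (up-regulation
#'   desired).
#' @param inflammatory_genes character vector of exactly 5 gene symbols
#'   (down-regulation desired).
#' @return An object of class `gene_panel` with elements `ifn_genes`,
#'   `inflammatory_genes`.
#' @examples
#' p <- default_panel()
#' panel_genes(p)
#' panel_directions(p)
#' @export
gene_panel <- function(ifn_genes, inflammatory_genes) {
  ifn_genes <- as.character(ifn_genes)
  inflammatory_genes <- as.character(inflammatory_genes)
  if (length(ifn_genes) != 5L) {
    stop("gene_panel: `ifn_genes` must contain exactly 5 symbols", call. = FALSE)
  }
  if (length(inflammatory_genes) != 5L) {
    stop("gene_panel: `inflammatory_genes` must contain exactly 5 symbols", call. = FALSE)
  }
  all10 <- c(toupper(ifn_genes), toupper(inflammatory_genes))
  if (anyDuplicated(all10)) {
    stop("gene_panel: panel genes must be unique (case-insensitive)", call. = FALSE)
  }
  structure(list(ifn_genes = ifn_genes, inflammatory_genes = inflammatory_genes),
            class = "gene_panel")
}

#' @rdname gene_panel
#' @export
default_panel <- function() {
  gene_panel(
    ifn_genes          = c("EGR1", "IFNB1", "ISG15", "IFIT3", "CXCL10"),
    inflammatory_genes = c("IL1B", "IL6", "TNF", "PTGS2", "NOS2")
  )
}

#' @rdname gene_panel
#' @param panel a `gene_panel`.
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "gene_panel"))
  c(panel$ifn_genes, panel$inflammatory_genes)
}

#' Desired-effect directions for the panel
#'
#' +1 for the IFN block (upregulation desired), -1 for the inflammatory block
#' (downregulation desired), in canonical panel order.
#'
#' @param panel a `gene_panel`.
#' @return integer vector of length 10 in `{-1, +1}`.
#' @export
panel_directions <- function(panel) {
  stopifnot(inherits(panel, "gene_panel"))
  stats::setNames(c(rep(1L, 5L), rep(-1L, 5L)), panel_genes(panel))
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel>\n")
  cat("  IFN-I (up desired):        ", paste(x$ifn_genes, collapse = ", "), "\n")
  cat("  inflammatory (down desired):", paste(x$inflammatory_genes, collapse = ", "), "\n")
  invisible(x)
}

# case-insensitive position lookup of panel genes among `universe` names;
# errors naming the first missing gene
match_panel <- function(panel, universe) {
  idx <- match(toupper(panel_genes(panel)), toupper(universe))
  if (anyNA(idx)) {
    missing <- panel_genes(panel)[which(is.na(idx))[1L]]
    stop(sprintf("panel gene '%s' not found in the gene universe", missing),
         call. = FALSE)
  }
  idx
}
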