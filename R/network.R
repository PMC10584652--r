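#' One-hop protein-protein interaction expansion
#'
#' Widens a risk-gene set with its direct interaction partners: edges with
#' `combined_score >= min_score` incident to at least one risk gene are
#' retained, and the expanded set is the union of the risk genes and the
#' endpoints of the retained edges. When a symbol map is supplied, edges
#' with an endpoint absent from the map are dropped first (with a reported
#' count), so the expansion never introduces identifiers the rest of the
#' pipeline cannot resolve.
#'
#' @param risk_genes Character vector of risk-gene symbols, or a data
#'   frame with a `gene_symbol` column.
#' @param edges PPI edge list from [read_ppi_edges()].
#' @param min_score Minimum combined score to trust an edge, in
#'   \[0, 1000\]; default 400 (STRING's medium-confidence cutoff).
#' @param symbol_map Optional symbol-to-id map restricting admissible
#'   endpoints.
#' @return A list with `genes` (expanded symbols, sorted) and `pairs`
#'   (retained edges, endpoints ordered `protein_a <= protein_b`, rows in
#'   lexicographic order).
#' @export
expand_ppi <- function(risk_genes, edges, min_score = 400L,
                       symbol_map = NULL) {
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      min_score < 0 || min_score > 1000)
    stop("min_score must be in [0, 1000], got ", min_score, call. = FALSE)
  if (is.data.frame(risk_genes)) {
    check_cols(risk_genes, "gene_symbol", "risk-gene table")
    risk_genes <- risk_genes$gene_symbol
  }
  risk <- sort(unique(as.character(risk_genes)))
  check_cols(edges, c("protein_a", "protein_b", "combined_score"),
             "PPI edge list")
  if (!length(risk)) {
    warning("empty risk-gene set: nothing to expand", call. = FALSE)
    return(list(genes = character(0),
                pairs = edges[0, c("protein_a", "protein_b",
                                   "combined_score")]))
  }
  if (!is.null(symbol_map)) {
    check_cols(symbol_map, "gene_symbol", "symbol map")
    known <- unique(symbol_map$gene_symbol)
    ok <- edges$protein_a %in% known & edges$protein_b %in% known
    if (any(!ok))
      message("dropped ", sum(!ok), " edge(s) with unmapped endpoints")
    edges <- edges[ok, , drop = FALSE]
  }
  keep <- edges$combined_score >= min_score &
    (edges$protein_a %in% risk | edges$protein_b %in% risk)
  pairs <- edges[keep, c("protein_a", "protein_b", "combined_score"),
                 drop = FALSE]
  if (nrow(pairs)) {
    lo <- pmin(pairs$protein_a, pairs$protein_b)
    hi <- pmax(pairs$protein_a, pairs$protein_b)
    pairs$protein_a <- lo
    pairs$protein_b <- hi
    pairs <- pairs[!duplicated(paste(lo, hi, sep = "\r")), , drop = FALSE]
    pairs <- pairs[order(pairs$protein_a, pairs$protein_b), , drop = FALSE]
  }
  genes <- sort(unique(c(risk, pairs$protein_a, pairs$protein_b)))
  list(genes = genes, pairs = reset_rows(pairs))
}

#' Summarize a network expansion
#'
#' @param risk_genes Risk-gene symbols going into [expand_ppi()].
#' @param expanded Expanded gene symbols (the `genes` element).
#' @param pairs Retained edge table (the `pairs` element).
#' @return A list with counts (`n_risk`, `n_expanded`, `n_added`,
#'   `n_pairs`) and `degree`, a named integer vector of retained-edge
#'   degrees over the expanded genes.
#' @export
summarize_expansion <- function(risk_genes, expanded, pairs) {
  if (is.data.frame(risk_genes)) risk_genes <- risk_genes$gene_symbol
  risk <- unique(as.character(risk_genes))
  if (!all(risk %in% expanded) && length(expanded))
    stop("risk genes must be contained in the expanded set", call. = FALSE)
  deg <- table(factor(c(pairs$protein_a, pairs$protein_b),
                      levels = expanded))
  list(n_risk = length(risk),
       n_expanded = length(expanded),
       n_added = length(setdiff(expanded, risk)),
       n_pairs = nrow(pairs),
       degree = stats::setNames(as.integer(deg), names(deg)))
}
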