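#' Writers for pipeline tables
#'
#' Each writer is the inverse of the corresponding reader: writing a valid
#' table and reading it back yields an equal structure (numeric columns to
#' within representation precision).
#'
#' @param x Data frame in the reader's canonical layout.
#' @param path Output file path.
#' @return The path, invisibly (except [write_bipartite_edges()], which
#'   returns the number of edge rows written).
#' @name writers
NULL

#' @rdname writers
#' @export
write_associations <- function(x, path) {
  check_cols(x, c("rsid", "chromosome", "position", "p_value",
                  "mapped_genes", "study_id"), "association table")
  write_tsv(x, path)
}

#' @rdname writers
#' @export
write_ld_proxies <- function(x, path) {
  check_cols(x, c("query_rsid", "proxy_rsid", "r_squared", "population",
                  "gencode_id", "gene_symbol", "consequence"),
             "LD proxy table")
  write_tsv(x, path)
}

#' @rdname writers
#' @export
write_eqtl <- function(x, path) {
  check_cols(x, c("rsid", "gencode_id", "tissue", "significant"),
             "eQTL table")
  write_tsv(x, path)
}

#' @rdname writers
#' @export
write_go_membership <- function(x, path) {
  check_cols(x, c("category", "term_id", "gencode_id", "term_size"),
             "GO membership table")
  write_tsv(x, path)
}

#' @rdname writers
#' @export
write_pid_list <- function(x, path) {
  write_tsv(data.frame(gene_symbol = x, stringsAsFactors = FALSE), path)
}

#' @rdname writers
#' @export
write_symbol_map <- function(x, path) {
  check_cols(x, c("gene_symbol", "gencode_id"), "symbol map")
  write_tsv(x, path)
}

#' @rdname writers
#' @export
write_ppi_edges <- function(x, path) {
  check_cols(x, c("protein_a", "protein_b", "combined_score"),
             "PPI edge list")
  write_tsv(x, path)
}

#' @rdname writers
#' @export
write_drug_targets <- function(x, path) {
  check_cols(x, c("drug_id", "drug_name", "target_gene",
                  "pharmacological_action", "groups"), "drug-target table")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_trials <- function(x, path) {
  check_cols(x, c("nct_id", "drug_name", "condition", "status"),
             "trial registry")
  write_tsv(x, path)
}

#' @rdname writers
#' @export
write_approvals <- function(x, path) {
  check_cols(x, c("drug_name", "condition", "approval_id"),
             "approval table")
  write_tsv(x, path)
}

#' Write a gene-score table
#'
#' Column layout mirrors the published scoring matrix: GENCODE id, symbol,
#' the six binary criteria in their canonical order, the total score and
#' the risk call.
#'
#' @param scores Output of [score_genes()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_scores <- function(scores, path) {
  check_cols(scores, c("gencode_id", "gene_symbol", flag_columns(),
                       "total", "is_risk"), "score table")
  out <- scores[, c("gencode_id", "gene_symbol", flag_columns(),
                    "total", "is_risk")]
  names(out) <- c("GENCODE_id", "GENCODE_name", "Missense", "Cis_eQTL",
                  "Biological_process", "Cellular_component",
                  "Molecular_function", "PID", "Total_score", "Is_risk")
  write_tsv(out, path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("GENCODE_id", "GENCODE_name", "Missense", "Cis_eQTL",
                    "Biological_process", "Cellular_component",
                    "Molecular_function", "PID", "Total_score", "Is_risk"),
             "score table")
  out <- data.frame(gencode_id = raw$GENCODE_id,
                    gene_symbol = raw$GENCODE_name,
                    stringsAsFactors = FALSE)
  flags <- c("Missense", "Cis_eQTL", "Biological_process",
             "Cellular_component", "Molecular_function", "PID")
  for (i in seq_along(flags)) out[[flag_columns()[i]]] <-
      as.integer(raw[[flags[i]]])
  out$total <- as.integer(raw$Total_score)
  out$is_risk <- as.logical(raw$Is_risk)
  out
}

#' Export the bipartite drug-gene network
#'
#' Writes one row per (drug, target gene) pair with the drug's triage
#' status, the edge-list form of the final gene-drug network figure.
#'
#' @param candidates Classified candidate table from
#'   [classify_drug_status()]; every candidate must have at least one
#'   target gene.
#' @param path Output TSV path.
#' @return The number of edge rows written.
#' @export
write_bipartite_edges <- function(candidates, path) {
  rows <- bipartite_edge_table(candidates)
  write_tsv(rows, path)
  nrow(rows)
}

#' @rdname write_bipartite_edges
#' @export
read_bipartite_edges <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("drug_id", "drug_name", "target_gene", "status"),
             "bipartite edge list")
  reset_rows(raw[, c("drug_id", "drug_name", "target_gene", "status")])
}

# expand a candidate table into per-(drug, gene) rows
bipartite_edge_table <- function(candidates) {
  check_cols(candidates, c("drug_id", "drug_name", "targets", "status"),
             "candidate table")
  targets <- split_field(candidates$targets)
  if (nrow(candidates) && any(lengths(targets) == 0L))
    stop("every drug candidate must have at least one target gene",
         call. = FALSE)
  n <- lengths(targets)
  data.frame(
    drug_id = rep(candidates$drug_id, n),
    drug_name = rep(candidates$drug_name, n),
    target_gene = unlist(targets, use.names = FALSE) %||% character(0),
    status = rep(as.character(candidates$status), n),
    stringsAsFactors = FALSE
  )
}
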