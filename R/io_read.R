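#' Read a GWAS association table
#'
#' Loads one association record per row from a tab-separated snapshot.
#' `rsid` and `p_value` are mandatory; `chromosome`, `position`,
#' `mapped_genes` and `study_id` are carried through when present.
#' P-values must parse to a number in (0, 1]. In strict mode (the default)
#' a malformed p-value is a fatal error naming the offending row; in
#' permissive mode such rows are rejected, counted in the `n_rejected`
#' attribute and reported via [message()].
#'
#' @param path Path to a TSV file.
#' @param dialect Column-mapping descriptor, see [dialect()].
#' @param strict Fail on malformed p-values instead of rejecting rows.
#'
#' @return A data frame with columns `rsid`, `chromosome`, `position`,
#'   `p_value`, `mapped_genes`, `study_id` and attributes `n_input`,
#'   `n_rejected`.
#' @export
read_associations <- function(path, dialect = default_association_dialect(),
                              strict = TRUE) {
  check_file(path)
  raw <- read_tsv_raw(path)
  idx <- resolve_columns(names(raw), dialect, mandatory = c("rsid", "p_value"))
  pick <- function(canon, default = NA_character_) {
    if (is.na(idx[[canon]])) rep(default, nrow(raw)) else raw[[idx[[canon]]]]
  }
  rsid <- trimws(pick("rsid"))
  p_raw <- pick("p_value")
  p <- suppressWarnings(as.numeric(p_raw))
  bad <- which(is.na(p) | p <= 0 | p > 1 | is.na(rsid) | !nzchar(rsid))
  if (length(bad)) {
    if (strict)
      stop("malformed association at row ", bad[1L], " (rsid = '",
           rsid[bad[1L]], "', p-value = '", p_raw[bad[1L]], "')",
           call. = FALSE)
    message("rejected ", length(bad), " association row(s) with malformed ",
            "rsid or p-value")
  }
  out <- data.frame(
    rsid = rsid,
    chromosome = pick("chromosome"),
    position = suppressWarnings(as.integer(pick("position"))),
    p_value = p,
    mapped_genes = pick("mapped_genes", default = ""),
    study_id = pick("study_id", default = ""),
    stringsAsFactors = FALSE
  )
  if (length(bad)) out <- out[-bad, , drop = FALSE]
  out <- reset_rows(out)
  attr(out, "n_input") <- nrow(raw)
  attr(out, "n_rejected") <- length(bad)
  out
}

#' Read a linkage-disequilibrium proxy table
#'
#' HaploReg-style layout: one proxy variant per row, keyed by the query
#' (lead) variant, with the LD r-squared, the reference-panel label, the
#' gene the proxy falls in (GENCODE id and symbol) and the functional
#' consequence. Multi-gene annotations must already be split into one row
#' per gene.
#'
#' @param path Path to a TSV file with columns `query_rsid`, `proxy_rsid`,
#'   `r_squared`, `population`, `gencode_id`, `gene_symbol`, `consequence`.
#' @return A data frame with those columns; `r_squared` validated to [0, 1].
#' @export
read_ld_proxies <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("query_rsid", "proxy_rsid", "r_squared", "population",
                    "gencode_id", "gene_symbol", "consequence"),
             "LD proxy table")
  r2 <- suppressWarnings(as.numeric(raw$r_squared))
  bad <- which(is.na(r2) | r2 < 0 | r2 > 1)
  if (length(bad))
    stop("r_squared outside [0,1] at row ", bad[1L], " ('",
         raw$r_squared[bad[1L]], "')", call. = FALSE)
  raw$r_squared <- r2
  reset_rows(raw)
}

#' Read a cis-eQTL table
#'
#' Expects columns `rsid`, `gencode_id`, `tissue` and either a 0/1
#' `significant` column (pre-thresholded upstream) or a numeric `fdr`
#' column, from which significance is derived at `fdr_threshold`.
#'
#' @param path Path to a TSV file.
#' @param fdr_threshold Used only when no `significant` column is present.
#' @return Data frame with `rsid`, `gencode_id`, `tissue`, `significant`.
#' @export
read_eqtl <- function(path, fdr_threshold = 0.05) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("rsid", "gencode_id", "tissue"), "eQTL table")
  if ("significant" %in% names(raw)) {
    sig <- suppressWarnings(as.integer(raw$significant))
    if (any(is.na(sig) | !sig %in% c(0L, 1L)))
      stop("eQTL 'significant' column must be 0/1", call. = FALSE)
  } else if ("fdr" %in% names(raw)) {
    fdr <- suppressWarnings(as.numeric(raw$fdr))
    if (anyNA(fdr)) stop("eQTL 'fdr' column must be numeric", call. = FALSE)
    sig <- as.integer(fdr < fdr_threshold)
  } else {
    stop("eQTL table needs a 'significant' or 'fdr' column", call. = FALSE)
  }
  data.frame(rsid = raw$rsid, gencode_id = raw$gencode_id,
             tissue = raw$tissue, significant = sig,
             stringsAsFactors = FALSE)
}

#' Read Gene Ontology membership tables
#'
#' One row per (term, gene). The optional `term_size` column gives the
#' term's size in the annotation background; when absent the number of
#' listed member genes is used.
#'
#' @param path Path to a TSV with columns `category` (BP/CC/MF), `term_id`,
#'   `gencode_id` and optionally `term_size`.
#' @return Data frame with `category`, `term_id`, `gencode_id`, `term_size`.
#' @export
read_go_membership <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("category", "term_id", "gencode_id"), "GO membership table")
  if (!all(raw$category %in% c("BP", "CC", "MF")))
    stop("GO category must be one of BP, CC, MF", call. = FALSE)
  if ("term_size" %in% names(raw)) {
    ts <- suppressWarnings(as.integer(raw$term_size))
    if (any(is.na(ts) | ts < 1L))
      stop("term_size must be a positive integer", call. = FALSE)
  } else {
    sizes <- tapply(raw$gencode_id, raw$term_id,
                    function(g) length(unique(g)))
    ts <- as.integer(sizes[raw$term_id])
  }
  data.frame(category = raw$category, term_id = raw$term_id,
             gencode_id = raw$gencode_id, term_size = ts,
             stringsAsFactors = FALSE)
}

#' Read a primary-immunodeficiency gene list
#'
#' @param path Path to a one-column TSV headed `gene_symbol`.
#' @return Character vector of gene symbols.
#' @export
read_pid_list <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, "gene_symbol", "PID gene list")
  unique(trimws(raw$gene_symbol))
}

#' Read a gene symbol-to-identifier map
#'
#' @param path Path to a TSV with columns `gene_symbol`, `gencode_id`.
#' @return Data frame with those two columns.
#' @export
read_symbol_map <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("gene_symbol", "gencode_id"), "symbol map")
  reset_rows(raw[, c("gene_symbol", "gencode_id")])
}

#' Read a protein-protein interaction edge list
#'
#' STRING protein-links layout: whitespace- or tab-separated columns
#' `protein_a`, `protein_b`, `combined_score` (header optional). Scores are
#' coerced to integers and must lie in [0, 1000]. Self-loops are removed
#' with a reported count. With `deduplicate = TRUE` (the default) symmetric
#' duplicates collapse to one undirected edge keeping the maximum score;
#' endpoints are stored with `protein_a <= protein_b` lexicographically.
#'
#' @param path Path to the edge-list file.
#' @param deduplicate Collapse symmetric duplicate edges.
#' @return Data frame `protein_a`, `protein_b`, `combined_score` with
#'   attribute `n_self_loops_removed`.
#' @export
read_ppi_edges <- function(path, deduplicate = TRUE) {
  check_file(path)
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "\\s+")[[1L]]
  has_header <- length(toks) >= 3L &&
    is.na(suppressWarnings(as.numeric(toks[3L])))
  raw <- utils::read.table(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("PPI edge list needs three columns: protein_a protein_b ",
         "combined_score", call. = FALSE)
  sc <- suppressWarnings(as.numeric(raw[[3L]]))
  bad <- which(is.na(sc) | sc < 0 | sc > 1000)
  if (length(bad))
    stop("combined_score outside [0,1000] at row ", bad[1L], " ('",
         raw[[3L]][bad[1L]], "')", call. = FALSE)
  edges <- data.frame(protein_a = as.character(raw[[1L]]),
                      protein_b = as.character(raw[[2L]]),
                      combined_score = as.integer(round(sc)),
                      stringsAsFactors = FALSE)
  self <- edges$protein_a == edges$protein_b
  n_self <- sum(self)
  if (n_self) message("removed ", n_self, " self-loop(s)")
  edges <- edges[!self, , drop = FALSE]
  if (deduplicate && nrow(edges)) {
    lo <- pmin(edges$protein_a, edges$protein_b)
    hi <- pmax(edges$protein_a, edges$protein_b)
    edges$protein_a <- lo
    edges$protein_b <- hi
    key <- paste(lo, hi, sep = "\r")
    maxs <- tapply(edges$combined_score, key, max)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$combined_score <-
      as.integer(maxs[paste(edges$protein_a, edges$protein_b, sep = "\r")])
  }
  edges <- reset_rows(edges)
  attr(edges, "n_self_loops_removed") <- n_self
  edges
}

#' Read a drug-target table
#'
#' DrugBank-style CSV projection, one row per (drug, target) link.
#' `pharmacological_action` must be one of `yes`, `no`, `unknown`;
#' `groups` is a ';'-separated set of approval-group labels. Duplicate
#' (drug_id, target_gene) pairs collapse to the first occurrence.
#'
#' @param path Path to a CSV file with columns `drug_id`, `drug_name`,
#'   `target_gene`, `pharmacological_action`, `groups`.
#' @return Data frame with those columns, unique per (drug_id, target_gene).
#' @export
read_drug_targets <- function(path) {
  check_file(path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  check_cols(raw, c("drug_id", "drug_name", "target_gene",
                    "pharmacological_action", "groups"),
             "drug-target table")
  pa <- tolower(trimws(raw$pharmacological_action))
  if (!all(pa %in% c("yes", "no", "unknown")))
    stop("pharmacological_action must be yes/no/unknown", call. = FALSE)
  raw$pharmacological_action <- pa
  key <- paste(raw$drug_id, raw$target_gene, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message("collapsed ", sum(dup), " duplicate drug-target link(s)")
  reset_rows(raw[!dup, c("drug_id", "drug_name", "target_gene",
                         "pharmacological_action", "groups")])
}

#' Read a clinical-trial registry table
#'
#' @param path Path to a TSV with columns `nct_id`, `drug_name`,
#'   `condition`, `status`. Registry identifiers must match `NCT` + 8
#'   digits; a violation is fatal.
#' @return Data frame with those columns.
#' @export
read_trials <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("nct_id", "drug_name", "condition", "status"),
             "trial registry")
  bad <- which(!grepl("^NCT[0-9]{8}$", raw$nct_id))
  if (length(bad))
    stop("malformed NCT identifier at row ", bad[1L], " ('",
         raw$nct_id[bad[1L]], "')", call. = FALSE)
  reset_rows(raw[, c("nct_id", "drug_name", "condition", "status")])
}

#' Read an approved-indication table
#'
#' @param path Path to a TSV with columns `drug_name`, `condition`,
#'   `approval_id`.
#' @return Data frame with those columns.
#' @export
read_approvals <- function(path) {
  check_file(path)
  raw <- read_tsv_raw(path)
  check_cols(raw, c("drug_name", "condition", "approval_id"),
             "approval table")
  reset_rows(raw[, c("drug_name", "condition", "approval_id")])
}
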