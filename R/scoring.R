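#' Canonical order of the six annotation criteria
#'
#' @return Character vector of the six flag column names, in the order of
#'   the published scoring matrix: missense, cis-eQTL, GO biological
#'   process, GO cellular component, GO molecular function, PID.
#' @export
flag_columns <- function() {
  c("missense", "cis_eqtl", "go_bp", "go_cc", "go_mf", "pid")
}

#' Score genes on the six-criterion annotation matrix
#'
#' Each criterion met awards one point, for a total of 0-6 per gene. Genes
#' whose total reaches `risk_threshold` are called biological risk genes.
#' Output is ranked by descending total score, ties broken by ascending
#' GENCODE id then symbol, which reproduces the published table ordering
#' deterministically.
#'
#' @param flags Data frame with `gencode_id`, `gene_symbol` and the six
#'   0/1 flag columns (see [flag_columns()]), e.g. from [annotate_genes()]
#'   or [table1_fixture()].
#' @param risk_threshold Minimum total for the risk call, in 0..6;
#'   default 2.
#' @return The input with `total` and `is_risk` columns appended, ranked.
#' @examples
#' score_genes(table1_fixture())[1, c("gene_symbol", "total")]
#' @export
score_genes <- function(flags, risk_threshold = 2L) {
  if (!is.numeric(risk_threshold) || length(risk_threshold) != 1L ||
      risk_threshold < 0 || risk_threshold > 6)
    stop("risk_threshold must be in 0..6, got ", risk_threshold,
         call. = FALSE)
  check_cols(flags, c("gencode_id", "gene_symbol", flag_columns()),
             "flag table")
  fm <- as.matrix(flags[, flag_columns(), drop = FALSE])
  storage.mode(fm) <- "integer"
  if (nrow(fm) && !all(fm %in% c(0L, 1L)))
    stop("annotation flags must be 0/1", call. = FALSE)
  out <- flags
  out$total <- as.integer(rowSums(fm))
  out$is_risk <- out$total >= risk_threshold
  reset_rows(out[order(-out$total, out$gencode_id, out$gene_symbol), ,
                 drop = FALSE])
}

#' Call biological risk genes at a score threshold
#'
#' @param scores Ranked score table from [score_genes()].
#' @param threshold Minimum total score, in 0..7 (7 gives the empty set).
#' @return The subset of `scores` with `total >= threshold`, ranking
#'   preserved.
#' @export
call_risk_genes <- function(scores, threshold = 2L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a non-negative integer, got ", threshold,
         call. = FALSE)
  check_cols(scores, "total", "score table")
  reset_rows(scores[scores$total >= threshold, , drop = FALSE])
}
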