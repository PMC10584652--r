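#' Published multiple myeloma scoring matrix
#'
#' The 14 multiple myeloma biological risk genes with their six binary
#' annotation flags (missense, cis-eQTL, GO biological process, cellular
#' component, molecular function, PID), as published. Totals are not
#' stored; [score_genes()] recomputes them.
#'
#' @return Data frame of 14 rows with `gencode_id`, `gene_symbol` and the
#'   six flag columns of [flag_columns()].
#' @examples
#' scores <- score_genes(table1_fixture())
#' nrow(call_risk_genes(scores, 2))  # 14
#' @export
table1_fixture <- function() {
  m <- matrix(c(
    # missense, cis_eqtl, go_bp, go_cc, go_mf, pid
    1, 1, 1, 1, 1, 0,  # RFWD3
    1, 0, 0, 1, 1, 0,  # HMGXB4
    0, 1, 1, 1, 0, 0,  # CDCA7L
    0, 1, 1, 1, 0, 0,  # CCHCR1
    0, 0, 1, 1, 0, 0,  # NCAPH2
    0, 0, 0, 1, 1, 0,  # SRCAP
    0, 1, 0, 1, 0, 0,  # CBX7
    0, 0, 0, 1, 1, 0,  # DTNB
    1, 1, 0, 0, 0, 0,  # PRR14
    1, 1, 0, 0, 0, 0,  # ULK4
    0, 1, 0, 1, 0, 0,  # TRAK1
    1, 1, 0, 0, 0, 0,  # HLA-C
    0, 0, 0, 1, 1, 0,  # POU5F1
    1, 0, 0, 0, 0, 1   # TNFRSF13B
  ), ncol = 6, byrow = TRUE)
  out <- data.frame(
    gencode_id = c("ENSG00000168411", "ENSG00000100281", "ENSG00000164649",
                   "ENSG00000204536", "ENSG00000025770", "ENSG00000080603",
                   "ENSG00000100307", "ENSG00000138101", "ENSG00000156858",
                   "ENSG00000168038", "ENSG00000182606", "ENSG00000204525",
                   "ENSG00000204531", "ENSG00000240505"),
    gene_symbol = c("RFWD3", "HMGXB4", "CDCA7L", "CCHCR1", "NCAPH2",
                    "SRCAP", "CBX7", "DTNB", "PRR14", "ULK4", "TRAK1",
                    "HLA-C", "POU5F1", "TNFRSF13B"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(flag_columns())) out[[flag_columns()[i]]] <-
      as.integer(m[, i])
  out
}

#' Published drug-repurposing evidence for multiple myeloma
#'
#' The nine candidate drugs named in the published analysis, with their
#' target genes (CAMLG or HDAC2), the panobinostat approval for multiple
#' myeloma, and the four registry records for the drugs in clinical trial
#' (cyclosporine NCT04813653, belinostat NCT00131261, vorinostat
#' NCT01502085, romidepsin NCT00765102). Drug identifiers (`D01`..`D09`)
#' and the approval evidence tag are synthetic placeholders; the drug
#' names, target assignments, NCT identifiers and approval are as
#' published.
#'
#' @return A list with `drug_targets`, `approvals` and `trials` tables in
#'   the reader layouts of [read_drug_targets()], [read_approvals()] and
#'   [read_trials()].
#' @examples
#' fx <- paper_drug_fixture()
#' cand <- map_drugs(c("CAMLG", "HDAC2"), fx$drug_targets)
#' cand <- classify_drug_status(cand, fx$approvals, fx$trials)
#' partition_candidates(cand)$counts
#' @export
paper_drug_fixture <- function() {
  drug_targets <- data.frame(
    drug_id = sprintf("D%02d", 1:9),
    drug_name = c("panobinostat", "cyclosporine", "belinostat",
                  "vorinostat", "romidepsin", "theophylline",
                  "aminophylline", "oxtriphylline", "tixocortol"),
    target_gene = c("HDAC2", "CAMLG", "HDAC2", "HDAC2", "HDAC2", "HDAC2",
                    "HDAC2", "HDAC2", "CAMLG"),
    pharmacological_action = c("yes", "yes", "yes", "yes", "yes", "yes",
                               "unknown", "unknown", "unknown"),
    groups = "approved",
    stringsAsFactors = FALSE
  )
  approvals <- data.frame(
    drug_name = "panobinostat",
    condition = "Multiple Myeloma",
    approval_id = "APPROVAL-MM-PANOBINOSTAT",
    stringsAsFactors = FALSE
  )
  trials <- data.frame(
    nct_id = c("NCT04813653", "NCT00131261", "NCT01502085", "NCT00765102"),
    drug_name = c("cyclosporine", "belinostat", "vorinostat", "romidepsin"),
    condition = "Multiple Myeloma",
    status = c("Recruiting", "Completed", "Completed", "Completed"),
    stringsAsFactors = FALSE
  )
  list(drug_targets = drug_targets, approvals = approvals, trials = trials)
}
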