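#' Normalize a drug name for matching
#'
#' Registry and approval tables spell drug names inconsistently. Names are
#' lowercased, trimmed, inner whitespace squeezed, and trailing salt or
#' formulation words stripped repeatedly (e.g. "Belinostat  Sodium" ->
#' "belinostat").
#'
#' @param x Character vector of drug names.
#' @param salts Suffix words to strip.
#' @return Normalized names.
#' @export
normalize_drug_name <- function(x, salts = c(
  "sodium", "hydrochloride", "hcl", "sulfate", "sulphate", "mesylate",
  "acetate", "phosphate", "citrate", "tartrate", "maleate", "besylate")) {
  x <- gsub("\\s+", " ", trimws(tolower(as.character(x))))
  repeat {
    last <- sub("^.*\\s", "", x)
    hit <- grepl(" ", x) & last %in% salts
    if (!any(hit)) break
    x[hit] <- trimws(sub("\\s+\\S+$", "", x[hit]))
  }
  x
}

#' Overlap an expanded gene set with a drug-target table
#'
#' Returns one candidate row per drug with at least one target inside the
#' expanded gene set (gene symbols matched case-insensitively). All
#' targeting links within the set are retained; `pharm_action_any` records
#' whether any of them has known pharmacological action.
#'
#' @param expanded_genes Character vector of gene symbols (e.g. the
#'   `genes` element of [expand_ppi()]).
#' @param drug_targets Drug-target table from [read_drug_targets()].
#' @param pharm_action_only Restrict to links with known pharmacological
#'   action (`pharmacological_action == "yes"`); by default all links are
#'   kept and the action is only annotated via `pharm_action_any`.
#' @return Candidate data frame with columns `drug_id`, `drug_name`,
#'   `targets` (';'-joined, sorted), `n_targets`, `pharm_action_any`,
#'   `status` (`NA`, see [classify_drug_status()]), `evidence` (empty);
#'   ordered by `drug_name`, then `drug_id`.
#' @export
map_drugs <- function(expanded_genes, drug_targets,
                      pharm_action_only = FALSE) {
  check_cols(drug_targets, c("drug_id", "drug_name", "target_gene",
                             "pharmacological_action"), "drug-target table")
  if (pharm_action_only)
    drug_targets <- drug_targets[
      drug_targets$pharmacological_action == "yes", , drop = FALSE]
  up <- toupper(unique(as.character(expanded_genes)))
  hits <- drug_targets[toupper(drug_targets$target_gene) %in% up, ,
                       drop = FALSE]
  ids <- unique(hits$drug_id)
  rows <- lapply(ids, function(d) {
    h <- hits[hits$drug_id == d, , drop = FALSE]
    data.frame(drug_id = d, drug_name = h$drug_name[1L],
               targets = join_field(list(h$target_gene)),
               n_targets = length(unique(h$target_gene)),
               pharm_action_any = any(h$pharmacological_action == "yes"),
               status = NA_character_, evidence = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    drug_id = character(0), drug_name = character(0), targets = character(0),
    n_targets = integer(0), pharm_action_any = logical(0),
    status = character(0), evidence = character(0),
    stringsAsFactors = FALSE))))
  reset_rows(out[order(out$drug_name, out$drug_id), , drop = FALSE])
}

#' Triage candidate drugs by development status for a disease
#'
#' Each candidate is assigned exactly one status with precedence
#' `approved_for_disease` > `in_trial` > `novel`:
#' \describe{
#'   \item{approved_for_disease}{a row in the approved-indication table
#'     matches the drug (normalized name) and the condition;}
#'   \item{in_trial}{at least one registry record matches the drug and the
#'     condition; the matching NCT identifiers are recorded as evidence;}
#'   \item{novel}{no approval and no matching trial.}
#' }
#' Condition matching is a case-insensitive substring test of `condition`
#' against the table's condition field.
#'
#' @param candidates Candidate table from [map_drugs()].
#' @param approvals Approved-indication table from [read_approvals()].
#' @param trials Trial registry from [read_trials()].
#' @param condition Disease name to match; default "multiple myeloma".
#' @return `candidates` with `status` and `evidence` filled in.
#' @export
classify_drug_status <- function(candidates, approvals, trials,
                                 condition = "multiple myeloma") {
  if (!is.character(condition) || length(condition) != 1L ||
      !nzchar(trimws(condition)))
    stop("condition must be a non-empty string", call. = FALSE)
  check_cols(candidates, c("drug_id", "drug_name"), "candidate table")
  check_cols(approvals, c("drug_name", "condition", "approval_id"),
             "approval table")
  check_cols(trials, c("nct_id", "drug_name", "condition"),
             "trial registry")
  cond_hit <- function(x) grepl(condition, x, ignore.case = TRUE,
                                fixed = FALSE)
  apr <- approvals[cond_hit(approvals$condition), , drop = FALSE]
  tri <- trials[cond_hit(trials$condition), , drop = FALSE]
  apr_name <- normalize_drug_name(apr$drug_name)
  tri_name <- normalize_drug_name(tri$drug_name)
  cand_name <- normalize_drug_name(candidates$drug_name)
  status <- character(nrow(candidates))
  evidence <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    a <- which(apr_name == cand_name[i])
    t <- which(tri_name == cand_name[i])
    if (length(a)) {
      status[i] <- "approved_for_disease"
      evidence[i] <- join_field(list(apr$approval_id[a]))
    } else if (length(t)) {
      status[i] <- "in_trial"
      evidence[i] <- join_field(list(tri$nct_id[t]))
    } else {
      status[i] <- "novel"
      evidence[i] <- ""
    }
  }
  candidates$status <- status
  candidates$evidence <- evidence
  candidates
}

#' Partition classified candidates by status
#'
#' @param candidates Classified candidate table; an unclassified candidate
#'   (`NA` status) is a fatal error.
#' @return A list with `counts`, a named integer vector over
#'   (`approved_for_disease`, `in_trial`, `novel`) summing to the
#'   candidate count, and `drugs`, per-status name lists sorted by drug
#'   name.
#' @export
partition_candidates <- function(candidates) {
  check_cols(candidates, c("drug_name", "status"), "candidate table")
  statuses <- c("approved_for_disease", "in_trial", "novel")
  if (any(is.na(candidates$status)) ||
      !all(candidates$status %in% statuses))
    stop("all candidates must be classified before partitioning",
         call. = FALSE)
  counts <- vapply(statuses, function(s) sum(candidates$status == s),
                   integer(1))
  drugs <- lapply(statuses, function(s)
    sort(candidates$drug_name[candidates$status == s]))
  names(drugs) <- statuses
  list(counts = counts, drugs = drugs)
}
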