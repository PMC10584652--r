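#' Pipeline configuration
#'
#' Bundles the input paths, output directory and every threshold of the
#' five-stage pipeline. Defaults are the published study settings:
#' genome-wide significance `p < 1e-8`, LD `r^2 > 0.80` in the 1000
#' Genomes Phase 1 Asian panel, enrichment significance 0.05 over a
#' 20000-gene background, risk call at a total score of 2, STRING
#' medium-confidence interaction cutoff 400, condition "multiple
#' myeloma".
#'
#' @param inputs Named list/vector of input paths with entries
#'   `associations`, `ld_proxies`, `eqtl`, `go_membership`, `pid_list`,
#'   `symbol_map`, `ppi_edges`, `drug_targets`, `approvals`, `trials`
#'   (the names used by [write_bundle()]).
#' @param out_dir Output directory for intermediate tables and the report.
#' @param p_threshold,r2_threshold,population,risk_threshold,alpha,background_n,ppi_min_score,condition
#'   Stage thresholds; see the stage functions for semantics.
#' @param strict Fail on malformed association rows instead of rejecting
#'   them.
#' @param association_dialect Column dialect for the association table.
#' @param seed Recorded in the report for provenance; the pipeline itself
#'   is deterministic.
#' @return A `gw2drug_config` list.
#' @export
pipeline_config <- function(inputs, out_dir,
                            p_threshold = 1e-8, r2_threshold = 0.80,
                            population = "ASN", risk_threshold = 2L,
                            alpha = 0.05, background_n = 20000L,
                            ppi_min_score = 400L,
                            condition = "multiple myeloma",
                            strict = TRUE,
                            association_dialect =
                              default_association_dialect(),
                            seed = 1L) {
  need <- c("associations", "ld_proxies", "eqtl", "go_membership",
            "pid_list", "symbol_map", "ppi_edges", "drug_targets",
            "approvals", "trials")
  inputs <- as.list(inputs)
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("inputs is missing path(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must lie in (0, 1]", call. = FALSE)
  if (r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (risk_threshold < 0 || risk_threshold > 6)
    stop("risk_threshold must lie in 0..6", call. = FALSE)
  if (ppi_min_score < 0 || ppi_min_score > 1000)
    stop("ppi_min_score must lie in [0, 1000]", call. = FALSE)
  if (!nzchar(trimws(condition)))
    stop("condition must be non-empty", call. = FALSE)
  structure(list(inputs = inputs[need], out_dir = out_dir,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 population = population,
                 risk_threshold = as.integer(risk_threshold),
                 alpha = alpha, background_n = as.integer(background_n),
                 ppi_min_score = as.integer(ppi_min_score),
                 condition = condition, strict = isTRUE(strict),
                 association_dialect = association_dialect,
                 seed = as.integer(seed)),
            class = "gw2drug_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The file may set any argument of [pipeline_config()] (with `inputs` as
#' a mapping of the ten table names to paths). `overrides` take precedence
#' over the file, which takes precedence over the defaults.
#'
#' @param path YAML configuration file.
#' @param overrides Named list of argument overrides.
#' @return A `gw2drug_config`.
#' @export
pipeline_config_from_yaml <- function(path, overrides = list()) {
  check_file(path)
  file_args <- yaml::read_yaml(path)
  args <- utils::modifyList(file_args, overrides)
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full repurposing pipeline
#'
#' Executes the five stages in order — significance selection, LD
#' expansion, six-criterion gene scoring, one-hop PPI expansion, drug
#' mapping and triage — writing each intermediate table plus a
#' machine-readable and a human-readable run report under
#' `config$out_dir`. The run is deterministic: identical inputs and
#' configuration give byte-identical outputs, report included.
#'
#' An association file from which nothing passes the significance filter
#' is not an error: the pipeline completes with all-zero downstream counts
#' and a warning.
#'
#' @param config A [pipeline_config()].
#' @return The run report: a list with the configuration echo, per-stage
#'   `counts`, `status_counts`, and the relative `outputs` paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "gw2drug_config"))
    stop("config must come from pipeline_config()", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ins <- config$inputs

  assoc <- run_stage("select", read_associations(
    ins$associations, dialect = config$association_dialect,
    strict = config$strict))
  selected <- run_stage("select", filter_associations(
    assoc, config$p_threshold, strict = TRUE))
  leads <- run_stage("select", deduplicate_snps(selected))
  if (nrow(leads) == 0L)
    warning("no associations passed the significance filter; ",
            "downstream stages will be empty", call. = FALSE)

  ld <- run_stage("expand-ld", read_ld_proxies(ins$ld_proxies))
  proxies <- run_stage("expand-ld", expand_ld(
    leads$rsid, ld, config$r2_threshold, config$population))
  genes <- run_stage("expand-ld", collect_genes(proxies))

  eqtl <- run_stage("score", read_eqtl(ins$eqtl))
  go <- run_stage("score", read_go_membership(ins$go_membership))
  pid <- run_stage("score", read_pid_list(ins$pid_list))
  flags <- run_stage("score", annotate_genes(
    genes, proxies, eqtl, go, pid, alpha = config$alpha,
    background_n = config$background_n))
  scores <- run_stage("score", score_genes(flags, config$risk_threshold))
  risk <- run_stage("score", call_risk_genes(scores,
                                             config$risk_threshold))

  symbol_map <- run_stage("expand-ppi", read_symbol_map(ins$symbol_map))
  ppi <- run_stage("expand-ppi", read_ppi_edges(ins$ppi_edges))
  expansion <- run_stage("expand-ppi", expand_ppi(
    risk$gene_symbol, ppi, config$ppi_min_score, symbol_map))

  drug_targets <- run_stage("map-drugs", read_drug_targets(
    ins$drug_targets))
  approvals <- run_stage("map-drugs", read_approvals(ins$approvals))
  trials <- run_stage("map-drugs", read_trials(ins$trials))
  candidates <- run_stage("map-drugs", map_drugs(expansion$genes,
                                                 drug_targets))
  candidates <- run_stage("map-drugs", classify_drug_status(
    candidates, approvals, trials, config$condition))
  partition <- run_stage("map-drugs", partition_candidates(candidates))

  out <- function(f) file.path(config$out_dir, f)
  write_associations(leads, out("selected_associations.tsv"))
  write_ld_proxies(proxies, out("ld_proxies.tsv"))
  write_tsv(genes[, c("gencode_id", "gene_symbol", "n_proxies")],
            out("genes.tsv"))
  write_scores(scores, out("gene_scores.tsv"))
  write_ppi_edges(expansion$pairs, out("ppi_pairs.tsv"))
  write_tsv(candidates, out("drug_candidates.tsv"))
  n_edges <- write_bipartite_edges(candidates, out("bipartite_edges.tsv"))

  report <- list(
    package = "gw2drug",
    version = as.character(utils::packageVersion("gw2drug")),
    params = list(p_threshold = config$p_threshold,
                  r2_threshold = config$r2_threshold,
                  population = config$population,
                  risk_threshold = config$risk_threshold,
                  alpha = config$alpha,
                  background_n = config$background_n,
                  ppi_min_score = config$ppi_min_score,
                  condition = config$condition,
                  strict = config$strict,
                  seed = config$seed),
    inputs = lapply(ins, as.character),
    counts = list(
      n_associations = attr(assoc, "n_input"),
      n_rejected_rows = attr(assoc, "n_rejected"),
      n_selected = nrow(selected),
      n_lead_snps = nrow(leads),
      n_proxies = nrow(proxies),
      n_genes = nrow(genes),
      n_risk_genes = nrow(risk),
      n_expanded_genes = length(expansion$genes),
      n_ppi_pairs = nrow(expansion$pairs),
      n_drug_candidates = nrow(candidates),
      n_bipartite_edges = n_edges),
    status_counts = as.list(partition$counts),
    drugs = partition$drugs,
    outputs = list(selected_associations = "selected_associations.tsv",
                   ld_proxies = "ld_proxies.tsv",
                   genes = "genes.tsv",
                   gene_scores = "gene_scores.tsv",
                   ppi_pairs = "ppi_pairs.tsv",
                   drug_candidates = "drug_candidates.tsv",
                   bipartite_edges = "bipartite_edges.tsv"))
  render_report(report, out("report.json"))
  report
}

#' Write a run report
#'
#' Writes the machine-readable report as JSON at `path` and a
#' human-readable text rendering alongside it (same name, `.txt`
#' extension). The JSON re-parses to an equal structure via
#' [read_report()].
#'
#' @param report Report list from [run_pipeline()].
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- paste0(tools::file_path_sans_ext(path), ".txt")
  fmt_kv <- function(x) sprintf("  %-22s %s", names(x),
                                vapply(x, function(v)
                                  paste(format(v), collapse = ", "),
                                  character(1)))
  lines <- c(
    sprintf("%s %s run report", report$package, report$version),
    "", "Parameters:", fmt_kv(report$params),
    "", "Stage counts:", fmt_kv(report$counts),
    "", "Drug status partition:", fmt_kv(report$status_counts),
    "", "Outputs:", fmt_kv(report$outputs))
  writeLines(lines, txt)
  invisible(path)
}

#' @rdname render_report
#' @export
read_report <- function(path) {
  check_file(path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
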