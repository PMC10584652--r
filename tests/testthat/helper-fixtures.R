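# small in-code builders shared across the suite

assoc_df <- function(rsid, p, gene = "", study = "S1") {
  data.frame(rsid = rsid, chromosome = "1", position = seq_along(rsid),
             p_value = p, mapped_genes = gene, study_id = study,
             stringsAsFactors = FALSE)
}

ld_df <- function(query, proxy, r2, pop = "ASN", gid = "", sym = "",
                  csq = "intronic") {
  data.frame(query_rsid = query, proxy_rsid = proxy, r_squared = r2,
             population = pop, gencode_id = gid, gene_symbol = sym,
             consequence = csq, stringsAsFactors = FALSE)
}

gene_df <- function(ids, syms = ids) {
  data.frame(gencode_id = ids, gene_symbol = syms, stringsAsFactors = FALSE)
}

edge_df <- function(a, b, s) {
  data.frame(protein_a = a, protein_b = b, combined_score = as.integer(s),
             stringsAsFactors = FALSE)
}

# independent enumeration oracle for the upper-tail hypergeometric
hg_tail_enum <- function(k, K, n, N) {
  i <- 0:min(K, n)
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(pmf[i >= k])
}

# a small planted-truth generator configuration, cheap enough to replay
# end-to-end many times
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_snps = 40L, n_genes = 12L, n_risk_genes = 4L, ld_block_mean = 4,
         ppi_noise_edges = 10L, n_decoy_terms = c(BP = 3L, CC = 3L, MF = 3L),
         seed = seed),
    list(...))
  do.call(generator_config, args)
}

# write a bundle to disk and run the installed pipeline over it
run_bundle <- function(bundle, out_dir = tempfile("gw2drug-out"),
                       bundle_dir = tempfile("gw2drug-bundle")) {
  dir <- bundle_dir
  paths <- write_bundle(bundle, dir)
  cfg <- bundle$config
  pc <- pipeline_config(
    inputs = paths[setdiff(names(paths), "manifest")], out_dir = out_dir,
    p_threshold = cfg$p_threshold, r2_threshold = cfg$r2_threshold,
    population = cfg$population, risk_threshold = cfg$risk_threshold,
    alpha = cfg$alpha, background_n = cfg$background_n,
    ppi_min_score = cfg$ppi_min_score, condition = cfg$condition)
  report <- suppressWarnings(suppressMessages(run_pipeline(pc)))
  list(report = report, out_dir = out_dir, bundle_dir = dir,
       paths = paths, config = pc)
}

# does the written pipeline output reproduce the bundle's planted manifest?
manifest_recovered <- function(bundle, run) {
  m <- bundle$manifest
  scores <- read_scores(file.path(run$out_dir, "gene_scores.tsv"))
  flags <- scores[order(scores$gencode_id),
                  c("gencode_id", "gene_symbol", flag_columns())]
  rownames(flags) <- NULL
  ok_flags <- isTRUE(all.equal(flags, m$flag_matrix,
                               check.attributes = FALSE))
  risk <- call_risk_genes(score_genes(flags,
                                      bundle$config$risk_threshold),
                          bundle$config$risk_threshold)
  ok_risk <- identical(sort(risk$gencode_id), m$risk_genes)
  cand <- utils::read.delim(file.path(run$out_dir, "drug_candidates.tsv"),
                            colClasses = "character")
  ok_drugs <- identical(cand$drug_name, m$drugs$drug_name) &&
    identical(cand$status, m$drugs$status) &&
    identical(cand$targets, m$drugs$targets)
  ok_exp <- run$report$counts$n_expanded_genes == length(m$expanded_genes) &&
    run$report$counts$n_ppi_pairs == m$n_pairs
  ok_flags && ok_risk && ok_drugs && ok_exp
}
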