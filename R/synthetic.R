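#' Configuration for the synthetic fixture generator
#'
#' Describes one internally consistent study: how many association rows to
#' draw, what fraction reach genome-wide significance, how many genes the
#' significant loci cover, how many of those are planted as risk genes,
#' LD-block geometry, per-criterion flag prevalences, interaction-network
#' density and the drug-status mix. The defaults emulate the published
#' multiple myeloma study: 72 significant lead SNPs, 63 candidate genes,
#' 14 risk genes, per-criterion prevalences matching the published counts
#' (missense 11, cis-eQTL 19, BP 4, CC 11, MF 5, PID 2 of 63), LD blocks
#' averaging 35 proxies so the proxy count is of order a few thousand, and
#' a 1 approved / 4 in-trial / 5 novel drug mix. The seed fully determines
#' the generated bundle.
#'
#' @param n_snps Total association rows drawn.
#' @param fraction_significant Fraction of rows below genome-wide
#'   significance.
#' @param n_genes Candidate gene pool size; significant loci are assigned
#'   to genes round-robin, so the realized candidate set is
#'   `min(n_genes, n_significant)`.
#' @param n_risk_genes Genes planted with a total score at or above
#'   `risk_threshold`; all others total strictly below it.
#' @param n_decoy_terms Per-category counts of non-enriched decoy GO terms.
#' @param ld_block_mean Mean high-LD proxies per significant lead SNP.
#' @param r2_high,r2_low Uniform ranges for above- and below-threshold
#'   proxy r-squared values; `r2_high[1]` must exceed `r2_threshold` and
#'   `r2_low[2]` must not.
#' @param flag_prevalence Named sampling weights over [flag_columns()]
#'   used when choosing which criteria a gene meets.
#' @param ppi_neighbors_mean Mean interaction partners planted per risk
#'   gene (at least one each).
#' @param ppi_noise_edges Count of non-qualifying noise edges.
#' @param status_mix Named integer vector (`approved`, `in_trial`,
#'   `novel`) of planted candidate drugs per status.
#' @param target_multiplicity Maximum targets sampled per drug.
#' @param n_decoy_drugs Drugs targeting only genes outside the expanded
#'   set (must not surface as candidates).
#' @param background_n,alpha,p_threshold,r2_threshold,population,risk_threshold,ppi_min_score,condition
#'   Pipeline thresholds the bundle is planted against.
#' @param seed Integer seed; same seed, same bundle, byte for byte.
#' @return A `gw2drug_generator_config` list.
#' @export
generator_config <- function(n_snps = 120L, fraction_significant = 0.6,
                             n_genes = 63L, n_risk_genes = 14L,
                             n_decoy_terms = c(BP = 8L, CC = 8L, MF = 8L),
                             ld_block_mean = 35, r2_high = c(0.85, 1),
                             r2_low = c(0.2, 0.75),
                             flag_prevalence = c(missense = 11, cis_eqtl = 19,
                                                 go_bp = 4, go_cc = 11,
                                                 go_mf = 5, pid = 2) / 63,
                             ppi_neighbors_mean = 2, ppi_noise_edges = 30L,
                             status_mix = c(approved = 1L, in_trial = 4L,
                                            novel = 5L),
                             target_multiplicity = 2L, n_decoy_drugs = 3L,
                             background_n = 20000L, alpha = 0.05,
                             p_threshold = 1e-8, r2_threshold = 0.80,
                             population = "ASN", risk_threshold = 2L,
                             ppi_min_score = 400L,
                             condition = "multiple myeloma", seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps),
              fraction_significant = fraction_significant,
              n_genes = as.integer(n_genes),
              n_risk_genes = as.integer(n_risk_genes),
              n_decoy_terms = n_decoy_terms, ld_block_mean = ld_block_mean,
              r2_high = r2_high, r2_low = r2_low,
              flag_prevalence = flag_prevalence,
              ppi_neighbors_mean = ppi_neighbors_mean,
              ppi_noise_edges = as.integer(ppi_noise_edges),
              status_mix = status_mix,
              target_multiplicity = as.integer(target_multiplicity),
              n_decoy_drugs = as.integer(n_decoy_drugs),
              background_n = as.integer(background_n), alpha = alpha,
              p_threshold = p_threshold, r2_threshold = r2_threshold,
              population = population,
              risk_threshold = as.integer(risk_threshold),
              ppi_min_score = as.integer(ppi_min_score),
              condition = condition, seed = as.integer(seed))
  if (cfg$fraction_significant < 0 || cfg$fraction_significant > 1)
    stop("fraction_significant must lie in [0, 1]", call. = FALSE)
  if (any(cfg$flag_prevalence < 0) ||
      !setequal(names(cfg$flag_prevalence), flag_columns()))
    stop("flag_prevalence needs non-negative weights named ",
         paste(flag_columns(), collapse = ", "), call. = FALSE)
  if (cfg$n_risk_genes > cfg$n_genes)
    stop("infeasible config: more risk genes (", cfg$n_risk_genes,
         ") than genes (", cfg$n_genes, ")", call. = FALSE)
  if (cfg$risk_threshold < 1L || cfg$risk_threshold > 6L)
    stop("risk_threshold must be in 1..6 for flag planting", call. = FALSE)
  if (cfg$r2_threshold >= 1 || cfg$r2_high[1] <= cfg$r2_threshold ||
      cfg$r2_low[2] > cfg$r2_threshold)
    stop("infeasible config: need r2_low[2] <= r2_threshold < r2_high[1] < 1",
         call. = FALSE)
  if (!setequal(names(cfg$status_mix), c("approved", "in_trial", "novel")))
    stop("status_mix needs counts named approved, in_trial, novel",
         call. = FALSE)
  structure(cfg, class = "gw2drug_generator_config")
}

#' Generate a synthetic fixture bundle with planted ground truth
#'
#' Builds every input table the pipeline consumes — associations, LD
#' proxies, whole-blood cis-eQTLs, GO memberships, a PID list, a symbol
#' map, a PPI edge list, drug targets, approvals and a trial registry —
#' together with a manifest of the planted truth (candidate genes, flag
#' matrix, risk genes, expanded gene set, candidate drugs with statuses).
#' Replaying the full pipeline on the bundle at the config's thresholds
#' reproduces the manifest exactly; the generator verifies the planted GO
#' enrichment is achievable and redraws internally (deterministically from
#' the seed) in the rare case it is not.
#'
#' Significant lead p-values are drawn log-uniform on (1e-30, 1e-9) and
#' non-significant ones uniform on (1e-7, 1), keeping a clean margin
#' around the significance boundary; boundary-exact cases belong to
#' dedicated boundary tests, not to generated bundles.
#'
#' @param config A [generator_config()].
#' @return A `FixtureBundle`: list of the ten input tables plus `manifest`
#'   and `config`.
#' @examples
#' b <- generate_bundle(generator_config(n_snps = 30, n_genes = 8,
#'                                       n_risk_genes = 3, seed = 7))
#' b$manifest$risk_genes
#' @export
generate_bundle <- function(config = generator_config()) {
  if (!inherits(config, "gw2drug_generator_config"))
    stop("config must come from generator_config()", call. = FALSE)
  n_sig <- round(config$fraction_significant * config$n_snps)
  n_cand <- min(config$n_genes, n_sig)
  if (config$n_risk_genes > n_cand)
    stop("infeasible config: ", config$n_risk_genes, " risk genes but only ",
         n_cand, " candidate genes reachable from ", n_sig,
         " significant SNPs", call. = FALSE)
  for (attempt in 0:9) {
    bundle <- withr::with_seed(config$seed + attempt * 1000003L,
                               generate_bundle_impl(config, n_sig, n_cand))
    if (!is.null(bundle)) return(bundle)
  }
  stop("could not plant an achievable GO enrichment in 10 draws",
       call. = FALSE)
}

# one full draw; returns NULL when the planted GO flags fail verification
generate_bundle_impl <- function(cfg, n_sig, n_cand) {
  gene_id <- function(i) sprintf("ENSG%011d", 100000L + i)
  gene_sym <- function(i) sprintf("GENE%04d", i)
  genes <- data.frame(gencode_id = gene_id(seq_len(cfg$n_genes)),
                      gene_symbol = gene_sym(seq_len(cfg$n_genes)),
                      stringsAsFactors = FALSE)

  # fresh rsID supply
  rs_counter <- new.env(parent = emptyenv())
  rs_counter$i <- 0L
  next_rs <- function(n) {
    out <- sprintf("rs%07d", rs_counter$i + seq_len(n))
    rs_counter$i <- rs_counter$i + n
    out
  }

  ## --- associations -------------------------------------------------
  rsids <- next_rs(cfg$n_snps)
  sig_idx <- if (n_sig) sort(sample.int(cfg$n_snps, n_sig)) else integer(0)
  p <- stats::runif(cfg$n_snps, 1e-7, 1)
  p[sig_idx] <- 10^stats::runif(n_sig, -30, -9)
  seed_gene <- integer(0)
  if (n_sig) seed_gene <- ((seq_len(n_sig) - 1L) %% n_cand) + 1L
  mapped <- rep("", cfg$n_snps)
  mapped[sig_idx] <- genes$gene_symbol[seed_gene]
  assoc <- data.frame(
    rsid = rsids, chromosome = as.character(sample.int(22L, cfg$n_snps,
                                                       replace = TRUE)),
    position = sample.int(2e8L, cfg$n_snps, replace = TRUE),
    p_value = p, mapped_genes = mapped,
    study_id = sprintf("GCST%06d", sample.int(999999L, cfg$n_snps,
                                              replace = TRUE)),
    stringsAsFactors = FALSE)
  # cross-study duplicates of a couple of leads, weaker p, to exercise dedup
  if (n_sig >= 2) {
    dup <- assoc[sig_idx[1:2], , drop = FALSE]
    dup$p_value <- dup$p_value * 5
    dup$study_id <- sprintf("GCST%06d", sample.int(999999L, 2))
    assoc <- rbind(assoc, dup)
  }

  ## --- LD proxies ----------------------------------------------------
  n_ld_decoys <- 10L
  ld_decoy <- data.frame(gencode_id = gene_id(900000L + seq_len(n_ld_decoys)),
                         gene_symbol = sprintf("LDDECOY%02d",
                                               seq_len(n_ld_decoys)),
                         stringsAsFactors = FALSE)
  csq_pool <- c("intronic", "intergenic", "synonymous")
  ld_rows <- vector("list", n_sig)
  for (j in seq_len(n_sig)) {
    g <- seed_gene[j]
    seed <- rsids[sig_idx[j]]
    m_hi <- stats::rpois(1L, cfg$ld_block_mean)
    m_lo <- stats::rpois(1L, max(1, cfg$ld_block_mean * 0.3))
    hi <- data.frame(
      query_rsid = seed,
      proxy_rsid = c(seed, next_rs(m_hi)),
      r_squared = c(1, stats::runif(m_hi, cfg$r2_high[1], cfg$r2_high[2])),
      population = cfg$population,
      gencode_id = genes$gencode_id[g], gene_symbol = genes$gene_symbol[g],
      consequence = sample(csq_pool, m_hi + 1L, replace = TRUE,
                           prob = c(0.7, 0.2, 0.1)),
      stringsAsFactors = FALSE)
    lo <- NULL
    if (m_lo > 0) {
      dk <- sample.int(n_ld_decoys, m_lo, replace = TRUE)
      lo <- data.frame(
        query_rsid = seed, proxy_rsid = next_rs(m_lo),
        r_squared = stats::runif(m_lo, cfg$r2_low[1], cfg$r2_low[2]),
        population = cfg$population,
        gencode_id = ld_decoy$gencode_id[dk],
        gene_symbol = ld_decoy$gene_symbol[dk],
        consequence = sample(csq_pool, m_lo, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    other <- hi[seq_len(min(2L, nrow(hi))), , drop = FALSE]
    other$population <- "EUR"
    ld_rows[[j]] <- rbind(hi, lo, other)
  }
  ld <- do.call(rbind, c(ld_rows, list(data.frame(
    query_rsid = character(0), proxy_rsid = character(0),
    r_squared = numeric(0), population = character(0),
    gencode_id = character(0), gene_symbol = character(0),
    consequence = character(0), stringsAsFactors = FALSE))))

  ## --- planted flags -------------------------------------------------
  cand <- genes[seq_len(n_cand), , drop = FALSE]
  risk_rows <- sort(sample.int(n_cand, cfg$n_risk_genes))
  totals <- integer(n_cand)
  hi_range <- cfg$risk_threshold:6L
  lo_range <- 0:(cfg$risk_threshold - 1L)
  totals[risk_rows] <- resample(hi_range, cfg$n_risk_genes, replace = TRUE,
                                prob = 0.5^seq_along(hi_range))
  totals[-risk_rows] <- resample(lo_range, n_cand - cfg$n_risk_genes,
                                 replace = TRUE,
                                 prob = 0.6^rev(seq_along(lo_range)))
  prev <- cfg$flag_prevalence[flag_columns()] + 1e-9
  fm <- matrix(0L, nrow = n_cand, ncol = 6L,
               dimnames = list(NULL, flag_columns()))
  for (i in seq_len(n_cand)) {
    if (totals[i])
      fm[i, sample(flag_columns(), totals[i], prob = prev)] <- 1L
  }
  flags <- cbind(cand, as.data.frame(fm), stringsAsFactors = FALSE)

  # plant missense consequences on the lead's own row for flagged genes
  for (g in which(fm[, "missense"] == 1L)) {
    seed <- rsids[sig_idx[match(g, seed_gene)]]
    row <- which(ld$query_rsid == seed & ld$proxy_rsid == seed &
                   ld$population == cfg$population)[1L]
    ld$consequence[row] <- "missense"
  }
  # and make sure unflagged candidate genes carry none
  unflagged <- cand$gencode_id[fm[, "missense"] == 0L]
  stray <- ld$gencode_id %in% unflagged & ld$consequence == "missense"
  ld$consequence[stray] <- "intronic"

  ## --- eQTL ----------------------------------------------------------
  lead_rs <- function(g) rsids[sig_idx[match(g, seed_gene)]]
  eq_rows <- list()
  for (g in which(fm[, "cis_eqtl"] == 1L))
    eq_rows[[length(eq_rows) + 1L]] <- data.frame(
      rsid = lead_rs(g), gencode_id = cand$gencode_id[g],
      tissue = "whole blood", significant = 1L, stringsAsFactors = FALSE)
  for (g in utils::head(which(fm[, "cis_eqtl"] == 0L), 3L)) {
    eq_rows[[length(eq_rows) + 1L]] <- data.frame(
      rsid = lead_rs(g), gencode_id = cand$gencode_id[g],
      tissue = c("liver", "whole blood"), significant = c(1L, 0L),
      stringsAsFactors = FALSE)
  }
  eqtl <- do.call(rbind, c(eq_rows, list(data.frame(
    rsid = character(0), gencode_id = character(0), tissue = character(0),
    significant = integer(0), stringsAsFactors = FALSE))))

  ## --- GO membership -------------------------------------------------
  go_rows <- list()
  decoy_size <- max(2L, round(cfg$background_n / 4))
  for (cat in c("BP", "CC", "MF")) {
    col <- c(BP = "go_bp", CC = "go_cc", MF = "go_mf")[[cat]]
    members <- cand$gencode_id[fm[, col] == 1L]
    if (length(members))
      go_rows[[length(go_rows) + 1L]] <- data.frame(
        category = cat, term_id = sprintf("GO:%s0000001", cat),
        gencode_id = members, term_size = length(members),
        stringsAsFactors = FALSE)
    nonmembers <- cand$gencode_id[fm[, col] == 0L]
    n_decoy <- cfg$n_decoy_terms[[cat]]
    if (length(nonmembers) && n_decoy > 0) {
      for (t in seq_len(n_decoy)) {
        picked <- sample(nonmembers, min(2L, length(nonmembers)))
        go_rows[[length(go_rows) + 1L]] <- data.frame(
          category = cat, term_id = sprintf("GO:%s%07d", cat, 1000L + t),
          gencode_id = picked, term_size = decoy_size,
          stringsAsFactors = FALSE)
      }
    }
  }
  go <- do.call(rbind, c(go_rows, list(data.frame(
    category = character(0), term_id = character(0),
    gencode_id = character(0), term_size = integer(0),
    stringsAsFactors = FALSE))))

  ## --- PID list -------------------------------------------------------
  pid <- c(cand$gene_symbol[fm[, "pid"] == 1L],
           c("PIDDECOY1", "PIDDECOY2", "PIDDECOY3"))

  ## --- verify planted annotation is recoverable -----------------------
  proxies <- expand_ld(assoc$rsid[assoc$p_value < cfg$p_threshold], ld,
                       cfg$r2_threshold, cfg$population)
  got <- annotate_genes(collect_genes(proxies), proxies, eqtl, go, pid,
                        alpha = cfg$alpha, background_n = cfg$background_n)
  want <- flags[order(flags$gencode_id), c("gencode_id", "gene_symbol",
                                           flag_columns())]
  if (!isTRUE(all.equal(reset_rows(want), reset_rows(got),
                        check.attributes = FALSE)))
    return(NULL)  # infeasible draw; caller reseeds

  ## --- PPI ------------------------------------------------------------
  risk <- cand[risk_rows, , drop = FALSE]
  n_risk <- nrow(risk)
  nbr_per <- if (n_risk) pmax(1L, stats::rpois(n_risk,
                                               cfg$ppi_neighbors_mean))
             else integer(0)
  n_nbr <- sum(nbr_per)
  nbr <- data.frame(gencode_id = gene_id(500000L + seq_len(n_nbr)),
                    gene_symbol = sprintf("NBR%04d", seq_len(n_nbr)),
                    stringsAsFactors = FALSE)
  ppi_decoy_sym <- sprintf("PPIDECOY%02d", 1:6)
  edge_rows <- list()
  off <- 0L
  for (i in seq_len(n_risk)) {
    k <- nbr_per[i]
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      protein_a = risk$gene_symbol[i],
      protein_b = nbr$gene_symbol[off + seq_len(k)],
      combined_score = resample(seq.int(cfg$ppi_min_score, 1000L), k,
                                replace = TRUE),
      stringsAsFactors = FALSE)
    off <- off + k
  }
  n_noise <- cfg$ppi_noise_edges
  if (n_noise > 0) {
    nonrisk_sym <- c(setdiff(cand$gene_symbol, risk$gene_symbol),
                     ppi_decoy_sym)
    # below-threshold edges touching risk genes, plus high-score edges
    # that never touch a risk gene: neither may enlarge the expansion
    low_n <- if (n_risk) ceiling(n_noise / 2) else 0L
    if (low_n > 0 && cfg$ppi_min_score > 0)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        protein_a = sample(risk$gene_symbol, low_n, replace = TRUE),
        protein_b = sample(ppi_decoy_sym, low_n, replace = TRUE),
        combined_score = sample.int(cfg$ppi_min_score, low_n,
                                    replace = TRUE) - 1L,
        stringsAsFactors = FALSE)
    high_n <- n_noise - if (n_risk && cfg$ppi_min_score > 0) low_n else 0L
    if (high_n > 0 && length(nonrisk_sym) >= 2)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        protein_a = sample(nonrisk_sym, high_n, replace = TRUE),
        protein_b = sample(nonrisk_sym, high_n, replace = TRUE),
        combined_score = sample.int(1000L, high_n, replace = TRUE),
        stringsAsFactors = FALSE)
  }
  ppi <- do.call(rbind, c(edge_rows, list(data.frame(
    protein_a = character(0), protein_b = character(0),
    combined_score = integer(0), stringsAsFactors = FALSE))))
  ppi <- ppi[ppi$protein_a != ppi$protein_b, , drop = FALSE]
  expanded <- sort(unique(c(risk$gene_symbol, nbr$gene_symbol)))
  n_pairs <- sum(nbr_per)

  ## --- drugs ----------------------------------------------------------
  mix <- cfg$status_mix
  n_drugs <- if (length(expanded)) sum(mix) else 0L
  status <- rep(c("approved_for_disease", "in_trial", "novel"),
                times = if (n_drugs) c(mix[["approved"]], mix[["in_trial"]],
                                       mix[["novel"]]) else c(0L, 0L, 0L))
  drug_name <- sprintf("drug%02d", seq_len(n_drugs))
  dt_rows <- list()
  apr_rows <- list()
  tri_rows <- list()
  nct_pool <- sprintf("NCT%08d", sample.int(99999999L, n_drugs * 2L))
  disease <- "Multiple Myeloma"
  targets <- vector("list", n_drugs)
  for (i in seq_len(n_drugs)) {
    tg <- sample(expanded, sample.int(min(cfg$target_multiplicity,
                                          length(expanded)), 1L))
    targets[[i]] <- sort(tg)
    dt_rows[[length(dt_rows) + 1L]] <- data.frame(
      drug_id = sprintf("SD%03d", i), drug_name = drug_name[i],
      target_gene = tg,
      pharmacological_action = sample(c("yes", "no", "unknown"), length(tg),
                                      replace = TRUE, prob = c(.5, .2, .3)),
      groups = "approved", stringsAsFactors = FALSE)
    if (status[i] == "approved_for_disease") {
      apr_rows[[length(apr_rows) + 1L]] <- data.frame(
        drug_name = drug_name[i], condition = disease,
        approval_id = sprintf("APR%03d", i), stringsAsFactors = FALSE)
      # approved drugs often also appear in the registry; precedence wins
      tri_rows[[length(tri_rows) + 1L]] <- data.frame(
        nct_id = nct_pool[2L * i], drug_name = drug_name[i],
        condition = disease, status = "Completed", stringsAsFactors = FALSE)
    } else if (status[i] == "in_trial") {
      reg_name <- if (isTRUE(i == which(status == "in_trial")[1L]))
        paste(drug_name[i], "sodium") else drug_name[i]
      tri_rows[[length(tri_rows) + 1L]] <- data.frame(
        nct_id = nct_pool[2L * i - 1L], drug_name = reg_name,
        condition = disease, status = "Recruiting",
        stringsAsFactors = FALSE)
    } else if (i %% 2L == 0L) {
      # some novel drugs are trialled for other diseases only
      tri_rows[[length(tri_rows) + 1L]] <- data.frame(
        nct_id = nct_pool[2L * i - 1L], drug_name = drug_name[i],
        condition = "Cutaneous T-Cell Lymphoma", status = "Completed",
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(cfg$n_decoy_drugs)) {
    dt_rows[[length(dt_rows) + 1L]] <- data.frame(
      drug_id = sprintf("SDX%03d", i),
      drug_name = sprintf("decoydrug%02d", i),
      target_gene = ppi_decoy_sym[(i - 1L) %% length(ppi_decoy_sym) + 1L],
      pharmacological_action = "yes", groups = "approved",
      stringsAsFactors = FALSE)
  }
  empty_dt <- data.frame(drug_id = character(0), drug_name = character(0),
                         target_gene = character(0),
                         pharmacological_action = character(0),
                         groups = character(0), stringsAsFactors = FALSE)
  drug_targets <- do.call(rbind, c(dt_rows, list(empty_dt)))
  approvals <- do.call(rbind, c(apr_rows, list(data.frame(
    drug_name = character(0), condition = character(0),
    approval_id = character(0), stringsAsFactors = FALSE))))
  trials <- do.call(rbind, c(tri_rows, list(data.frame(
    nct_id = character(0), drug_name = character(0),
    condition = character(0), status = character(0),
    stringsAsFactors = FALSE))))

  symbol_map <- rbind(genes, ld_decoy, nbr,
                      data.frame(gencode_id = gene_id(700000L +
                                                        seq_along(ppi_decoy_sym)),
                                 gene_symbol = ppi_decoy_sym,
                                 stringsAsFactors = FALSE))

  manifest <- list(
    n_significant = n_sig,
    candidate_genes = reset_rows(cand[order(cand$gencode_id),
                                      c("gencode_id", "gene_symbol")]),
    flag_matrix = reset_rows(want),
    risk_genes = sort(risk$gencode_id),
    expanded_genes = expanded,
    n_pairs = n_pairs,
    drugs = {
      d <- data.frame(drug_name = drug_name, status = status,
                      targets = join_field(targets),
                      stringsAsFactors = FALSE)
      reset_rows(d[order(d$drug_name), , drop = FALSE])
    })

  list(config = cfg, associations = assoc, ld_proxies = ld, eqtl = eqtl,
       go_membership = go, pid_list = pid, symbol_map = symbol_map,
       ppi_edges = reset_rows(ppi), drug_targets = drug_targets,
       approvals = approvals, trials = trials, manifest = manifest)
}

#' Write a fixture bundle to disk
#'
#' Emits every table of a [generate_bundle()] result in the reader
#' dialects of the io module, plus the planted-truth manifest as JSON.
#'
#' @param bundle A `FixtureBundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    associations = file.path(dir, "associations.tsv"),
    ld_proxies = file.path(dir, "ld_proxies.tsv"),
    eqtl = file.path(dir, "eqtl.tsv"),
    go_membership = file.path(dir, "go_membership.tsv"),
    pid_list = file.path(dir, "pid_genes.tsv"),
    symbol_map = file.path(dir, "symbol_map.tsv"),
    ppi_edges = file.path(dir, "ppi_edges.tsv"),
    drug_targets = file.path(dir, "drug_targets.csv"),
    approvals = file.path(dir, "approvals.tsv"),
    trials = file.path(dir, "trials.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_associations(bundle$associations, paths[["associations"]])
  write_ld_proxies(bundle$ld_proxies, paths[["ld_proxies"]])
  write_eqtl(bundle$eqtl, paths[["eqtl"]])
  write_go_membership(bundle$go_membership, paths[["go_membership"]])
  write_pid_list(bundle$pid_list, paths[["pid_list"]])
  write_symbol_map(bundle$symbol_map, paths[["symbol_map"]])
  write_ppi_edges(bundle$ppi_edges, paths[["ppi_edges"]])
  write_drug_targets(bundle$drug_targets, paths[["drug_targets"]])
  write_approvals(bundle$approvals, paths[["approvals"]])
  write_trials(bundle$trials, paths[["trials"]])
  jsonlite::write_json(bundle$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(paths)
}
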