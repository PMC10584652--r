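#' Expand lead SNPs to linkage-disequilibrium proxies
#'
#' For each seed (lead) variant, collects the proxy variants in the
#' requested reference-panel population whose r-squared with the seed is
#' strictly greater than the threshold. Every seed is additionally carried
#' as its own proxy at r-squared 1, so a lead variant is never lost even
#' when the LD table has no entry for it (in that case a warning reports
#' the synthesized self-proxy, whose gene annotation is unknown).
#'
#' @param seed_snps Character vector of lead-variant rsIDs.
#' @param ld_table LD proxy table from [read_ld_proxies()].
#' @param r2_threshold Keep proxies with `r_squared > r2_threshold`;
#'   default 0.80.
#' @param population Reference-panel label to restrict to (exact match on
#'   the `population` column); default `"ASN"`, the 1000 Genomes Phase 1
#'   Asian panel label.
#'
#' @return A data frame in LD-proxy layout, deduplicated on
#'   (query_rsid, proxy_rsid) keeping the maximum r-squared, ordered by
#'   (query_rsid, proxy_rsid).
#' @export
expand_ld <- function(seed_snps, ld_table, r2_threshold = 0.80,
                      population = "ASN") {
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must be a single value in [0, 1], got ", r2_threshold,
         call. = FALSE)
  check_cols(ld_table, c("query_rsid", "proxy_rsid", "r_squared",
                         "population", "gencode_id", "gene_symbol",
                         "consequence"), "LD proxy table")
  seeds <- unique(as.character(seed_snps))
  pop <- ld_table[ld_table$population == population &
                    ld_table$query_rsid %in% seeds, , drop = FALSE]
  hit <- pop[pop$r_squared > r2_threshold, , drop = FALSE]

  # seeds must survive as their own proxies regardless of the table
  have_self <- unique(hit$query_rsid[hit$query_rsid == hit$proxy_rsid])
  need_self <- setdiff(seeds, have_self)
  if (length(need_self)) {
    absent <- setdiff(need_self, unique(pop$query_rsid))
    if (length(absent))
      warning("seed SNP(s) absent from the LD table, retained as ",
              "self-proxies: ", paste(absent, collapse = ", "),
              call. = FALSE)
    self_gene <- function(s) {
      own <- pop[pop$query_rsid == s & pop$proxy_rsid == s, , drop = FALSE]
      if (nrow(own)) c(own$gencode_id[1L], own$gene_symbol[1L])
      else c("", "")
    }
    ann <- vapply(need_self, self_gene, character(2))
    hit <- rbind(hit, data.frame(
      query_rsid = need_self, proxy_rsid = need_self, r_squared = 1,
      population = population, gencode_id = ann[1L, ],
      gene_symbol = ann[2L, ], consequence = "self",
      stringsAsFactors = FALSE))
  }
  if (nrow(hit)) {
    ord <- order(hit$query_rsid, hit$proxy_rsid, -hit$r_squared)
    hit <- hit[ord, , drop = FALSE]
    key <- paste(hit$query_rsid, hit$proxy_rsid, sep = "\r")
    hit <- hit[!duplicated(key), , drop = FALSE]
  }
  reset_rows(hit)
}

#' Collect the genes carried by a proxy set
#'
#' Groups proxies by the gene they fall in. Proxies with an empty gene
#' annotation (e.g. intergenic variants or synthesized self-proxies with
#' unknown position) contribute no gene. Genes are keyed by GENCODE id.
#'
#' @param proxies LD-proxy data frame, e.g. from [expand_ld()].
#' @return A data frame with one row per gene: `gencode_id`,
#'   `gene_symbol`, `n_proxies`, and a list-column `proxy_rsids` of the
#'   distinct proxy variants mapping to the gene; ordered by `gencode_id`.
#' @export
collect_genes <- function(proxies) {
  check_cols(proxies, c("proxy_rsid", "gencode_id", "gene_symbol"),
             "proxy table")
  keep <- !is.na(proxies$gencode_id) & nzchar(proxies$gencode_id)
  p <- proxies[keep, , drop = FALSE]
  if (!nrow(p)) {
    out <- data.frame(gencode_id = character(0), gene_symbol = character(0),
                      n_proxies = integer(0), stringsAsFactors = FALSE)
    out$proxy_rsids <- list()
    return(out)
  }
  ids <- sort(unique(p$gencode_id))
  rs <- lapply(ids, function(g)
    sort(unique(p$proxy_rsid[p$gencode_id == g])))
  sym <- vapply(ids, function(g) {
    s <- p$gene_symbol[p$gencode_id == g]
    s <- s[!is.na(s) & nzchar(s)]
    if (length(s)) s[1L] else ""
  }, character(1))
  out <- data.frame(gencode_id = ids, gene_symbol = unname(sym),
                    n_proxies = lengths(rs), stringsAsFactors = FALSE)
  out$proxy_rsids <- rs
  reset_rows(out)
}
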