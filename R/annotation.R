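#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes without replacement from a background of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' The probability mass is accumulated in log-space via [lchoose()], so
#' the tail is exact to well below 1e-12 for backgrounds of the sizes used
#' in enrichment testing.
#'
#' @param k Observed overlap count(s); vectorized.
#' @param K Number of annotated genes in the background.
#' @param n Query-set size.
#' @param N Background size.
#' @return `P(X >= k)`, one value per element of `k`.
#' @examples
#' hypergeometric_tail(2, 4, 3, 10)  # 1/3
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(K) == 1L, length(n) == 1L, length(N) == 1L)
  bad <- !is.finite(c(k, K, n, N)) | c(k, K, n, N) < 0 |
    c(k, K, n, N) != floor(c(k, K, n, N))
  if (any(bad) || K > N || n > N)
    stop("invalid hypergeometric parameters: k=", paste(k, collapse = ","),
         " K=", K, " n=", n, " N=", N,
         " (need integers, 0 <= K <= N, 0 <= n <= N, k >= 0)",
         call. = FALSE)
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  support <- seq.int(lo, hi)
  terms <- exp(lchoose(K, support) + lchoose(N - K, n - support) -
                 lchoose(N, n))
  tails <- rev(cumsum(rev(terms)))  # tails[j] = P(X >= support[j])
  vapply(k, function(ki) {
    if (ki <= lo) return(1)
    if (ki > hi) return(0)
    min(1, tails[ki - lo + 1L])
  }, numeric(1))
}

#' Term enrichment over a candidate gene set
#'
#' For every annotation term touched by the query set, computes the
#' upper-tail hypergeometric enrichment p-value of the overlap between the
#' query genes and the term's members, against a background of
#' `background_n` genes. Term size `K` in the background is taken from the
#' membership table's `term_size` column (never smaller than the observed
#' overlap).
#'
#' @param query_genes Character vector of GENCODE ids under test.
#' @param membership GO-style membership table from [read_go_membership()].
#' @param background_n Background gene count; default 20000 protein-coding
#'   genes.
#' @param correction `"none"` (raw p-values, the default) or `"BH"` for a
#'   Benjamini-Hochberg adjustment within each category; when applied, the
#'   unadjusted values are kept in a `raw_p` column and `p_value` carries
#'   the adjusted ones used downstream.
#' @return Data frame with one row per (category, term): `term_id`,
#'   `category`, `k`, `K`, `n`, `N`, `p_value`; terms with zero overlap are
#'   omitted.
#' @export
enrich_terms <- function(query_genes, membership, background_n = 20000,
                         correction = c("none", "BH")) {
  correction <- match.arg(correction)
  check_cols(membership, c("category", "term_id", "gencode_id", "term_size"),
             "membership table")
  q <- unique(query_genes)
  n <- length(q)
  if (n > background_n)
    stop("query set (", n, ") larger than background (", background_n, ")",
         call. = FALSE)
  key <- paste(membership$category, membership$term_id, sep = "\r")
  terms <- membership[!duplicated(key), c("category", "term_id", "term_size")]
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    members <- unique(membership$gencode_id[
      membership$category == terms$category[i] &
        membership$term_id == terms$term_id[i]])
    k <- length(intersect(q, members))
    if (k == 0L) return(NULL)
    K <- min(max(terms$term_size[i], k), background_n)
    data.frame(term_id = terms$term_id[i], category = terms$category[i],
               k = k, K = K, n = n, N = background_n,
               p_value = hypergeometric_tail(k, K, n, background_n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(term_id = character(0), category = character(0),
               k = integer(0), K = integer(0), n = integer(0),
               N = integer(0), p_value = numeric(0),
               stringsAsFactors = FALSE))))
  if (correction == "BH") {
    out$raw_p <- out$p_value
    out$p_value <- stats::ave(out$p_value, out$category,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  }
  reset_rows(out)
}

#' Binary functional-annotation flags
#'
#' Each function scores one of the six gene-prioritization criteria,
#' returning a 0/1 integer per gene (vectorized over the gene table):
#' \describe{
#'   \item{`flag_missense()`}{the gene carries at least one LD proxy
#'     annotated as a missense variant;}
#'   \item{`flag_cis_eqtl()`}{at least one of the gene's proxies has a
#'     significant whole-blood cis-eQTL record for that gene;}
#'   \item{`flag_go_category()`}{the gene belongs to at least one term of
#'     the requested Gene Ontology category enriched at `p_value < alpha`
#'     over the candidate set;}
#'   \item{`flag_pid()`}{the gene is on the primary-immunodeficiency list,
#'     matched case-insensitively by symbol or exactly by GENCODE id.}
#' }
#'
#' @param genes Gene table with columns `gencode_id`, `gene_symbol`.
#' @param proxies r-squared-filtered LD proxy table, e.g. [expand_ld()]
#'   output.
#' @param eqtl cis-eQTL table from [read_eqtl()].
#' @param tissue Tissue restriction for the eQTL criterion
#'   (case-insensitive); default whole blood.
#' @param enrichment Output of [enrich_terms()] over the candidate set.
#' @param membership GO membership table.
#' @param category One of `"BP"`, `"CC"`, `"MF"`.
#' @param alpha Enrichment significance level; default 0.05.
#' @param pid_list Character vector of PID gene symbols (or ids).
#' @return Integer vector of 0/1 flags, one per row of `genes`.
#' @name annotation_flags
NULL

#' @rdname annotation_flags
#' @export
flag_missense <- function(genes, proxies) {
  check_cols(genes, "gencode_id", "gene table")
  check_cols(proxies, c("gencode_id", "consequence"), "proxy table")
  mis <- unique(proxies$gencode_id[proxies$consequence == "missense"])
  as.integer(genes$gencode_id %in% mis)
}

#' @rdname annotation_flags
#' @export
flag_cis_eqtl <- function(genes, proxies, eqtl, tissue = "whole blood") {
  check_cols(genes, "gencode_id", "gene table")
  check_cols(proxies, c("proxy_rsid", "gencode_id"), "proxy table")
  check_cols(eqtl, c("rsid", "gencode_id", "tissue", "significant"),
             "eQTL table")
  e <- eqtl[tolower(eqtl$tissue) == tolower(tissue) & eqtl$significant == 1L,
            , drop = FALSE]
  vapply(genes$gencode_id, function(g) {
    rs <- proxies$proxy_rsid[proxies$gencode_id == g]
    as.integer(any(e$gencode_id == g & e$rsid %in% rs))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname annotation_flags
#' @export
flag_go_category <- function(genes, enrichment, membership, category,
                             alpha = 0.05) {
  stopifnot(category %in% c("BP", "CC", "MF"))
  check_cols(genes, "gencode_id", "gene table")
  check_cols(enrichment, c("term_id", "category", "p_value"),
             "enrichment table")
  sig_terms <- enrichment$term_id[enrichment$category == category &
                                    enrichment$p_value < alpha]
  flagged <- unique(membership$gencode_id[
    membership$category == category & membership$term_id %in% sig_terms])
  as.integer(genes$gencode_id %in% flagged)
}

#' @rdname annotation_flags
#' @export
flag_pid <- function(genes, pid_list) {
  check_cols(genes, c("gencode_id", "gene_symbol"), "gene table")
  pid_up <- toupper(trimws(pid_list))
  as.integer(toupper(genes$gene_symbol) %in% pid_up |
               genes$gencode_id %in% pid_list)
}

#' Compute all six annotation flags for a candidate gene set
#'
#' Convenience wrapper running the six criteria against one bundle of
#' inputs. GO enrichment is computed internally over the candidate set.
#'
#' @inheritParams annotation_flags
#' @param go_membership GO membership table (categories BP, CC, MF).
#' @param background_n Enrichment background size; default 20000.
#' @return Data frame with `gencode_id`, `gene_symbol` and the six flag
#'   columns `missense`, `cis_eqtl`, `go_bp`, `go_cc`, `go_mf`, `pid`.
#' @export
annotate_genes <- function(genes, proxies, eqtl, go_membership, pid_list,
                           alpha = 0.05, background_n = 20000,
                           tissue = "whole blood") {
  enr <- enrich_terms(genes$gencode_id, go_membership, background_n)
  out <- data.frame(gencode_id = genes$gencode_id,
                    gene_symbol = genes$gene_symbol,
                    stringsAsFactors = FALSE)
  out$missense <- flag_missense(genes, proxies)
  out$cis_eqtl <- flag_cis_eqtl(genes, proxies, eqtl, tissue)
  out$go_bp <- flag_go_category(genes, enr, go_membership, "BP", alpha)
  out$go_cc <- flag_go_category(genes, enr, go_membership, "CC", alpha)
  out$go_mf <- flag_go_category(genes, enr, go_membership, "MF", alpha)
  out$pid <- flag_pid(genes, pid_list)
  reset_rows(out)
}
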