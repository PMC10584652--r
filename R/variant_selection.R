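#' Filter associations at genome-wide significance
#'
#' Keeps association records whose p-value falls below the significance
#' threshold. The boundary is exclusive by default (`p < threshold`, the
#' conventional genome-wide criterion); `strict = FALSE` switches to
#' `p <= threshold` for sensitivity runs. Input order is preserved.
#'
#' @param records Association data frame from [read_associations()].
#' @param p_threshold Significance threshold in (0, 1]; default `1e-8`.
#' @param strict Use a strict `<` at the boundary (default) rather than `<=`.
#'
#' @return The subset of `records` passing the filter, in input order.
#' @examples
#' df <- data.frame(rsid = c("rs1", "rs2"), chromosome = "1",
#'                  position = 1L, p_value = c(1e-9, 1e-8),
#'                  mapped_genes = "", study_id = "")
#' filter_associations(df)$rsid  # rs2 sits exactly on the boundary: excluded
#' @export
filter_associations <- function(records, p_threshold = 1e-8, strict = TRUE) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be a single value in (0, 1], got ", p_threshold,
         call. = FALSE)
  check_cols(records, c("rsid", "p_value"), "association table")
  keep <- if (strict) records$p_value < p_threshold
          else records$p_value <= p_threshold
  reset_rows(records[keep, , drop = FALSE])
}

#' Deduplicate lead SNPs across studies
#'
#' The same variant can be reported by several studies; downstream stages
#' want one record per rsID. The record with the smallest p-value is kept
#' (the most significant evidence for the locus), and the result is
#' ordered by ascending p-value, ties broken by rsID, so output order is
#' deterministic.
#'
#' @param records Association data frame.
#' @return One record per rsID, ordered by (p_value, rsid).
#' @export
deduplicate_snps <- function(records) {
  check_cols(records, c("rsid", "p_value"), "association table")
  ord <- order(records$p_value, records$rsid)
  out <- records[ord, , drop = FALSE]
  reset_rows(out[!duplicated(out$rsid), , drop = FALSE])
}
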