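#' Column-mapping dialects
#'
#' External tables arrive with header flavours that differ between database
#' export versions. A dialect is a declarative map from the canonical field
#' names this package uses to the header names found in a particular file
#' flavour, so real snapshots and synthetic fixtures share one reader code
#' path. Header matching is case-insensitive, and the canonical name itself
#' is always accepted as a fallback.
#'
#' @param ... Named character entries, `canonical = "header in file"`.
#'
#' @return A `gw2drug_dialect` object (named list of header names).
#' @examples
#' d <- dialect(rsid = "SNPS", p_value = "P-VALUE")
#' @export
dialect <- function(...) {
  map <- c(...)
  if (length(map) == 0L || is.null(names(map)) || any(!nzchar(names(map))) ||
      !is.character(map))
    stop("dialect() needs named character entries", call. = FALSE)
  structure(as.list(map), class = "gw2drug_dialect")
}

#' @rdname dialect
#' @export
default_association_dialect <- function() {
  dialect(rsid = "rsid", chromosome = "chromosome", position = "position",
          p_value = "p_value", mapped_genes = "mapped_genes",
          study_id = "study_id")
}

#' @rdname dialect
#' @export
gwas_catalog_dialect <- function() {
  dialect(rsid = "SNPS", chromosome = "CHR_ID", position = "CHR_POS",
          p_value = "P-VALUE", mapped_genes = "MAPPED_GENE",
          study_id = "STUDY ACCESSION")
}

# resolve canonical -> column index in `header`; NA where absent
resolve_columns <- function(header, dialect, mandatory = character(0)) {
  idx <- vapply(names(dialect), function(canon) {
    cands <- unique(c(dialect[[canon]], canon))
    hit <- match(tolower(cands), tolower(header))
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[[1L]] else NA_integer_
  }, integer(1))
  miss <- intersect(mandatory, names(idx)[is.na(idx)])
  if (length(miss))
    stop("mandatory column(s) not resolvable through dialect: ",
         paste(miss, collapse = ", "), call. = FALSE)
  idx
}
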