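# internal helpers shared across readers and pipeline stages

`%||%` <- function(a, b) if (is.null(a)) b else a

check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || is.na(path) || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  invisible(path)
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

# all columns read as character; each reader coerces what it validates
read_tsv_raw <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

reset_rows <- function(df) {
  rownames(df) <- NULL
  df
}

# ';'-joined list fields used in the drug-candidate table
join_field <- function(x) {
  vapply(x, function(v) paste(sort(unique(as.character(v))), collapse = ";"),
         character(1))
}

# sample() semantics without the scalar-x surprise
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

split_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
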