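# Shared small helpers (no exports).

# Read a TSV with exactly the given columns; unknown or missing columns are a
# loud error. All readers in the package funnel through this.
read_strict_tsv <- function(path, required, optional = character()) {
  tb <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  extra <- setdiff(names(tb), c(required, optional))
  if (length(extra) > 0) {
    rlang::abort(paste0(
      "Unknown column(s) in ", path, ": ", paste(extra, collapse = ", "),
      " (expected: ", paste(c(required, optional), collapse = ", "), ")"
    ))
  }
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "Missing required column(s) in ", path, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  tibble::as_tibble(tb)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# Variant key used across score/MAF tables and truth records.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
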