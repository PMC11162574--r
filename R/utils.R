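`%||%` <- function(a, b) if (is.null(a)) b else a

## all load errors funnel through here so messages carry no call noise
load_error <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

#' Write a data frame as a headered TSV
#'
#' All pipeline outputs go through this writer: tab-separated, header row,
#' no quoting, no row names, `NA` written literally.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, required_cols = NULL) {
  if (!file.exists(path)) load_error("input file does not exist: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    if (length(miss) > 0) {
      load_error("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", "))
    }
  }
  df
}
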