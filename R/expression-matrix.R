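#' Gene-by-tissue expression matrix
#'
#' A numeric matrix of expression values (FPKM/TPM or their log2(x+1)
#' transform) with gene ids as row names and tissue labels as column names,
#' carrying an explicit scale flag so that downstream operations can refuse
#' inputs on the wrong scale. Tissue column order is preserved as given and
#' must be identical across matrices that are compared by Euclidean
#' distance.
#'
#' @param values Numeric matrix with unique, non-empty row names (gene ids)
#'   and column names (tissue labels). No missing values are allowed; on the
#'   raw scale all values must be non-negative.
#' @param scale Either `"raw"` (abundance units as loaded) or `"log2p1"`
#'   (values are `log2(x + 1)`).
#' @return An `expression_matrix` object.
#' @seealso [read_expression_matrix()], [log_transform()]
#' @export
expression_matrix <- function(values, scale = c("raw", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    load_error("expression values must be a numeric matrix")
  }
  ids <- rownames(values)
  if (nrow(values) > 0 && (is.null(ids) || any(!nzchar(ids)))) {
    load_error("expression matrix requires non-empty gene ids as row names")
  }
  if (is.null(colnames(values)) || any(!nzchar(colnames(values)))) {
    load_error("expression matrix requires tissue labels as column names")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    load_error("duplicated gene id(s): %s", paste(dup, collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- ids[rowSums(is.na(values)) > 0]
    load_error("missing expression value(s) in row(s): %s",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  if (scale == "raw" && any(values < 0)) {
    bad <- ids[rowSums(values < 0) > 0]
    load_error("negative expression value(s) in row(s): %s",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(values, expr_scale = scale,
            class = c("expression_matrix", "matrix", "array"))
}

#' Scale flag of an expression matrix
#'
#' @param x An [expression_matrix()].
#' @return `"raw"` or `"log2p1"`.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "expr_scale")
  if (is.null(sc)) load_error("not an expression_matrix (no scale flag)")
  sc
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  sc <- expr_scale(x)
  m <- unclass(x)
  attr(m, "expr_scale") <- NULL
  out <- m[i, j, drop = drop]
  if (is.matrix(out)) {
    structure(out, expr_scale = sc,
              class = c("expression_matrix", "matrix", "array"))
  } else {
    out
  }
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d tissues [%s scale]\n",
              nrow(x), ncol(x), expr_scale(x)))
  cat("tissues:", paste(colnames(x), collapse = ", "), "\n")
  print(utils::head(unclass(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more genes\n")
  invisible(x)
}

#' Read a gene-by-tissue expression matrix from TSV
#'
#' Expects a header row of tissue labels with the first column holding gene
#' ids. Values are validated on load: missing cells, negative values and
#' duplicated gene ids are rejected with the offending rows named, never
#' silently coerced.
#'
#' @param path TSV file path.
#' @param tissue_labels Optional character vector giving the required tissue
#'   set and order; the loaded columns are checked against it and returned
#'   in this order. Default `NULL` keeps the file's own column order.
#' @return An [expression_matrix()] on the raw scale.
#' @export
read_expression_matrix <- function(path, tissue_labels = NULL) {
  df <- read_tsv_file(path)
  if (ncol(df) < 2) load_error("%s: need a gene-id column plus >= 1 tissue", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  num <- vapply(vals, function(col) suppressWarnings(as.numeric(col)), numeric(nrow(df)))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1)
  dimnames(num) <- list(ids, names(vals))
  if (!is.null(tissue_labels)) {
    miss <- setdiff(tissue_labels, colnames(num))
    if (length(miss) > 0) {
      load_error("%s: missing tissue column(s): %s", path,
                 paste(miss, collapse = ", "))
    }
    num <- num[, tissue_labels, drop = FALSE]
  }
  expression_matrix(num, scale = "raw")
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: values round-trip to full
#' precision. The scale flag is not serialized; matrices are written on
#' whatever scale they carry and the reader always returns `"raw"`, so only
#' raw-scale matrices should be written for later re-loading.
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  ## 17 significant digits so numeric values survive the text round trip
  for (j in seq(2, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  write_tsv(df, path)
}
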