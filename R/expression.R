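#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric gene x sample matrix carrying a value
#' scale tag. Rows are genes, columns are samples; both must carry unique
#' names. The tag records where the matrix sits in the normalization chain.
#'
#' @param values Numeric matrix with unique rownames (gene IDs) and unique
#'   colnames (sample IDs).
#' @param scale One of `"counts"`, `"cpm"`, `"log2"`, `"standardized"`,
#'   `"pooled"`. The `"counts"` tag requires nonnegative integral values.
#' @return A numeric matrix of class `"ExpressionMatrix"` with attribute
#'   `scale`.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- expression_matrix(m, "counts")
#' expr_scale(em)
#' @export
expression_matrix <- function(values,
                              scale = c("counts", "cpm", "log2",
                                        "standardized", "pooled")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene IDs: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample IDs: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (scale == "counts") {
    if (any(values < 0)) stop("counts must be nonnegative")
    if (any(abs(values - round(values)) > 1e-8)) stop("counts must be integral")
  }
  structure(values, scale = scale, class = c("ExpressionMatrix", class(values)))
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("not a tagged expression matrix")
  s
}

# retag the result of a matrix operation, preserving dimnames
retag <- function(values, scale) {
  attr(values, "scale") <- scale
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(x), ncol(x), expr_scale(x)))
  y <- x
  attr(y, "scale") <- NULL
  class(y) <- "matrix"
  print(utils::head(y, 5L), ...)
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Read / write tab-separated expression matrices
#'
#' The on-disk format is one header row of sample IDs, a first column of gene
#' IDs (named `gene_id`), and tab-separated numeric cells. The scale tag is
#' stored in a `# scale: <tag>` comment line preceding the header.
#'
#' @param path File path.
#' @return `read_expression()` returns an [expression_matrix()].
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- "log2"
  skip <- 0L
  if (startsWith(first, "# scale:")) {
    scale <- trimws(sub("^# scale:", "", first))
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id")
    stop("malformed expression header: first column must be 'gene_id'")
  gid <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                   gid[bad], colnames(vals)[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gid
  expression_matrix(m, scale)
}

#' @rdname read_expression
#' @param x An `ExpressionMatrix`.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", expr_scale(x)), con)
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
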