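## Delimited-text I/O. The canonical on-disk format is a tab-delimited
## matrix with a header row of variable names and a first column of row
## names; the background block may instead be supplied as a two-column
## long-format pair file (variable id, annotation term).

#' Read a delimited numeric matrix
#'
#' @param path file path; tab-delimited with a header row and row names in
#'   the first column.
#' @param sep field separator (default tab).
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a numeric matrix as delimited text
#'
#' Full double precision is kept, so a write/read round trip reproduces
#' the values exactly.
#'
#' @param x matrix (or vector, written as a one-column matrix).
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_matrix <- function(x, path, sep = "\t") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  df <- data.frame(id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a background matrix from an annotation pair file
#'
#' Turns long-format (variable id, annotation term) pairs — for example an
#' exported gene-to-GO-term list — into the binary `L x K` membership
#' matrix expected by [lpls()]: entry `(l, k)` is 1 when variable `k` is
#' annotated with term `l`.
#'
#' @param pairs two-column `data.frame` (or matrix): variable id, term.
#' @param variables character vector of all variable ids, in the column
#'   order of the predictor matrix.
#' @return Binary matrix with one row per distinct term (in order of first
#'   appearance) and one column per variable.
#' @export
pairs_to_z <- function(pairs, variables) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) stop("'pairs' must have two columns: variable, term")
  vid <- as.character(pairs[[1]])
  term <- as.character(pairs[[2]])
  unknown <- setdiff(unique(vid), variables)
  if (length(unknown))
    stop("pair file refers to unknown variable id(s): ",
         paste(utils::head(unknown, 10), collapse = ", "))
  terms <- unique(term)
  Z <- matrix(0, length(terms), length(variables),
              dimnames = list(terms, variables))
  Z[cbind(match(term, terms), match(vid, variables))] <- 1
  Z
}

#' Read and validate the three data blocks
#'
#' Loads the response, predictor and background blocks from delimited
#' files, reconciles their dimensions and returns them ready for
#' [lpls()]. The background block may be given either as a matrix file
#' (`z_path`) or assembled from a long-format annotation pair file
#' (`pairs_path`).
#'
#' @param y_path file holding the response: a one-column matrix (header +
#'   row names) or a headerless single column of numbers.
#' @param x_path file holding the predictor matrix.
#' @param z_path optional file holding the `L x K` background matrix.
#' @param pairs_path optional two-column (variable, term) file used
#'   instead of `z_path`.
#' @param orientation `"samples_rows"` (default) if rows of the X file are
#'   samples, `"samples_cols"` if the file is transposed.
#' @param sep field separator (default tab).
#' @return A list with validated `y`, `X`, `Z`.
#' @export
read_blocks <- function(y_path, x_path, z_path = NULL, pairs_path = NULL,
                        orientation = c("samples_rows", "samples_cols"),
                        sep = "\t") {
  orientation <- match.arg(orientation)
  X <- read_matrix(x_path, sep)
  if (orientation == "samples_cols") X <- t(X)
  y_raw <- tryCatch(read_matrix(y_path, sep), error = function(e) NULL)
  if (is.null(y_raw) || ncol(y_raw) < 1) {
    y <- scan(y_path, quiet = TRUE)
  } else {
    y <- as.numeric(y_raw[, 1])
  }
  if (is.null(z_path) && is.null(pairs_path))
    stop("supply either 'z_path' or 'pairs_path' for the background block")
  if (!is.null(z_path)) {
    Z <- read_matrix(z_path, sep)
    if (!is.null(colnames(Z)) && !is.null(colnames(X)) &&
        ncol(Z) == ncol(X) && !identical(colnames(Z), colnames(X)))
      Z <- Z[, colnames(X), drop = FALSE]
  } else {
    pairs <- utils::read.table(pairs_path, header = FALSE, sep = sep,
                               colClasses = "character")
    Z <- pairs_to_z(pairs, colnames(X))
  }
  validate_blocks(y, X, Z)
  list(y = y, X = X, Z = Z)
}
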