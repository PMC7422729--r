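# CSV readers/writers for response, time, and item-parameter tables.
#
# All matrices travel as plain CSV with a header row of item IDs and a first
# column of person IDs; item parameters as columns item,a,b,c. Every artifact
# written gets a plain-text sidecar recording seed, dimensions, and a content
# hash so it can be regenerated exactly.

#' Read a person-by-item matrix from CSV
#'
#' Expects a header row of item IDs and a first column of person IDs.
#' Validation depends on `kind`: responses must be 0/1, raw times strictly
#' positive, transformed times merely finite.
#'
#' @param path CSV file path.
#' @param kind one of `"response"`, `"time"`, `"tstar"`.
#' @return numeric matrix with person IDs as rownames and item IDs as
#'   colnames (integer matrix for responses).
#' @export
read_matrix_csv <- function(path, kind = c("response", "time", "tstar")) {
  kind <- match.arg(kind)
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("expected an ID column plus at least one item column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  rownames(m) <- as.character(df[[1]])
  bad_cell <- function(i) {
    ij <- arrayInd(i, dim(m))
    sprintf("row '%s', column '%s'", rownames(m)[ij[1]], colnames(m)[ij[2]])
  }
  if (kind == "response") {
    bad <- which(is.na(m) | !(m %in% c(0, 1)))
    if (length(bad)) stop("invalid response value at ", bad_cell(bad[1]),
                          " (responses must be 0 or 1)")
    storage.mode(m) <- "integer"
  } else if (kind == "time") {
    bad <- which(!is.finite(m) | m <= 0)
    if (length(bad)) stop("invalid raw time at ", bad_cell(bad[1]),
                          " (times must be positive)")
  } else {
    bad <- which(!is.finite(m))
    if (length(bad)) stop("non-finite transformed time at ", bad_cell(bad[1]))
  }
  m
}

#' Write a person-by-item matrix to CSV
#'
#' @param m matrix; missing dimnames are filled with `P1..PN` / `I1..IJ`.
#' @param path output CSV path.
#' @param id_col name of the person-ID column, default `"person"`.
#' @return the path, invisibly.
#' @export
write_matrix_csv <- function(m, path, id_col = "person") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("I", seq_len(ncol(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read item parameters from CSV
#'
#' Expects columns `item`, `a`, `b`, `c` (extra columns are ignored).
#'
#' @param path CSV file path.
#' @param D logistic scaling constant to attach (not stored in the file).
#' @return an [item_params()] object.
#' @export
read_item_params <- function(path, D = 1.7) {
  df <- read.csv(path)
  need <- c("a", "b", "c")
  if (!all(need %in% names(df)))
    stop("item-parameter CSV must have columns a, b, c")
  item_params(df$a, df$b, df$c, D = D)
}

#' Write item parameters to CSV
#'
#' @param items an [item_params()] object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_item_params <- function(items, path) {
  items <- .check_items(items)
  write.csv(data.frame(item = seq_len(items$J), a = items$a, b = items$b,
                       c = items$c),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# small stable content hash (rolling polynomial over the serialized object,
# mod 2^31 - 1) so sidecars can certify artifact identity without extra
# dependencies
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a result table with a reproducibility sidecar
#'
#' Writes any data.frame to CSV (floats at 6 significant digits, stable
#' column order) plus a `<path>.meta` text sidecar recording the package
#' version, seed, and a content hash of the table and configuration.
#'
#' @param x data.frame to write.
#' @param path output CSV path.
#' @param seed seed that produced the artifact (recorded, may be NA).
#' @param config optional list of settings folded into the hash.
#' @return the path, invisibly.
#' @export
write_summary <- function(x, path, seed = NA, config = list()) {
  stopifnot(is.data.frame(x))
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  write.csv(x, path, row.names = FALSE)
  meta <- c(sprintf("package: g3plt %s", as.character(packageVersion("g3plt"))),
            sprintf("seed: %s", seed),
            sprintf("rows: %d", nrow(x)),
            sprintf("hash: %s", .config_hash(list(x, config))))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
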