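#' Read a genes-by-time expression matrix
#'
#' Expects delimited text with gene ids in the first column and numeric
#' expression values at successive time points in the remaining columns.
#' The delimiter is chosen from the file extension (`.csv` comma, anything
#' else tab).  Ragged rows, non-numeric cells and fewer than two time points
#' are rejected with the offending line number.
#'
#' @param path File path.
#' @return Numeric matrix, gene ids as rownames, columns in file order.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header and data rows")
  fields <- strsplit(lines, sep, fixed = TRUE)
  width <- length(fields[[1]])
  if (width < 3L) stop("line 1: need at least 2 time-point columns")
  for (i in seq_along(fields))
    if (length(fields[[i]]) != width)
      stop("line ", i, ": expected ", width, " fields, found ",
           length(fields[[i]]))
  ids <- vapply(fields[-1], `[[`, "", 1L)
  vals <- lapply(seq_along(fields)[-1], function(i) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (anyNA(v)) stop("line ", i, ": non-numeric expression value")
    v
  })
  X <- do.call(rbind, vals)
  rownames(X) <- ids
  colnames(X) <- fields[[1]][-1]
  X
}

#' Write a genes-by-time expression matrix
#'
#' Tab- or comma-delimited (by extension), gene ids in the first column,
#' floats at 17 significant digits so a write/read round trip is exact.
#'
#' @param X Numeric matrix with rownames.
#' @param path Output path.
#' @export
write_expression <- function(X, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ids <- rownames(X) %||% paste0("g", seq_len(nrow(X)))
  tps <- colnames(X) %||% paste0("t", seq_len(ncol(X)) - 1L)
  body <- apply(X, 1L, function(r) paste(fmt17(r), collapse = sep))
  writeLines(c(paste(c("gene", tps), collapse = sep),
               paste(ids, body, sep = sep)), path)
  invisible(path)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Read or write a network
#'
#' Two interchangeable on-disk forms: a signed edge-list TSV with columns
#' `source`, `target`, `weight`, and a dense adjacency CSV with gene ids as
#' header row and first column.  `write_network()` stores entries with
#' magnitude above `sign_threshold` (edge list) or the full matrix
#' (adjacency); conversion round-trips exactly on the stored entries.
#'
#' @param path File path; `kind` defaults from the extension (`.tsv`/`.txt`
#'   edge list, `.csv` adjacency).
#' @param kind `"edgelist"` or `"adjacency"`.
#' @param gene_ids For reading an edge list: the full ordered gene universe.
#'   Unknown ids in the file are an error; defaults to the ids seen, in
#'   order of appearance.
#' @return `read_network()` returns the dense matrix with gene-id dimnames.
#' @export
read_network <- function(path, kind = NULL, gene_ids = NULL) {
  kind <- kind %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency" else "edgelist")
  kind <- match.arg(kind, c("edgelist", "adjacency"))
  if (kind == "adjacency") {
    df <- utils::read.csv(path, check.names = FALSE)
    A <- as.matrix(df[, -1, drop = FALSE])
    rownames(A) <- df[[1]]
    storage.mode(A) <- "double"
    return(A)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(df)))
    stop("edge list needs columns source, target, weight")
  ids <- gene_ids %||% unique(c(rbind(df$source, df$target)))
  bad <- setdiff(c(df$source, df$target), ids)
  if (length(bad)) stop("unknown gene id(s): ", paste(bad, collapse = ", "))
  key <- paste(df$source, df$target)
  if (anyDuplicated(key))
    stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(match(df$source, ids), match(df$target, ids))] <- df$weight
  A
}

#' @rdname read_network
#' @param A Square numeric matrix (or `"grn"` object) to write.
#' @param sign_threshold Edge-list form stores entries with `|a_ij|` above
#'   this.
#' @export
write_network <- function(A, path, kind = NULL, sign_threshold = 0) {
  if (inherits(A, "grn")) A <- A$A
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  ids <- rownames(A) %||% paste0("g", seq_len(nrow(A)))
  kind <- kind %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency" else "edgelist")
  kind <- match.arg(kind, c("edgelist", "adjacency"))
  if (kind == "adjacency") {
    lines <- c(paste(c("gene", ids), collapse = ","),
               vapply(seq_len(nrow(A)), function(i)
                 paste(c(ids[i], fmt17(A[i, ])), collapse = ","), ""))
    writeLines(lines, path)
    return(invisible(path))
  }
  keep <- which(abs(A) > sign_threshold, arr.ind = TRUE)
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  lines <- c("source\ttarget\tweight",
             sprintf("%s\t%s\t%s", ids[keep[, 1]], ids[keep[, 2]],
                     fmt17(A[keep])))
  writeLines(lines, path)
  invisible(path)
}
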