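#' Validate a binary adjacency matrix
#'
#' Checks that `W` is a square numeric matrix with entries in \{0, 1\},
#' symmetric and with a zero diagonal. These are the structural requirements
#' on the network estimand: a link between regions `j` and `k` is encoded as
#' `W[j, k] = W[k, j] = 1`, self-links are not allowed.
#'
#' @param W matrix to validate.
#' @param arg name used in error messages.
#' @return `W`, invisibly, with dimnames untouched.
#' @export
validate_adjacency <- function(W, arg = "W") {
  if (!is.matrix(W) || !is.numeric(W))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(W) != ncol(W))
    stop(sprintf("`%s` must be square (got %d x %d)", arg, nrow(W), ncol(W)),
         call. = FALSE)
  if (anyNA(W) || !all(W %in% c(0, 1)))
    stop(sprintf("`%s` must be binary (entries 0 or 1)", arg), call. = FALSE)
  if (!isTRUE(all.equal(W, t(W), check.attributes = FALSE)))
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  if (any(diag(W) != 0))
    stop(sprintf("`%s` must have a zero diagonal", arg), call. = FALSE)
  invisible(W)
}

#' Enumerate the strict upper-triangle index pairs
#'
#' Row-major order over pairs `(j, k)` with `j < k`; this is the fixed sweep
#' order used by [fit_mnl()] so that runs are reproducible.
#'
#' @param K number of regions.
#' @return integer matrix with columns `j`, `k`, one row per unordered pair.
#' @export
upper_tri_pairs <- function(K) {
  stopifnot(K >= 2)
  j <- rep(seq_len(K - 1L), times = (K - 1L):1L)
  k <- unlist(lapply(seq_len(K - 1L), function(a) (a + 1L):K))
  cbind(j = j, k = as.integer(k))
}

#' Make a symmetric binary matrix from its upper triangle
#'
#' @param K size; `ut` vector of 0/1 values in the column-major order of
#'   `upper.tri(diag(K))`.
#' @return K x K adjacency matrix.
#' @keywords internal
symmetrise_upper <- function(K, ut) {
  W <- matrix(0, K, K)
  W[upper.tri(W)] <- ut
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

#' Write an adjacency matrix to delimited text
#'
#' Writes the full square 0/1 matrix as comma-separated text with region
#' labels as header, and alongside it an equivalent two-column edge list
#' (`<prefix>_edges.csv`). Either representation can be read back with
#' [read_adjacency()].
#'
#' @param W adjacency matrix; dimnames, if present, are used as labels.
#' @param path output path of the square matrix file.
#' @param edge_path optional output path of the edge list; defaults to
#'   `path` with `_edges` inserted before the extension; `NA` suppresses it.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(W, path, edge_path = NULL) {
  validate_adjacency(W)
  K <- nrow(W)
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(K))
  dimnames(W) <- list(labels, labels)
  df <- data.frame(roi = labels, W, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (is.null(edge_path))
    edge_path <- sub("(\\.[^.]*)?$", "_edges\\1", path)
  if (!is.na(edge_path)) {
    idx <- which(upper.tri(W) & W == 1, arr.ind = TRUE)
    edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]])
    utils::write.csv(edges, edge_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an adjacency matrix from delimited text
#'
#' Accepts either the square-matrix format written by [write_adjacency()]
#' (first column = labels) or a two-column edge list; symmetry, binariness
#' and zero diagonal are enforced on read.
#'
#' @param path file to read.
#' @param labels region labels, required when reading an edge list so the
#'   node set is unambiguous.
#' @return adjacency matrix with label dimnames.
#' @export
read_adjacency <- function(path, labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 2L) {
    if (is.null(labels))
      stop("reading an edge list requires `labels`", call. = FALSE)
    K <- length(labels)
    W <- matrix(0, K, K, dimnames = list(labels, labels))
    from <- match(df[[1]], labels)
    to <- match(df[[2]], labels)
    if (anyNA(from) || anyNA(to))
      stop("edge list mentions nodes not in `labels`", call. = FALSE)
    W[cbind(from, to)] <- 1
    W[cbind(to, from)] <- 1
  } else {
    labs <- as.character(df[[1]])
    W <- as.matrix(df[, -1, drop = FALSE])
    dimnames(W) <- list(labs, colnames(df)[-1])
    storage.mode(W) <- "double"
  }
  validate_adjacency(W)
  W
}
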