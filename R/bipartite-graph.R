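#' Build a bipartite graph from a biadjacency matrix or an edge table
#'
#' A `bipartite_graph` holds the binary biadjacency matrix M of a two-layer
#' network: rows are one layer (countries, pollinators, species, ...), columns
#' the other (products, plants, sites, ...). Entry `m[c, p] = 1` records a link
#' between row node `c` and column node `p`; links inside a layer do not exist
#' by construction.
#'
#' @param x either a numeric matrix (any strictly positive value is coerced to
#'   1 with a warning, since inputs are often thresholded weights), or a data
#'   frame whose first two columns are (row label, column label) edge pairs.
#'   Duplicate edges collapse to a single link. Label order is order of first
#'   appearance.
#' @param row_labels,col_labels optional character vectors of unique labels;
#'   default to existing dimnames or `r1..rC` / `c1..cP`.
#' @return an object of class `bipartite_graph`.
#' @examples
#' toy <- bipartite_graph(matrix(c(1, 1, 1, 0, 0, 0), nrow = 2))
#' glance(toy)
#' @export
bipartite_graph <- function(x, row_labels = NULL, col_labels = NULL) {
  if (is.data.frame(x)) {
    return(edges_to_graph(x))
  }
  m <- as.matrix(x)
  if (!is.numeric(m)) {
    abort("biadjacency entries must be numeric 0/1 values")
  }
  if (anyNA(m)) abort("biadjacency matrix contains missing values")
  if (any(m < 0)) abort("biadjacency entries must be nonnegative")
  if (any(m > 0 & m != 1)) {
    warn("non-binary positive entries found; coercing every positive value to 1")
    m <- (m > 0) + 0L
  }
  if (nrow(m) < 1L || ncol(m) < 1L) abort("both layers need at least one node")
  rn <- row_labels %||% rownames(m) %||% paste0("r", seq_len(nrow(m)))
  cn <- col_labels %||% colnames(m) %||% paste0("c", seq_len(ncol(m)))
  if (anyDuplicated(rn) || anyDuplicated(cn)) {
    abort("node labels must be unique within each layer")
  }
  if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
    abort("label lengths do not match matrix dimensions")
  }
  dimnames(m) <- list(rn, cn)
  new_bipartite_graph(m)
}

new_bipartite_graph <- function(m) {
  storage.mode(m) <- "integer"
  structure(list(matrix = m), class = "bipartite_graph")
}

edges_to_graph <- function(df) {
  if (ncol(df) < 2L) abort("edge table needs two columns: (row label, column label)")
  r <- as.character(df[[1L]])
  p <- as.character(df[[2L]])
  if (anyNA(r) || anyNA(p)) abort("edge table contains missing labels")
  rn <- unique(r)
  cn <- unique(p)
  m <- matrix(0L, length(rn), length(cn), dimnames = list(rn, cn))
  m[cbind(match(r, rn), match(p, cn))] <- 1L
  new_bipartite_graph(m)
}

#' Extract the biadjacency matrix of a bipartite graph
#'
#' @param g a [bipartite_graph()].
#' @return integer 0/1 matrix with row/column labels as dimnames.
#' @export
biadjacency <- function(g) {
  stopifnot(inherits(g, "bipartite_graph"))
  g$matrix
}

#' @export
dim.bipartite_graph <- function(x) dim(x$matrix)

#' @export
print.bipartite_graph <- function(x, ...) {
  m <- x$matrix
  cat(sprintf(
    "# bipartite_graph: %d x %d, %d links (connectance %.3f)\n",
    nrow(m), ncol(m), sum(m), sum(m) / length(m)
  ))
  invisible(x)
}

#' Read a biadjacency matrix from disk
#'
#' Supported layouts:
#' * `dense`: TSV/CSV with a header row of column labels and a leading column
#'   of row labels; cells are 0/1 (any positive value is coerced to 1 with a
#'   warning). Delimiter is inferred from the extension (`.csv` = comma,
#'   otherwise tab).
#' * `edgelist`: two whitespace/tab-separated label columns (row label,
#'   column label); `#` comments allowed; duplicate edges collapse.
#' * `sparse`: Matrix-Market coordinate file; labels optionally supplied via
#'   one-label-per-line side files.
#'
#' @param path input file.
#' @param format one of `"dense"`, `"edgelist"`, `"sparse"`.
#' @param row_label_file,col_label_file optional label files for `sparse`.
#' @return a [bipartite_graph()].
#' @export
read_biadjacency <- function(path, format = c("dense", "edgelist", "sparse"),
                             row_label_file = NULL, col_label_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("input file does not exist: %s", path))
  switch(format,
    dense = read_dense(path),
    edgelist = read_edgelist(path),
    sparse = read_sparse(path, row_label_file, col_label_file)
  )
}

read_dense <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.table(path,
      header = TRUE, sep = sep, row.names = 1, check.names = FALSE,
      comment.char = "", stringsAsFactors = FALSE, colClasses = "character"
    ),
    error = function(e) abort(sprintf("cannot parse dense matrix %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L || ncol(df) == 0L) abort(sprintf("empty biadjacency file: %s", path))
  chr <- as.matrix(df)
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-numeric cell '%s' at line %d of %s",
      chr[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L, path
    ))
  }
  dimnames(num) <- dimnames(chr)
  bipartite_graph(num)
}

read_edgelist <- function(path) {
  df <- tryCatch(
    read.table(path,
      header = FALSE, comment.char = "#", stringsAsFactors = FALSE,
      col.names = c("row", "col"), colClasses = "character"
    ),
    error = function(e) abort(sprintf("cannot parse edge list %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) abort(sprintf("empty edge list: %s", path))
  edges_to_graph(df)
}

read_sparse <- function(path, row_label_file, col_label_file) {
  sm <- tryCatch(Matrix::readMM(path),
    error = function(e) abort(sprintf("cannot parse Matrix-Market file %s: %s", path, conditionMessage(e)))
  )
  m <- as.matrix(sm)
  rn <- if (!is.null(row_label_file)) readLines(row_label_file) else NULL
  cn <- if (!is.null(col_label_file)) readLines(col_label_file) else NULL
  bipartite_graph(m, row_labels = rn, col_labels = cn)
}

#' Elementary topological summary of a bipartite graph
#'
#' Returns, as a one-row tibble: the number of links
#' `L = sum(m_cp)`, the connectance `L / (C * P)`, the rectangularity
#' `R = |P - C| / (P + C)` (a sign-free index of layer-size asymmetry in
#' `[0, 1)`), and both mean degrees `L / C` and `L / P`.
#'
#' @param g a [bipartite_graph()].
#' @return one-row tibble.
#' @export
graph_summary <- function(g) {
  m <- biadjacency(g)
  C <- nrow(m)
  P <- ncol(m)
  L <- sum(m)
  tibble(
    n_rows = C, n_cols = P, n_links = L,
    connectance = L / (C * P),
    rectangularity = abs(P - C) / (P + C),
    mean_degree_rows = L / C,
    mean_degree_cols = L / P
  )
}

#' @export
glance.bipartite_graph <- function(x, ...) graph_summary(x)

#' Degree sequences of both layers
#'
#' Row degrees are the *diversification* `d_c` (number of column nodes a row
#' node touches); column degrees are the *ubiquity* `u_p`. Their sums coincide
#' with the number of links.
#'
#' @param g a [bipartite_graph()].
#' @return tibble with columns `label`, `layer` (`"rows"`/`"cols"`), `degree`.
#' @export
node_degrees <- function(g) {
  m <- biadjacency(g)
  tibble(
    label = c(rownames(m), colnames(m)),
    layer = rep(c("rows", "cols"), c(nrow(m), ncol(m))),
    degree = c(as.integer(rowSums(m)), as.integer(colSums(m)))
  )
}

#' @export
tidy.bipartite_graph <- function(x, ...) {
  idx <- which(x$matrix == 1L, arr.ind = TRUE)
  tibble(
    row = rownames(x$matrix)[idx[, 1L]],
    col = colnames(x$matrix)[idx[, 2L]]
  )
}

#' Monopartite projection of a bipartite graph
#'
#' The weighted projection on the row layer is `M %*% t(M)`: its off-diagonal
#' entry counts the column nodes shared by two row nodes and its diagonal is
#' the row degree sequence. The binary projection applies a step function to
#' the weights and zeroes the diagonal, linking two same-layer nodes whenever
#' they share at least one neighbour. The column-layer projection uses
#' `t(M) %*% M` symmetrically.
#'
#' @param g a [bipartite_graph()].
#' @param layer `"rows"` or `"cols"`.
#' @return object of class `bipartite_projection` with elements `labels`,
#'   `weights`, `binary`, `layer`.
#' @export
project <- function(g, layer = c("rows", "cols")) {
  layer <- match.arg(layer)
  m <- biadjacency(g)
  w <- if (layer == "rows") tcrossprod(m) else crossprod(m)
  b <- (w > 0) + 0L
  diag(b) <- 0L
  structure(
    list(labels = rownames(w), weights = w, binary = b, layer = layer),
    class = "bipartite_projection"
  )
}

#' @export
print.bipartite_projection <- function(x, ...) {
  cat(sprintf(
    "# bipartite_projection (%s layer): %d nodes, %d binary edges\n",
    x$layer, length(x$labels), sum(x$binary) / 2
  ))
  invisible(x)
}

#' @export
tidy.bipartite_projection <- function(x, ...) {
  idx <- which(upper.tri(x$weights) & x$weights > 0, arr.ind = TRUE)
  tibble(
    from = x$labels[idx[, 1L]],
    to = x$labels[idx[, 2L]],
    weight = x$weights[idx]
  )
}

# reorder rows/columns, keeping labels attached
permute_graph <- function(g, row_order = NULL, col_order = NULL) {
  m <- biadjacency(g)
  if (!is.null(row_order)) m <- m[row_order, , drop = FALSE]
  if (!is.null(col_order)) m <- m[, col_order, drop = FALSE]
  new_bipartite_graph(m)
}
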