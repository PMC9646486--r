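# Mutual k-nearest-neighbor graph over cells and the column-stochastic
# random-walk transition matrix. kNN is exact (full Euclidean distances);
# ties are broken by lower cell index so everything is deterministic.

#' Exact k-nearest-neighbor search in embedding space
#'
#' Euclidean distances between all pairs of cells are computed from the
#' embedding coordinates; each cell's `k` nearest other cells are returned,
#' nearest first, ties broken by lower cell index.
#'
#' @param embedding An `lsi_embedding` or a numeric cells x d matrix.
#' @param k Number of neighbors (default 30).
#' @return Integer matrix, n_cells x k; row i holds the ordered neighbor
#'   indices of cell i.
#' @export
knn_search <- function(embedding, k = 30) {
  coords <- if (inherits(embedding, "lsi_embedding")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  if (k >= n) stop_tp("k = ", k, " must be smaller than the number of cells (", n, ")")
  if (k < 1) stop_tp("k must be >= 1")
  dmat <- as.matrix(stats::dist(coords))
  diag(dmat) <- Inf
  nn <- matrix(0L, n, k)
  idx <- seq_len(n)
  for (i in idx) {
    ord <- order(dmat[i, ], idx)   # ties -> lower index first
    nn[i, ] <- ord[seq_len(k)]
  }
  nn
}

#' Build the mutual-kNN cell graph
#'
#' An undirected edge joins cells i and j iff each appears in the other's
#' k-nearest-neighbor list. A cell left without any mutual edge is connected
#' to its single nearest neighbor (a "fallback" edge) so that every cell has
#' degree >= 1. The mutuality requirement caps the mutual degree at `k` and
#' prevents extreme hubs.
#'
#' @param neighbors Integer neighbor matrix from [knn_search()].
#' @return An object of class `cell_graph`: list with `n_cells`, `edges`
#'   (tibble `i`, `j`, `fallback`, i < j), `degree`, `mutual_degree`,
#'   `n_components`, and `k`.
#' @export
build_mknn_graph <- function(neighbors) {
  n <- nrow(neighbors)
  k <- ncol(neighbors)
  # mutual edges: j in nn[i] and i in nn[j]
  ii <- rep(seq_len(n), each = k)
  jj <- as.integer(t(neighbors))
  # membership test via sparse indicator of the directed kNN relation
  ind <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  mutual <- ind * Matrix::t(ind)            # 1 where both directions present
  mutual_t <- methods::as(Matrix::triu(mutual, k = 1), "TsparseMatrix")
  ei <- mutual_t@i + 1L
  ej <- mutual_t@j + 1L
  mdeg <- integer(n)
  tab <- table(c(ei, ej))
  mdeg[as.integer(names(tab))] <- as.integer(tab)
  isolated <- which(mdeg == 0L)
  fi <- fj <- integer(0)
  if (length(isolated) > 0) {
    nn1 <- neighbors[isolated, 1L]
    fi <- pmin(isolated, nn1)
    fj <- pmax(isolated, nn1)
    dup <- duplicated(cbind(fi, fj))        # two isolated cells may share an edge
    fi <- fi[!dup]; fj <- fj[!dup]
  }
  edges <- tibble::tibble(i = c(ei, fi), j = c(ej, fj),
                          fallback = rep(c(FALSE, TRUE), c(length(ei), length(fi))))
  edges <- edges[order(edges$i, edges$j), ]
  deg <- integer(n)
  tab <- table(c(edges$i, edges$j))
  deg[as.integer(names(tab))] <- as.integer(tab)
  g <- igraph::graph_from_edgelist(cbind(edges$i, edges$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  ncomp <- igraph::count_components(g)
  if (ncomp > 1) {
    warn_tp("mutual-kNN graph has ", ncomp, " connected components; ",
            "propagation mass stays within the seeded component(s)")
  }
  structure(list(n_cells = n, edges = edges, degree = deg,
                 mutual_degree = mdeg, n_components = ncomp, k = k),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, %d edges (%d fallback), %d component(s)\n",
              x$n_cells, nrow(x$edges), sum(x$edges$fallback), x$n_components))
  invisible(x)
}

#' Binary adjacency matrix of a cell graph
#'
#' @param graph A `cell_graph`.
#' @return Symmetric sparse 0/1 `dgCMatrix`.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  n <- graph$n_cells
  Matrix::sparseMatrix(i = c(graph$edges$i, graph$edges$j),
                       j = c(graph$edges$j, graph$edges$i),
                       x = 1, dims = c(n, n))
}

#' Column-stochastic random-walk transition matrix
#'
#' `M[i, j] = A[i, j] / degree(j)`: each column of the binary adjacency is
#' normalized to sum to one, so a walker at cell j moves to each neighbor
#' with equal probability.
#'
#' @param graph A `cell_graph` with minimum degree >= 1.
#' @return Sparse column-stochastic `dgCMatrix`.
#' @export
transition_matrix <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  if (any(graph$degree < 1)) {
    stop_tp("graph has isolated node(s); minimum degree must be >= 1")
  }
  A <- adjacency_matrix(graph)
  A %*% Matrix::Diagonal(graph$n_cells, 1 / graph$degree)
}

#' Export a graph as an edge-list TSV (`i j is_fallback`)
#'
#' @param graph A `cell_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graph_edges <- function(graph, path) {
  readr::write_tsv(dplyr::rename(graph$edges, is_fallback = "fallback"),
                   path, progress = FALSE)
  invisible(path)
}
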