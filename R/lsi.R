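# TF-IDF weighting and latent semantic indexing of the binarized
# peak-by-cell matrix. The SVD is computed exactly from the
# cell-by-cell cross-product, so the embedding is deterministic.

#' TF-IDF transform of a binarized peak-by-cell matrix
#'
#' The counts are binarized, then weighted as
#' `w[i, j] = tf[i, j] * log(1 + N / df[i])` (natural log), where `df[i]` is
#' the number of cells in which peak `i` is open and `N` the number of cells.
#' With `tf_mode = "frequency"` (default) the term frequency is the binary
#' entry divided by the cell's total number of open peaks, i.e. the matrix is
#' weighted against the total number of features per cell; with
#' `tf_mode = "binary"` the raw binary entry is used.
#'
#' @param pcm A [peak_cell_matrix()] or a sparse peaks x cells matrix.
#' @param tf_mode `"frequency"` (per-cell feature frequency, default) or
#'   `"binary"` (raw binarized entry).
#' @return A `dgCMatrix` of TF-IDF weights with the sparsity pattern of the
#'   binarized input.
#' @export
tfidf_transform <- function(pcm, tf_mode = c("frequency", "binary")) {
  tf_mode <- match.arg(tf_mode)
  m <- if (inherits(pcm, "peak_cell_matrix")) pcm$counts else
    methods::as(methods::as(methods::as(pcm, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  if (prod(dim(m)) == 0) stop_tp("matrix is empty")
  b <- Matrix::drop0(m)
  b@x <- rep(1, length(b@x))
  n_cells <- ncol(b)
  cell_totals <- as.numeric(Matrix::colSums(b))
  if (any(cell_totals == 0)) {
    bad <- colnames(b)[cell_totals == 0] %||% which(cell_totals == 0)
    stop_tp("cell(s) with zero open peaks (cannot form term frequencies): ",
            paste(head(bad, 5), collapse = ", "))
  }
  df <- as.numeric(Matrix::rowSums(b))
  idf <- ifelse(df > 0, log(1 + n_cells / df), 0)
  if (tf_mode == "frequency") {
    b <- b %*% Matrix::Diagonal(n_cells, 1 / cell_totals)
  }
  w <- Matrix::Diagonal(length(idf), idf) %*% b
  w <- methods::as(w, "CsparseMatrix")
  dimnames(w) <- dimnames(m)
  w
}

#' LSI embedding by truncated SVD of the TF-IDF matrix
#'
#' Returns the cell-side coordinates `V %*% Sigma` of the rank-`d` truncated
#' SVD `W = U Sigma V'`. The decomposition is computed exactly through the
#' eigendecomposition of the cells x cells cross-product `W'W`, so results
#' are deterministic; `seed` is accepted for interface compatibility with
#' randomized solvers and ignored. Component signs are canonicalized so that
#' the largest-magnitude loading of each component is positive.
#'
#' @param tfidf Sparse peaks x cells TF-IDF matrix from [tfidf_transform()].
#' @param d Number of components to keep (default 30).
#' @param seed Ignored (the solver is exact); present for call compatibility.
#' @param drop_depth_cor Drop components whose absolute Pearson correlation
#'   with log per-cell depth exceeds `depth_cor_limit` (off by default; the
#'   leading component of real scATAC-seq LSI often tracks sequencing
#'   depth).
#' @param depths Per-cell depths used for the correlation filter; defaults
#'   to the column sums of `tfidf`'s non-zero pattern (open-peak counts).
#' @param depth_cor_limit Correlation threshold for the filter
#'   (default 0.9).
#' @return An object of class `lsi_embedding`: list with `coords`
#'   (cells x `d`, rownames = barcodes), `d`, and `singular_values`
#'   (non-increasing).
#' @export
lsi_embed <- function(tfidf, d = 30, seed = NULL, drop_depth_cor = FALSE,
                      depths = NULL, depth_cor_limit = 0.9) {
  n_peaks <- nrow(tfidf)
  n_cells <- ncol(tfidf)
  if (d >= min(n_peaks, n_cells)) {
    stop_tp("d = ", d, " must be smaller than min(#peaks, #cells) = ",
            min(n_peaks, n_cells))
  }
  if (d < 2) stop_tp("d must be >= 2")
  # sparse crossprod wins on sparse inputs; BLAS on dense-ish ones
  dens <- length(methods::as(tfidf, "CsparseMatrix")@x) / prod(dim(tfidf))
  cp <- if (dens > 0.25) crossprod(as.matrix(tfidf)) else
    as.matrix(Matrix::crossprod(tfidf))   # cells x cells
  eig <- eigen(cp, symmetric = TRUE)
  ev <- pmax(eig$values[seq_len(d)], 0)
  sv <- sqrt(ev)
  coords <- eig$vectors[, seq_len(d), drop = FALSE] %*% diag(sv, d)
  # canonical sign: largest-magnitude coordinate positive per component
  for (j in seq_len(d)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  if (drop_depth_cor) {
    if (is.null(depths)) {
      b <- Matrix::drop0(tfidf)
      b@x <- rep(1, length(b@x))
      depths <- as.numeric(Matrix::colSums(b))
    }
    ld <- log1p(depths)
    cors <- abs(apply(coords, 2, stats::cor, y = ld))
    drop <- which(cors > depth_cor_limit)
    if (length(drop) > 0) {
      inform(paste0("dropping ", length(drop), " depth-correlated LSI ",
                    "component(s): ", paste(drop, collapse = ", ")))
      coords <- coords[, -drop, drop = FALSE]
      sv <- sv[-drop]
    }
  }
  rownames(coords) <- colnames(tfidf)
  new_lsi_embedding(coords, sv)
}

new_lsi_embedding <- function(coords, singular_values = NULL) {
  structure(list(coords = coords, d = ncol(coords),
                 singular_values = singular_values),
            class = "lsi_embedding")
}

#' @export
print.lsi_embedding <- function(x, ...) {
  cat(sprintf("<lsi_embedding> %d cells x %d components\n",
              nrow(x$coords), x$d))
  invisible(x)
}

#' Load a precomputed embedding (e.g. batch-corrected LSI) from TSV
#'
#' Supports substituting an externally computed, e.g. batch-corrected,
#' low-dimensional matrix for the built-in LSI. The file must have a
#' `barcode` first column; rows are re-ordered to match `barcodes`.
#'
#' @param path TSV with header `barcode` then numeric component columns.
#' @param barcodes Barcode order of the count matrix the embedding must match.
#' @return An `lsi_embedding` (with `singular_values = NULL`).
#' @export
load_external_embedding <- function(path, barcodes) {
  if (!file.exists(path)) stop_tp("file not found: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "barcode") stop_tp("first column must be `barcode`")
  if (nrow(df) != length(barcodes)) {
    stop_tp("embedding has ", nrow(df), " rows but the matrix has ",
            length(barcodes), " barcodes")
  }
  idx <- match(barcodes, df$barcode)
  if (anyNA(idx)) {
    stop_tp("barcode(s) missing from embedding: ",
            paste(head(barcodes[is.na(idx)], 5), collapse = ", "))
  }
  coords <- as.matrix(df[idx, -1, drop = FALSE])
  if (!is.numeric(coords)) stop_tp("embedding columns must be numeric")
  rownames(coords) <- barcodes
  new_lsi_embedding(coords)
}

#' Write an embedding to TSV (barcode first column)
#'
#' @param embedding An `lsi_embedding`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(embedding, path) {
  df <- tibble::as_tibble(embedding$coords, .name_repair = "minimal")
  names(df) <- paste0("LSI", seq_len(ncol(df)))
  df <- dplyr::bind_cols(tibble::tibble(barcode = rownames(embedding$coords)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
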