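# Readers/writers for the standard single-cell ATAC formats and basic
# sparsity diagnostics. Counts are stored peaks x cells (dgCMatrix); peaks are
# BED 0-based half-open; variants are 1-based (VCF-like).

#' Construct a peak-by-cell count matrix container
#'
#' Bundles a sparse non-negative count matrix (peaks in rows, cells in
#' columns) with its peak intervals and cell barcodes, validating that the
#' three agree.
#'
#' @param counts Sparse (or dense) non-negative count matrix, peaks x cells.
#' @param peaks Data frame with columns `chrom`, `start`, `end` (BED 0-based
#'   half-open), one row per matrix row.
#' @param barcodes Character vector of unique cell identifiers, one per
#'   matrix column.
#' @param validate Set to `FALSE` to skip consistency checks.
#'
#' @return An object of class `peak_cell_matrix`: a list with elements
#'   `counts` (`dgCMatrix`), `peaks` (tibble with an `index` column, 0-based)
#'   and `barcodes`.
#' @export
peak_cell_matrix <- function(counts, peaks, barcodes, validate = TRUE) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  peaks <- tibble::as_tibble(peaks)
  if (!all(c("chrom", "start", "end") %in% names(peaks))) {
    stop_tp("`peaks` needs columns chrom, start, end")
  }
  peaks$index <- seq_len(nrow(peaks)) - 1L
  if (validate) {
    if (nrow(peaks) != nrow(counts) || length(barcodes) != ncol(counts)) {
      stop_tp("dimension mismatch: counts are ", nrow(counts), " x ",
              ncol(counts), " but ", nrow(peaks), " peaks and ",
              length(barcodes), " barcodes were given")
    }
    if (anyDuplicated(barcodes)) stop_tp("barcodes must be unique")
    if (any(peaks$start >= peaks$end)) {
      bad <- which(peaks$start >= peaks$end)[1]
      stop_tp("malformed peak interval at row ", bad, ": start >= end")
    }
    if (any(counts@x < 0)) stop_tp("counts must be non-negative")
  }
  rownames(counts) <- NULL
  colnames(counts) <- barcodes
  structure(list(counts = counts, peaks = peaks,
                 barcodes = as.character(barcodes)),
            class = "peak_cell_matrix")
}

#' @export
print.peak_cell_matrix <- function(x, ...) {
  nz <- length(x$counts@x)
  cat(sprintf("<peak_cell_matrix> %d peaks x %d cells, %d non-zeros (%.1f%% sparse)\n",
              nrow(x$counts), ncol(x$counts), nz,
              100 * (1 - nz / prod(dim(x$counts)))))
  invisible(x)
}

#' @export
dim.peak_cell_matrix <- function(x) dim(x$counts)

#' Read a peak-by-cell matrix from MatrixMarket + BED + barcode files
#'
#' @param mtx_path MatrixMarket coordinate file (may be gzipped).
#' @param peaks_path BED3+ file of peak intervals, one per matrix row.
#' @param barcodes_path One barcode per line, one per matrix column.
#' @param cells_in_rows If `TRUE` the .mtx stores cells x peaks and is
#'   transposed on read.
#' @param validate Passed to [peak_cell_matrix()].
#'
#' @return A [peak_cell_matrix()].
#' @export
read_peak_cell_matrix <- function(mtx_path, peaks_path, barcodes_path,
                                  cells_in_rows = FALSE, validate = TRUE) {
  for (p in c(mtx_path, peaks_path, barcodes_path)) {
    if (!file.exists(p)) stop_tp("file not found: ", p)
  }
  counts <- Matrix::readMM(mtx_path)
  if (cells_in_rows) counts <- Matrix::t(counts)
  peaks <- read_bed_peaks(peaks_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(peaks) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop_tp("dimension mismatch between files: matrix ", nrow(counts), " x ",
            ncol(counts), ", ", nrow(peaks), " BED rows, ",
            length(barcodes), " barcodes")
  }
  peak_cell_matrix(counts, peaks, barcodes, validate = validate)
}

read_bed_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_tp("malformed BED line ", which(nf < 3)[1], " in ", path,
            ": fewer than 3 tab-separated fields")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop_tp("malformed BED line ", which(is.na(start) | is.na(end))[1],
            " in ", path, ": non-integer coordinates")
  }
  tibble::tibble(chrom = vapply(fields, `[[`, "", 1), start = start, end = end)
}

#' Write a peak-by-cell matrix to MatrixMarket + BED + barcode files
#'
#' @param pcm A [peak_cell_matrix()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_peak_cell_matrix <- function(pcm, dir, prefix = "matrix") {
  stopifnot(inherits(pcm, "peak_cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mtx = file.path(dir, paste0(prefix, ".mtx")),
             peaks = file.path(dir, paste0(prefix, ".peaks.bed")),
             barcodes = file.path(dir, paste0(prefix, ".barcodes.txt")))
  Matrix::writeMM(pcm$counts, paths[["mtx"]])
  writeLines(paste(pcm$peaks$chrom, pcm$peaks$start, pcm$peaks$end, sep = "\t"),
             paths[["peaks"]])
  writeLines(pcm$barcodes, paths[["barcodes"]])
  invisible(paths)
}

#' Read fine-mapped variants and filter on posterior probability
#'
#' Reads a tab-delimited table with header columns `chrom pos id pp` (and
#' optionally `trait`), validates posterior probabilities, and keeps only
#' records with PP strictly greater than `pp_threshold` (default 0.001, the
#' conventional retention filter for fine-mapped blood-trait variants).
#'
#' @param path TSV file (may be gzipped); `pos` is 1-based.
#' @param pp_threshold Strict lower bound on retained PP.
#' @param trait Optional trait label overriding/filling the `trait` column.
#' @return A tibble with columns `chrom`, `pos`, `id`, `pp`, `trait`,
#'   in file order.
#' @export
read_finemapped_variants <- function(path, pp_threshold = 0.001, trait = NULL) {
  if (!file.exists(path)) stop_tp("file not found: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  need <- c("chrom", "pos", "id", "pp")
  if (!all(need %in% names(df))) {
    stop_tp("variant file must have columns chrom, pos, id, pp; found: ",
            paste(names(df), collapse = ", "))
  }
  if (nrow(df) == 0) {
    warn_tp("variant file ", path, " is empty")
    return(tibble::tibble(chrom = character(), pos = integer(),
                          id = character(), pp = double(),
                          trait = character()))
  }
  validate_variants(df, pp_threshold = pp_threshold, trait = trait)
}

#' Validate and filter an in-memory variant table
#'
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `pp`.
#' @inheritParams read_finemapped_variants
#' @return Filtered tibble, order preserved.
#' @export
validate_variants <- function(variants, pp_threshold = 0.001, trait = NULL) {
  df <- tibble::as_tibble(variants)
  if (any(!is.finite(df$pp)) || any(df$pp < 0) || any(df$pp > 1)) {
    stop_tp("posterior probabilities must lie in [0, 1]; offending id(s): ",
            paste(head(df$id[!is.finite(df$pp) | df$pp < 0 | df$pp > 1], 3),
                  collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    dups <- unique(df$id[duplicated(df$id)])
    warn_tp("duplicate variant id(s) ", paste(head(dups, 3), collapse = ", "),
            "; keeping first occurrence of each")
    df <- df[!duplicated(df$id), ]
  }
  df <- df[df$pp > pp_threshold, ]
  if (is.null(df[["trait"]])) df$trait <- trait %||% NA_character_
  if (!is.null(trait)) df$trait <- trait
  df$pos <- as.integer(df$pos)
  df[, c("chrom", "pos", "id", "pp", "trait")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate variant posterior probabilities onto peaks
#'
#' Each variant's PP is added to every peak that contains it. Peaks are BED
#' 0-based half-open; the 1-based variant position is converted to 0-based
#' (`pos - 1`) before the containment test, so a variant at 1-based position
#' 101 lies inside the peak `[100, 200)`. A variant inside several
#' overlapping peaks contributes its full PP to each.
#'
#' @param variants Tibble as returned by [read_finemapped_variants()].
#' @param peaks Peak tibble (`chrom`, `start`, `end`), e.g. `pcm$peaks`.
#' @return Numeric weight vector, one entry per peak row.
#' @export
overlap_variants_peaks <- function(variants, peaks) {
  peaks <- tibble::as_tibble(peaks)
  w <- numeric(nrow(peaks))
  if (nrow(variants) > 0) {
    pk <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
    vr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
    hits <- GenomicRanges::findOverlaps(vr, pk)
    if (length(hits) > 0) {
      add <- tapply(variants$pp[S4Vectors_from(hits)], S4Vectors_to(hits), sum)
      w[as.integer(names(add))] <- as.numeric(add)
    }
  }
  if (sum(w) <= 0) {
    stop_tp("trait has no accessible causal variants: no variant position ",
            "falls inside any peak")
  }
  w
}

# thin indirection keeps S4Vectors out of the NAMESPACE imports
S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")

#' Per-peak and per-cell sparsity of a count matrix
#'
#' Peak sparsity is the fraction of cells with no signal for that peak; cell
#' sparsity is the fraction of peaks with no signal in that cell. In typical
#' scATAC-seq data both exceed 0.95, which is the motivation for propagating
#' trait enrichment over a cell-to-cell graph instead of trusting per-cell
#' co-localization alone.
#'
#' @param pcm A [peak_cell_matrix()].
#' @return A list with numeric vectors `peak` (length = #peaks) and `cell`
#'   (length = #cells), both in \[0, 1\].
#' @export
sparsity_metrics <- function(pcm) {
  stopifnot(inherits(pcm, "peak_cell_matrix"))
  m <- pcm$counts
  if (prod(dim(m)) == 0) stop_tp("matrix is empty")
  b <- m
  b@x <- as.numeric(b@x > 0)
  list(peak = 1 - as.numeric(Matrix::rowSums(b)) / ncol(m),
       cell = setNames(1 - as.numeric(Matrix::colSums(b)) / nrow(m),
                       pcm$barcodes))
}
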