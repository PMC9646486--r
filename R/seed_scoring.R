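# Per-cell bias-corrected trait-enrichment Z-scores (weighted chromatin
# accessibility deviations against bias-matched background peaks) and seed
# cell selection.

#' Bias-corrected weighted accessibility deviation Z-scores
#'
#' For each cell c the raw deviation is `sum_p w_p * (x_pc - e_pc)` where
#' `e_pc = row_total_p * col_total_c / grand_total` is the expected count
#' under independence of peaks and cells. The raw deviation is standardized
#' against `n_background` background deviations in which every weighted peak
#' is replaced by a bias-matched background peak — a peak sampled (with
#' replacement) from its nearest neighbors in standardized bias-feature
#' space. Bias features are log1p mean accessibility and, when supplied, GC
#' fraction; matching on them corrects technical confounding such as GC
#' content and amplification/depth bias.
#'
#' @param pcm A [peak_cell_matrix()].
#' @param peak_weights Non-negative per-peak weights from
#'   [overlap_variants_peaks()].
#' @param n_background Number of background draws (default 50).
#' @param gc Optional per-peak GC fraction used as a second bias feature.
#' @param n_candidates Background candidate pool size per weighted peak
#'   (nearest peaks in bias space; default 50).
#' @param seed RNG seed making the background draws reproducible.
#' @param trait Optional trait label attached to the result.
#' @return A tibble with columns `barcode`, `z` and attributes `raw`
#'   (raw deviations) and `method = "builtin"`.
#' @export
weighted_deviation_zscores <- function(pcm, peak_weights, n_background = 50,
                                       gc = NULL, n_candidates = 50,
                                       seed = 1L, trait = NULL) {
  stopifnot(inherits(pcm, "peak_cell_matrix"))
  m <- pcm$counts
  n_peaks <- nrow(m); n_cells <- ncol(m)
  if (length(peak_weights) != n_peaks) {
    stop_tp("peak_weights length ", length(peak_weights),
            " != number of peaks ", n_peaks)
  }
  if (all(peak_weights == 0)) stop_tp("all peak weights are zero")
  if (n_background < 2) stop_tp("n_background must be >= 2")

  row_tot <- as.numeric(Matrix::rowSums(m))
  col_tot <- as.numeric(Matrix::colSums(m))
  grand <- sum(row_tot)
  # deviation for an arbitrary weight vector, vectorized over cells:
  # w'X - (w'row_tot) * col_tot / grand
  dev_for <- function(w_idx, w_val) {
    obs <- as.numeric(w_val %*% m[w_idx, , drop = FALSE])
    obs - sum(w_val * row_tot[w_idx]) * col_tot / grand
  }

  widx <- which(peak_weights > 0)
  wval <- peak_weights[widx]
  raw <- dev_for(widx, wval)

  # bias features, standardized
  feats <- cbind(log1p(row_tot / n_cells))
  if (!is.null(gc)) {
    if (length(gc) != n_peaks) stop_tp("gc length != number of peaks")
    feats <- cbind(feats, gc)
  } else {
    inform("no GC feature supplied; background matching uses mean accessibility only")
  }
  feats <- scale(feats)
  feats[is.nan(feats)] <- 0

  # candidate pools: nearest peaks in bias space for each weighted peak
  n_cand <- min(n_candidates, n_peaks)
  cand <- matrix(0L, length(widx), n_cand)
  for (a in seq_along(widx)) {
    d2 <- colSums((t(feats) - feats[widx[a], ])^2)
    cand[a, ] <- order(d2, seq_len(n_peaks))[seq_len(n_cand)]
  }

  withr_seed(seed, {
    bg <- matrix(0, n_cells, n_background)
    for (b in seq_len(n_background)) {
      pick <- cand[cbind(seq_along(widx), sample.int(n_cand, length(widx), replace = TRUE))]
      # several weighted peaks can map to the same background peak: sum weights
      agg <- rowsum(wval, pick)
      bg[, b] <- dev_for(as.integer(rownames(agg)), as.numeric(agg))
    }
  })

  mu <- rowMeans(bg)
  sdv <- apply(bg, 1, stats::sd)
  z <- (raw - mu) / sdv
  degen <- !is.finite(z)
  if (any(degen)) {
    warn_tp(sum(degen), " cell(s) had zero background variance; z set to 0")
    z[degen] <- 0
  }
  out <- tibble::tibble(barcode = pcm$barcodes, z = as.numeric(z))
  attr(out, "raw") <- as.numeric(raw)
  attr(out, "method") <- "builtin"
  attr(out, "trait") <- trait
  out
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Per-peak GC fraction from a genome FASTA
#'
#' Computes the G+C base fraction of each peak interval for use as the
#' optional GC bias feature of [weighted_deviation_zscores()].
#'
#' @param fasta_path FASTA file whose sequence names cover the peak
#'   chromosomes.
#' @param peaks Peak tibble (`chrom`, `start`, `end`; BED 0-based
#'   half-open).
#' @return Numeric vector of GC fractions, one per peak.
#' @export
gc_content_from_fasta <- function(fasta_path, peaks) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_tp("gc_content_from_fasta() needs the Biostrings package")
  }
  if (!file.exists(fasta_path)) stop_tp("file not found: ", fasta_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  peaks <- tibble::as_tibble(peaks)
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing) > 0) {
    stop_tp("chromosome(s) absent from FASTA: ",
            paste(head(missing, 5), collapse = ", "))
  }
  lens <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  if (any(peaks$end > lens)) {
    stop_tp("peak(s) extend beyond their chromosome sequence (first at row ",
            which(peaks$end > lens)[1], ")")
  }
  seqs <- Biostrings::subseq(genome[peaks$chrom],
                             start = peaks$start + 1L, end = peaks$end)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE,
                                        as.prob = TRUE)
  as.numeric(freq[, "G"] + freq[, "C"])
}

#' Load externally computed per-cell Z-scores
#'
#' Escape hatch for users who score cells with an external bias-corrected
#' deviation tool: a two-column TSV (`barcode`, `z`) is re-ordered to the
#' count matrix barcode order.
#'
#' @param path TSV with header columns `barcode` and `z`.
#' @param barcodes Barcode order of the count matrix.
#' @return A tibble (`barcode`, `z`) with `method = "external"` attribute.
#' @export
load_external_zscores <- function(path, barcodes) {
  if (!file.exists(path)) stop_tp("file not found: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("barcode", "z") %in% names(df))) {
    stop_tp("z-score file must have columns `barcode` and `z`")
  }
  idx <- match(barcodes, df$barcode)
  if (anyNA(idx)) {
    stop_tp("barcode(s) missing from z-score file: ",
            paste(head(barcodes[is.na(idx)], 5), collapse = ", "))
  }
  out <- tibble::tibble(barcode = barcodes, z = as.numeric(df$z[idx]))
  attr(out, "method") <- "external"
  out
}

#' Select seed cells from trait Z-scores
#'
#' Cells whose upper-tail normal p-value is below `alpha` (i.e.
#' `z > qnorm(1 - alpha)`) form the initial seed set; if they exceed
#' `floor(cap_fraction * n_cells)` cells, only the that many highest-z cells
#' are kept (ties broken by lower cell index). Five percent of cells is
#' normally ample to represent the trait-relevant population.
#'
#' @param z Tibble from [weighted_deviation_zscores()] or a numeric vector.
#' @param alpha Upper-tail p-value cutoff for the initial filter
#'   (default 0.05).
#' @param cap_fraction Maximum fraction of cells kept as seeds
#'   (default 0.05).
#' @return An object of class `seed_set`: list with logical `indicator`,
#'   `n_seeds`, and `z_threshold_used` (the normal quantile applied).
#' @export
select_seed_cells <- function(z, alpha = 0.05, cap_fraction = 0.05) {
  zv <- if (is.data.frame(z)) z$z else as.numeric(z)
  if (any(!is.finite(zv))) stop_tp("z-scores must be finite")
  check_scalar_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  check_scalar_prob(cap_fraction, "cap_fraction", open_left = TRUE)
  n <- length(zv)
  thr <- stats::qnorm(1 - alpha)
  init <- which(zv > thr)
  if (length(init) == 0) {
    stop_tp("no cell passes the seed filter: max z = ",
            format(max(zv), digits = 4), " but the threshold is ",
            format(thr, digits = 4),
            "; consider supplying external z-scores or raising alpha")
  }
  cap <- max(1L, as.integer(floor(cap_fraction * n)))
  keep <- init
  if (length(init) > cap) {
    ord <- order(-zv[init], init)      # highest z first, ties by lower index
    keep <- init[ord[seq_len(cap)]]
  }
  ind <- logical(n)
  ind[keep] <- TRUE
  structure(list(indicator = ind, n_seeds = length(keep),
                 z_threshold_used = thr),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seeds of %d cells (z > %.4f)\n",
              x$n_seeds, length(x$indicator), x$z_threshold_used))
  invisible(x)
}
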