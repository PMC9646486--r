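# Independent slow oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (dense loops, all-pairs scans) so they stay
# independent of the implementation paths they check.

toy_pcm <- function(counts, chrom = "chr1", width = 100L) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  start <- (seq_len(n) - 1L) * 2L * width
  peak_cell_matrix(counts,
                   data.frame(chrom = chrom, start = start,
                              end = start + width),
                   sprintf("bc%03d", seq_len(ncol(counts))))
}

random_pcm <- function(n_peaks, n_cells, density = 0.3, max_count = 5,
                       seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_peaks * n_cells, 1, density) *
                sample(max_count, n_peaks * n_cells, replace = TRUE),
              n_peaks, n_cells)
  # ensure no empty cell (TF-IDF precondition)
  for (j in which(colSums(m) == 0)) m[sample(n_peaks, 1), j] <- 1
  toy_pcm(m)
}

# dense elementwise TF-IDF evaluation
oracle_tfidf <- function(counts, tf_mode = "frequency") {
  b <- (as.matrix(counts) > 0) * 1
  N <- ncol(b)
  out <- matrix(0, nrow(b), N)
  for (i in seq_len(nrow(b))) {
    df_i <- sum(b[i, ] > 0)
    if (df_i == 0) next
    for (j in seq_len(N)) {
      tf <- if (tf_mode == "frequency") b[i, j] / sum(b[, j]) else b[i, j]
      out[i, j] <- tf * log(1 + N / df_i)
    }
  }
  out
}

# all-pairs kNN lists with index tie-break
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

# mutual edge set from neighbor lists, as a sorted i<j matrix
oracle_mutual_edges <- function(nn) {
  n <- nrow(nn)
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in nn[i, ]) {
      if (j > i && i %in% nn[j, ]) edges <- rbind(edges, c(i, j))
    }
  }
  if (is.null(edges)) matrix(integer(0), 0, 2) else
    edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# quadratic variant-in-peak weight accumulation
oracle_overlap <- function(variants, peaks) {
  w <- numeric(nrow(peaks))
  for (v in seq_len(nrow(variants))) {
    pos0 <- variants$pos[v] - 1L
    for (p in seq_len(nrow(peaks))) {
      if (variants$chrom[v] == peaks$chrom[p] &&
          pos0 >= peaks$start[p] && pos0 < peaks$end[p]) {
        w[p] <- w[p] + variants$pp[v]
      }
    }
  }
  w
}

# auROC by explicit concordant-pair counting (ties count half)
oracle_auroc <- function(scores, pos) {
  s_pos <- scores[pos]
  s_neg <- scores[!pos]
  tot <- 0
  for (a in s_pos) for (b in s_neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s_pos) * length(s_neg))
}

# cell_graph object from an explicit edge list (testing transition math)
graph_from_edges <- function(n, edges) {
  edges <- as.data.frame(edges)
  names(edges) <- c("i", "j")
  edges$fallback <- FALSE
  deg <- integer(n)
  tab <- table(c(edges$i, edges$j))
  deg[as.integer(names(tab))] <- as.integer(tab)
  structure(list(n_cells = n, edges = tibble::as_tibble(edges),
                 degree = deg, mutual_degree = deg,
                 n_components = NA_integer_, k = NA_integer_),
            class = "cell_graph")
}

# standard small synthetic dataset used by several suites
standard_fixture <- function(seed = 42, cells_per_type = 300, q = 0.3) {
  bulk <- synthetic_bulk_profiles(seed = seed)
  sim <- synthesize_cells(bulk, n = 10000, q = q,
                          cells_per_type = cells_per_type, seed = seed)
  variants <- synthetic_variants(bulk, "typeA", seed = seed)
  list(bulk = bulk, sim = sim, variants = variants)
}
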