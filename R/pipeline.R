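# End-to-end wrapper: counts + variants -> per-cell trait relevance, with
# broom-style tidy()/glance() and ggplot2 autoplot() on the fitted object.

#' Score per-cell trait relevance by seeded network propagation
#'
#' Runs the full pipeline on a peak-by-cell count matrix and a set of
#' fine-mapped variants: per-cell bias-corrected enrichment Z-scores
#' ([weighted_deviation_zscores()]), seed selection
#' ([select_seed_cells()]), TF-IDF/LSI embedding ([lsi_embed()]),
#' mutual-kNN graph ([build_mknn_graph()]), random walk with restart
#' ([random_walk_restart()]), TRS rescaling ([compute_trs()]) and,
#' optionally, the degree-matched permutation test ([permutation_test()]).
#' Any of z-scores and embedding can be supplied precomputed, replacing the
#' corresponding stage.
#'
#' @param pcm A [peak_cell_matrix()].
#' @param variants Variant tibble (ignored when `z` is given).
#' @param z Optional precomputed per-cell z tibble/vector.
#' @param embedding Optional precomputed `lsi_embedding`.
#' @param d LSI components (default 30).
#' @param tf_mode Passed to [tfidf_transform()].
#' @param k Neighbors for the mutual-kNN graph (default 30).
#' @param seed_alpha Seed-filter upper-tail p cutoff (default 0.05).
#' @param cap_fraction Seed cap as a fraction of cells (default 0.05).
#' @param n_background Background draws for the z scorer (default 50).
#' @param gc Optional per-peak GC fraction (bias feature).
#' @param gamma Restart probability (default 0.05).
#' @param tol Convergence tolerance (default 1e-5).
#' @param max_iter Iteration cap (default 1000).
#' @param norm Convergence norm, `"l1"` or `"linf"`.
#' @param ceiling_quantile,top_fraction Passed to [compute_trs()].
#' @param permute Run the permutation test (default `FALSE`).
#' @param B Number of permutations (default 1000).
#' @param perm_alpha Enrichment call threshold on the empirical p
#'   (default 0.05).
#' @param seed Global RNG seed for the scorer and permutation streams.
#'
#' @return An object of class `trait_relevance`: list with `cells` (tibble
#'   `barcode`, `z`, `is_seed`, `np`, `trs`, and `p`/`state` when permuted),
#'   `graph`, `seed_set`, `propagation`, `trs` (`trs_vector`), `embedding`,
#'   and `params`.
#' @export
trait_relevance <- function(pcm, variants = NULL, z = NULL, embedding = NULL,
                            d = 30, tf_mode = "frequency", k = 30,
                            seed_alpha = 0.05, cap_fraction = 0.05,
                            n_background = 50, gc = NULL,
                            gamma = 0.05, tol = 1e-5, max_iter = 1000,
                            norm = "l1", ceiling_quantile = 0.99,
                            top_fraction = 0.01, permute = FALSE, B = 1000,
                            perm_alpha = 0.05, seed = 1L) {
  stopifnot(inherits(pcm, "peak_cell_matrix"))
  if (is.null(z)) {
    if (is.null(variants)) stop_tp("supply either `variants` or `z`")
    w <- overlap_variants_peaks(variants, pcm$peaks)
    z <- weighted_deviation_zscores(pcm, w, n_background = n_background,
                                    gc = gc, seed = seed)
  } else if (!is.data.frame(z)) {
    z <- tibble::tibble(barcode = pcm$barcodes, z = as.numeric(z))
  }
  if (is.null(embedding)) {
    tfidf <- tfidf_transform(pcm, tf_mode = tf_mode)
    embedding <- lsi_embed(tfidf, d = d)
  }
  nn <- knn_search(embedding, k = k)
  graph <- build_mknn_graph(nn)
  M <- transition_matrix(graph)
  seeds <- select_seed_cells(z, alpha = seed_alpha,
                             cap_fraction = cap_fraction)
  v0 <- initial_distribution(seeds, graph$n_cells)
  prop <- random_walk_restart(M, v0, gamma = gamma, tol = tol,
                              max_iter = max_iter, norm = norm)
  trs <- compute_trs(prop, z, ceiling_quantile = ceiling_quantile,
                     top_fraction = top_fraction)
  cells <- tibble::tibble(barcode = pcm$barcodes, z = z$z,
                          is_seed = seeds$indicator, np = prop$np,
                          trs = trs$trs)
  if (permute) {
    pt <- permutation_test(M, graph, seeds, prop$np, B = B, gamma = gamma,
                           tol = tol, max_iter = max_iter, norm = norm,
                           alpha = perm_alpha, seed = seed)
    cells$p <- pt$p
    cells$state <- pt$state
  }
  structure(list(cells = cells, graph = graph, seed_set = seeds,
                 propagation = prop, trs = trs, embedding = embedding,
                 params = list(d = d, tf_mode = tf_mode, k = k,
                               seed_alpha = seed_alpha,
                               cap_fraction = cap_fraction,
                               n_background = n_background, gamma = gamma,
                               tol = tol, max_iter = max_iter, norm = norm,
                               ceiling_quantile = ceiling_quantile,
                               top_fraction = top_fraction,
                               permute = permute,
                               B = if (permute) B else NA_integer_,
                               perm_alpha = perm_alpha, seed = seed)),
            class = "trait_relevance")
}

#' @export
print.trait_relevance <- function(x, ...) {
  cat(sprintf(paste0("<trait_relevance> %d cells, %d seeds, converged in %d",
                     " iterations; scale factor %.3f\n"),
              nrow(x$cells), x$seed_set$n_seeds, x$propagation$iterations,
              x$trs$scale_factor))
  if (!is.null(x$cells$state)) {
    cat(sprintf("  %.1f%% of cells trait-enriched (empirical p < %g, B = %d)\n",
                100 * mean(x$cells$state == "enriched"),
                x$params$perm_alpha, x$params$B))
  }
  invisible(x)
}

#' @rdname trait_relevance
#' @param x A `trait_relevance` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trait_relevance <- function(x, ...) x$cells

#' @rdname trait_relevance
#' @exportS3Method generics::glance
glance.trait_relevance <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells),
                 n_seeds = x$seed_set$n_seeds,
                 n_edges = nrow(x$graph$edges),
                 n_fallback_edges = sum(x$graph$edges$fallback),
                 n_components = x$graph$n_components,
                 iterations = x$propagation$iterations,
                 converged = x$propagation$converged,
                 scale_factor = x$trs$scale_factor,
                 ceiling_value = x$trs$ceiling_value,
                 frac_enriched = if (is.null(x$cells$state)) NA_real_
                                 else mean(x$cells$state == "enriched"))
}

#' Plot per-cell trait relevance in embedding space
#'
#' Scatter of the first two embedding components colored by TRS (or any
#' per-cell column of the result).
#'
#' @param object A `trait_relevance` object.
#' @param colour Cell column to map to color (default `"trs"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trait_relevance <- function(object, colour = "trs", ...) {
  df <- tibble::tibble(dim1 = object$embedding$coords[, 1],
                       dim2 = object$embedding$coords[, 2])
  df[[colour]] <- object$cells[[colour]]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                        colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "LSI 1", y = "LSI 2", colour = colour) +
    ggplot2::theme_minimal()
  if (is.numeric(df[[colour]])) p <- p + ggplot2::scale_colour_viridis_c()
  p
}

#' @rdname autoplot.trait_relevance
#' @export
plot_trs <- function(object, colour = "trs", ...) {
  autoplot.trait_relevance(object, colour = colour, ...)
}
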