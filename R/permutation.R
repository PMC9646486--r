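# Degree-matched permutation null for propagation scores and per-cell
# enrichment calls.

#' Sample a degree-matched permuted seed set
#'
#' Draws a seed set of the same size whose multiset of graph degrees equals
#' the real seeds' degree multiset: within each degree class, permuted seeds
#' are sampled without replacement from all cells of that degree (real seeds
#' included as candidates). When a degree class has fewer candidates than
#' seeds of that degree, candidates are borrowed from the nearest degree
#' values (expanding +/-1, +/-2, ...) with a warning; in that case the
#' degree multiset matches only approximately.
#'
#' @param graph A `cell_graph`.
#' @param seed_set A `seed_set` (or logical indicator).
#' @param seed RNG seed.
#' @return Logical indicator vector of the permuted seeds.
#' @export
degree_matched_seed_sample <- function(graph, seed_set, seed = NULL) {
  ind <- if (inherits(seed_set, "seed_set")) seed_set$indicator
         else as.logical(seed_set)
  n <- graph$n_cells
  if (length(ind) != n) stop_tp("seed indicator length != n_cells")
  if (sum(ind) < 1) stop_tp("seed set is empty")
  deg <- graph$degree
  if (!is.null(seed)) set.seed(seed)
  seed_deg <- deg[ind]
  need <- table(seed_deg)
  chosen <- integer(0)
  for (dstr in names(need)) {
    d <- as.integer(dstr)
    m <- as.integer(need[[dstr]])
    pool <- which(deg == d)
    pool <- setdiff(pool, chosen)
    if (length(pool) < m) {
      width <- 0L
      while (length(pool) < m && width < max(deg)) {
        width <- width + 1L
        extra <- which(abs(deg - d) == width)
        pool <- union(pool, setdiff(extra, chosen))
      }
      warn_tp("degree class ", d, " has too few candidates; expanded to ",
              "degrees within +/-", width)
      if (length(pool) < m) {
        warn_tp("degree-matched sampling infeasible; falling back to ",
                "size-matched unconstrained sampling")
        chosen <- sample.int(n, sum(ind))
        ind_out <- logical(n); ind_out[chosen] <- TRUE
        return(ind_out)
      }
    }
    chosen <- c(chosen, pool[sample.int(length(pool), m)])
  }
  out <- logical(n)
  out[chosen] <- TRUE
  out
}

#' Propagation scores under the degree-matched permutation null
#'
#' Repeats the random walk `B` times, each from a freshly drawn
#' degree-matched permuted seed set with the corresponding uniform initial
#' distribution. Draw `b` uses RNG seed `seed + b`, so permutations are
#' independent and the whole collection is reproducible.
#'
#' @param M Column-stochastic transition matrix.
#' @param graph The `cell_graph` the degrees come from.
#' @param seed_set The real `seed_set`.
#' @param B Number of permutations (default 1000).
#' @param gamma,tol,max_iter,norm Passed to [random_walk_restart()].
#' @param seed Base RNG seed for the permutation stream.
#' @return Numeric matrix, n_cells x B, of permuted stationary scores.
#' @export
permutation_null <- function(M, graph, seed_set, B = 1000, gamma = 0.05,
                             tol = 1e-5, max_iter = 1000, norm = "l1",
                             seed = 1L) {
  if (B < 1) stop_tp("B must be >= 1")
  n <- graph$n_cells
  perm <- matrix(0, n, B)
  for (b in seq_len(B)) {
    ind_b <- degree_matched_seed_sample(graph, seed_set, seed = seed + b)
    v0_b <- initial_distribution(ind_b, n)
    perm[, b] <- random_walk_restart(M, v0_b, gamma = gamma, tol = tol,
                                     max_iter = max_iter, norm = norm)$np
  }
  perm
}

#' Empirical per-cell p-values against the permutation null
#'
#' `p_c = (1 + #\{b : real_np_c <= perm_np_cb\}) / (1 + B)`; ties count
#' against the real score, so p lies in `[1/(B+1), 1]` and the minimum is
#' reached exactly when the real score beats every permutation.
#'
#' @param real_np Real stationary scores (numeric or `propagation_scores`).
#' @param permuted Matrix from [permutation_null()] (n_cells x B).
#' @return A tibble with columns `np`, `exceed_count`, `p`.
#' @export
empirical_pvalues <- function(real_np, permuted) {
  np <- if (inherits(real_np, "propagation_scores")) real_np$np
        else as.numeric(real_np)
  if (nrow(permuted) != length(np)) stop_tp("dimension mismatch")
  B <- ncol(permuted)
  exceed <- rowSums(permuted >= np)
  tibble::tibble(np = np, exceed_count = as.integer(exceed),
                 p = (1 + exceed) / (1 + B))
}

#' Classify cells as trait-enriched or trait-depleted
#'
#' A cell is enriched iff its empirical p-value is strictly below `alpha`.
#'
#' @param pvalues Numeric p-values (or tibble with a `p` column).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of `"enriched"` / `"depleted"` labels.
#' @export
classify_cells <- function(pvalues, alpha = 0.05) {
  p <- if (is.data.frame(pvalues)) pvalues$p else as.numeric(pvalues)
  if (any(p <= 0 | p > 1)) stop_tp("p-values must lie in (0, 1]")
  ifelse(p < alpha, "enriched", "depleted")
}

#' Run the full permutation test
#'
#' Convenience wrapper: builds the null with [permutation_null()], computes
#' [empirical_pvalues()] and [classify_cells()].
#'
#' @inheritParams permutation_null
#' @param real_np Real stationary scores.
#' @param alpha Enrichment significance level (default 0.05).
#' @return A tibble with columns `np`, `exceed_count`, `p`, `state`.
#' @export
permutation_test <- function(M, graph, seed_set, real_np, B = 1000,
                             gamma = 0.05, tol = 1e-5, max_iter = 1000,
                             norm = "l1", alpha = 0.05, seed = 1L) {
  perm <- permutation_null(M, graph, seed_set, B = B, gamma = gamma,
                           tol = tol, max_iter = max_iter, norm = norm,
                           seed = seed)
  res <- empirical_pvalues(real_np, perm)
  res$state <- classify_cells(res$p, alpha = alpha)
  res
}
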