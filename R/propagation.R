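# Random walk with restart over the cell graph and conversion of the
# stationary distribution into the trait relevance score (TRS).

#' Uniform initial distribution over seed cells
#'
#' Probability mass 1 is split equally across the seed cells:
#' `v0 = 1/n_seeds` on seeds and 0 elsewhere.
#'
#' @param seed_set A `seed_set` (or logical indicator vector).
#' @param n_cells Total number of cells; defaults to the indicator length.
#' @return Numeric probability vector of length `n_cells`.
#' @export
initial_distribution <- function(seed_set, n_cells = NULL) {
  ind <- if (inherits(seed_set, "seed_set")) seed_set$indicator
         else as.logical(seed_set)
  if (is.null(n_cells)) n_cells <- length(ind)
  if (length(ind) != n_cells) stop_tp("indicator length != n_cells")
  ns <- sum(ind)
  if (ns < 1) stop_tp("seed set is empty")
  v0 <- numeric(n_cells)
  v0[ind] <- 1 / ns
  v0
}

#' Random walk with restart to the stationary distribution
#'
#' Iterates `v <- (1 - gamma) * M %*% v + gamma * v0` from `v = v0` until the
#' chosen norm of the change drops below `tol` or `max_iter` is reached.
#' With a column-stochastic `M` every iterate is a probability vector, so the
#' total mass stays 1 throughout; the restart probability `gamma` damps long
#' walks and guarantees geometric convergence (the map is a contraction with
#' factor `1 - gamma` in L1).
#'
#' @param M Column-stochastic sparse transition matrix from
#'   [transition_matrix()].
#' @param v0 Initial probability vector (the seed distribution).
#' @param gamma Restart probability in (0, 1) (default 0.05).
#' @param tol Convergence tolerance on the change between iterates
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 1000).
#' @param norm `"l1"` (default; sum of absolute changes) or `"linf"`
#'   (maximum absolute change).
#' @return An object of class `propagation_scores`: list with `np`
#'   (stationary probabilities), `iterations`, and `converged`.
#' @export
random_walk_restart <- function(M, v0, gamma = 0.05, tol = 1e-5,
                                max_iter = 1000, norm = c("l1", "linf")) {
  norm <- match.arg(norm)
  check_scalar_prob(gamma, "gamma", open_left = TRUE, open_right = TRUE)
  if (tol <= 0) stop_tp("tol must be > 0")
  if (max_iter < 1) stop_tp("max_iter must be >= 1")
  n <- length(v0)
  if (any(dim(M) != n)) stop_tp("M and v0 dimensions disagree")
  csums <- as.numeric(Matrix::colSums(M))
  if (max(abs(csums - 1)) > 1e-8) {
    stop_tp("M is not column-stochastic (max column-sum deviation ",
            format(max(abs(csums - 1)), digits = 3), ")")
  }
  if (abs(sum(v0) - 1) > 1e-8 || any(v0 < 0)) {
    stop_tp("v0 must be a probability vector")
  }
  nrm <- if (norm == "l1") function(x) sum(abs(x)) else function(x) max(abs(x))
  v <- v0
  converged <- FALSE
  iters <- 0L
  for (s in seq_len(max_iter)) {
    v_new <- as.numeric((1 - gamma) * (M %*% v)) + gamma * v0
    iters <- s
    if (nrm(v_new - v) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  if (!converged) {
    warn_tp("random walk did not converge within ", max_iter,
            " iterations (norm = ", norm, ", tol = ", tol, ")")
  }
  structure(list(np = v, iterations = iters, converged = converged),
            class = "propagation_scores")
}

#' @export
print.propagation_scores <- function(x, ...) {
  cat(sprintf("<propagation_scores> %d cells, %d iterations, converged: %s\n",
              length(x$np), x$iterations, x$converged))
  invisible(x)
}

#' Exact stationary distribution by direct linear solve
#'
#' Solves the fixed point of the restart iteration in closed form:
#' `v = gamma * (I - (1 - gamma) M)^{-1} v0`. Intended as an exact
#' cross-check of [random_walk_restart()] on graphs small enough for a dense
#' solve.
#'
#' @inheritParams random_walk_restart
#' @param size_guard Refuse dense solves above this many cells
#'   (default 5000).
#' @return Numeric probability vector.
#' @export
solve_stationary_exact <- function(M, v0, gamma = 0.05, size_guard = 5000) {
  check_scalar_prob(gamma, "gamma", open_left = TRUE)
  n <- length(v0)
  if (n > size_guard) {
    stop_tp("n = ", n, " exceeds the dense-solve guard (", size_guard,
            "); use random_walk_restart()")
  }
  if (gamma == 1) return(v0)
  A <- diag(n) - (1 - gamma) * as.matrix(M)
  as.numeric(gamma * solve(A, v0))
}

#' Convert stationary propagation scores into the trait relevance score
#'
#' The stationary scores are (1) clipped at their 99th percentile (linear
#' interpolation quantile) so a handful of extreme cells share a common
#' ceiling, (2) min-max scaled to \[0, 1\] across cells, and (3) multiplied
#' by a scale factor equal to the mean bias-corrected Z-score of the top 1%
#' of cells by z, which re-attaches the enrichment magnitude of the original
#' co-localization analysis and makes scores comparable across datasets of
#' different sizes.
#'
#' @param scores A `propagation_scores` (or numeric stationary vector).
#' @param z Tibble from [weighted_deviation_zscores()] or numeric z vector.
#' @param ceiling_quantile Clipping quantile (default 0.99).
#' @param top_fraction Fraction of top-z cells averaged into the scale
#'   factor (default 0.01).
#' @return An object of class `trs_vector`: list with `trs`, `scale_factor`,
#'   and `ceiling_value`.
#' @export
compute_trs <- function(scores, z, ceiling_quantile = 0.99,
                        top_fraction = 0.01) {
  np <- if (inherits(scores, "propagation_scores")) scores$np
        else as.numeric(scores)
  zv <- if (is.data.frame(z)) z$z else as.numeric(z)
  if (length(np) != length(zv)) stop_tp("np and z lengths differ")
  n <- length(np)
  if (n < 2) stop_tp("need at least 2 cells")
  check_scalar_prob(ceiling_quantile, "ceiling_quantile", open_left = TRUE)
  check_scalar_prob(top_fraction, "top_fraction", open_left = TRUE)

  ceiling_value <- as.numeric(stats::quantile(np, ceiling_quantile, type = 7))
  clipped <- pmin(np, ceiling_value)
  rng <- max(clipped) - min(clipped)
  m_top <- max(1L, as.integer(ceiling(top_fraction * n)))
  scale_factor <- mean(sort(zv, decreasing = TRUE)[seq_len(m_top)])
  if (rng == 0) {
    warn_tp("propagation scores are constant after clipping; TRS is all zero")
    trs <- numeric(n)
  } else {
    scaled <- (clipped - min(clipped)) / rng
    if (scale_factor < 0) {
      warn_tp("scale factor (mean top-", format(100 * top_fraction),
              "% z) is negative (", format(scale_factor, digits = 4),
              "); TRS signs follow it unmodified")
    }
    trs <- scaled * scale_factor
  }
  structure(list(trs = trs, scale_factor = scale_factor,
                 ceiling_value = ceiling_value),
            class = "trs_vector")
}
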