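uniform_bulk <- function(n_peaks, value = 10) {
  gap <- 1000L
  start <- (seq_len(n_peaks) - 1L) * gap
  structure(list(counts = matrix(value, n_peaks, 2,
                                 dimnames = list(NULL, c("typeA", "typeB"))),
                 peaks = tibble::tibble(chrom = "chrS", start = start,
                                        end = start + 500L),
                 cell_types = c("typeA", "typeB"),
                 specific = tibble::tibble(type = character(),
                                           peak = integer())),
            class = "bulk_profile")
}

test_that("noise limits of the binomial model collapse as expected", {
  k <- 400; n <- 200
  bulk <- synthetic_bulk_profiles(n_peaks = k, n_specific_peaks_per_type = 20,
                                  seed = 81)
  # q = 1: p_i = n/(2k) regardless of the bulk profile
  s1 <- synthesize_cells(bulk, n = n, q = 1, cells_per_type = 100, seed = 82)
  s2 <- synthesize_cells(uniform_bulk(k), n = n, q = 1, cells_per_type = 100,
                         seed = 82)
  expect_identical(as.matrix(s1$pcm$counts), as.matrix(s2$pcm$counts))
  p_unif <- n / (2 * k)
  mean_count <- sum(s1$pcm$counts) / prod(dim(s1$pcm$counts))
  se <- sqrt(2 * p_unif * (1 - p_unif) / (k * 200))
  expect_lt(abs(mean_count - 2 * p_unif), 3 * se)

  # q = 0: expected count of peak i equals r_i
  s0 <- synthesize_cells(bulk, n = n, q = 0, cells_per_type = 200, seed = 83)
  r <- n * bulk$counts[, 1] / sum(bulk$counts[, 1])
  obs <- Matrix::rowMeans(s0$pcm$counts[, s0$labels == "typeA"])
  idx <- which(r < 0.5)                   # clearly unclamped regime
  p <- r[idx] / 2
  se <- sqrt(sum(2 * p * (1 - p) / 200)) / length(idx)
  expect_lt(abs(mean(obs[idx] - r[idx])), 3 * se)
})

test_that("expected fragments per cell stay near n", {
  # uniform bulk, k = 12000, n = 6000, q = 0.3: E[total] = n
  k <- 12000; n <- 6000
  sim <- synthesize_cells(uniform_bulk(k), n = n, q = 0.3,
                          cells_per_type = 100, seed = 84)
  totals <- Matrix::colSums(sim$pcm$counts)
  p <- n / (2 * k)
  se <- sqrt(k * 2 * p * (1 - p) / length(totals))
  expect_lt(abs(mean(totals) - n), 3 * se)
  expect_lte(max(sim$pcm$counts@x), 2)     # binomial with 2 trials
  # saturated regime: p = n/(2k) = 1 forces exactly 2 reads everywhere,
  # so per-cell totals equal n deterministically
  sat <- synthesize_cells(uniform_bulk(1000), n = 2000, q = 0.3,
                          cells_per_type = 10, seed = 84)
  expect_true(all(Matrix::colSums(sat$pcm$counts) == 2000))
})

test_that("bulk generator elevates each type's specific block in its type", {
  bulk <- synthetic_bulk_profiles(n_peaks = 2000,
                                  n_specific_peaks_per_type = 100,
                                  signal_ratio = 10, seed = 85)
  blocks <- split(bulk$specific$peak, bulk$specific$type)
  for (t in c("typeA", "typeB")) {
    own <- mean(bulk$counts[blocks[[t]], t])
    other <- mean(bulk$counts[setdiff(unlist(blocks), blocks[[t]]), t])
    expect_gt(own, other)
  }
  # deterministic from the seed
  again <- synthetic_bulk_profiles(n_peaks = 2000,
                                   n_specific_peaks_per_type = 100,
                                   signal_ratio = 10, seed = 85)
  expect_identical(bulk$counts, again$counts)
})

test_that("ratio 1 without type dispersion makes types exchangeable", {
  bulk <- synthetic_bulk_profiles(n_peaks = 500,
                                  n_specific_peaks_per_type = 20,
                                  signal_ratio = 1, type_dispersion = 0,
                                  seed = 86)
  expect_identical(bulk$counts[, 1], bulk$counts[, 2])
})

test_that("synthetic variants land in target peaks at the requested rate", {
  bulk <- synthetic_bulk_profiles(n_peaks = 1000,
                                  n_specific_peaks_per_type = 50, seed = 87)
  target <- bulk$specific$peak[bulk$specific$type == "typeA"]
  in_target <- function(v) {
    hits <- vapply(v$pos - 1L, function(p0) {
      which(bulk$peaks$start <= p0 & p0 < bulk$peaks$end)[1]
    }, integer(1))
    mean(hits %in% target)
  }
  v1 <- synthetic_variants(bulk, "typeA", n_variants = 40,
                           target_fraction = 1, seed = 88)
  expect_equal(in_target(v1), 1)
  v0 <- synthetic_variants(bulk, "typeA", n_variants = 40,
                           target_fraction = 0, seed = 88)
  expect_equal(in_target(v0), 0)
  v8 <- synthetic_variants(bulk, "typeA", n_variants = 50,
                           target_fraction = 0.8, seed = 88)
  expect_equal(in_target(v8), 0.8)
  # every variant lies inside a peak: total overlap weight = total PP
  w <- overlap_variants_peaks(v8, bulk$peaks)
  expect_equal(sum(w), sum(v8$pp), tolerance = 1e-12)

  expect_error(synthetic_variants(bulk, "typeC"), "unknown target type")
})

test_that("ranking metrics match hand counts and the pairwise oracle", {
  scores <- c(rep(1, 500), rep(0, 500)) + rnorm(1000, sd = 1e-6)
  labels <- rep(c("pos", "neg"), each = 500)
  m <- evaluate_ranking(scores, labels, "pos")
  expect_equal(m$accuracy, 1)
  expect_equal(m$auroc, 1)
  expect_equal(m$tpr, 1)
  expect_equal(m$fpr, 0)

  set.seed(89)
  scores <- rnorm(2000)
  labels <- sample(c("a", "b"), 2000, TRUE)
  m <- evaluate_ranking(scores, labels, "a")
  n_pos <- sum(labels == "a"); n_neg <- sum(labels == "b")
  se <- sqrt((n_pos + n_neg + 1) / (12 * n_pos * n_neg))
  expect_lt(abs(m$auroc - 0.5), 3 * se)

  # 20 hand-written pairs with ties vs concordant-pair counting
  scores <- c(3, 1, 2, 2, 5, 0, 4, 2, 1, 3, 0, 5, 2, 4, 1, 3, 2, 0, 4, 5)
  labels <- rep(c("x", "y"), 10)
  m <- evaluate_ranking(scores, labels, "x")
  expect_equal(m$auroc, oracle_auroc(scores, labels == "x"))

  expect_error(evaluate_ranking(1:5, rep("x", 5), "x"), "one class")
})
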