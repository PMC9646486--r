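test_that("raw deviations vanish when observation equals expectation", {
  # every column proportional to row totals: x_pc == e_pc exactly
  row_profile <- c(4, 2, 1, 3)
  m <- outer(row_profile, c(1, 2, 3))
  pcm <- toy_pcm(m)
  w <- c(1, 0, 2, 0)
  res <- suppressMessages(suppressWarnings(
    weighted_deviation_zscores(pcm, w, n_background = 5, seed = 1)))
  expect_equal(attr(res, "raw"), rep(0, 3), tolerance = 1e-12)
  expect_equal(res$z, rep(0, 3))           # zero background variance -> 0
})

test_that("raw deviations equal the dense marginal-expectation oracle", {
  rnd <- random_pcm(40, 15, density = 0.3, seed = 51)
  w <- numeric(40); w[c(3, 7, 20)] <- c(0.5, 1, 0.25)
  res <- suppressMessages(
    weighted_deviation_zscores(rnd, w, n_background = 10, seed = 2))
  dense <- as.matrix(rnd$counts)
  e <- outer(rowSums(dense), colSums(dense)) / sum(dense)
  expect_equal(attr(res, "raw"),
               as.numeric(t(w) %*% (dense - e)), tolerance = 1e-10)
})

test_that("z separates a group whose specific peaks carry the weights", {
  set.seed(52)
  # group A cells open peaks 1:10; group B cells open peaks 11:20
  m <- rbind(cbind(matrix(rbinom(10 * 20, 1, 0.8), 10, 20),
                   matrix(rbinom(10 * 20, 1, 0.05), 10, 20)),
             cbind(matrix(rbinom(10 * 20, 1, 0.05), 10, 20),
                   matrix(rbinom(10 * 20, 1, 0.8), 10, 20)),
             matrix(rbinom(30 * 40, 1, 0.5), 30, 40))
  pcm <- toy_pcm(m)
  w <- numeric(50); w[1:10] <- 1
  res <- suppressMessages(
    weighted_deviation_zscores(pcm, w, n_background = 30, seed = 3))
  expect_gt(mean(res$z[1:20]), mean(res$z[21:40]))
})

test_that("background count changes z but not the raw deviation", {
  rnd <- random_pcm(60, 20, density = 0.3, seed = 53)
  w <- numeric(60); w[sample(60, 8)] <- runif(8)
  r1 <- suppressMessages(
    weighted_deviation_zscores(rnd, w, n_background = 2, seed = 7))
  r2 <- suppressMessages(
    weighted_deviation_zscores(rnd, w, n_background = 50, seed = 7))
  expect_equal(attr(r1, "raw"), attr(r2, "raw"))
  expect_false(isTRUE(all.equal(r1$z, r2$z)))
  # reproducible under the same seed
  r3 <- suppressMessages(
    weighted_deviation_zscores(rnd, w, n_background = 50, seed = 7))
  expect_identical(r2$z, r3$z)
})

test_that("external z-scores adopt the matrix barcode order", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "z.tsv")
  barcodes <- sprintf("bc%03d", 1:8)
  z <- rnorm(8)
  readr::write_tsv(tibble::tibble(barcode = barcodes, z = z), path)
  res <- load_external_zscores(path, barcodes)
  expect_equal(res$z, z)

  perm <- sample(8)
  readr::write_tsv(tibble::tibble(barcode = barcodes[perm], z = z[perm]), path)
  res <- load_external_zscores(path, barcodes)
  expect_equal(res$z, z)                 # order corrected

  readr::write_tsv(tibble::tibble(barcode = barcodes[-3], z = z[-3]), path)
  expect_error(load_external_zscores(path, barcodes), "bc003")
})

test_that("seed selection applies the one-tailed filter and the 5% cap", {
  # z = 1.65 passes p < 0.05 (threshold 1.6449); z = 1.64 does not
  z <- c(1.65, 1.64, rep(0, 18))
  s <- select_seed_cells(z)
  expect_identical(which(s$indicator), 1L)

  set.seed(54)
  z <- c(rnorm(900), rnorm(100, mean = 3))     # ~100 initial seeds
  s <- select_seed_cells(z)
  expect_identical(s$n_seeds, 50L)             # floor(0.05 * 1000)
  # brute-force sort oracle
  init <- which(z > qnorm(0.95))
  expect_gt(length(init), 50)
  top <- init[order(-z[init], init)][1:50]
  expect_identical(which(s$indicator), sort(top))
})

test_that("seed selection is monotone and errors without any seed", {
  set.seed(55)
  z <- rnorm(200)
  s <- select_seed_cells(z, alpha = 0.2, cap_fraction = 0.05)
  nonseed <- which(!s$indicator)[1]
  z2 <- z
  z2[nonseed] <- max(z) + 1
  s2 <- select_seed_cells(z2, alpha = 0.2, cap_fraction = 0.05)
  expect_true(s2$indicator[nonseed])

  expect_error(select_seed_cells(rep(-1, 50)), "no cell passes")
  # tiny datasets clamp the cap to at least one seed
  s3 <- select_seed_cells(c(3, 2.5, 0, 0, 0), cap_fraction = 0.05)
  expect_identical(s3$n_seeds, 1L)
})

test_that("GC fractions from a FASTA match hand-counted bases", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chrT test", "ACGTACGTGGGGCCCCAAAATTTT"), fa)
  peaks <- tibble::tibble(chrom = "chrT",
                          start = c(0L, 8L, 16L),
                          end = c(8L, 16L, 24L))
  gc <- gc_content_from_fasta(fa, peaks)
  expect_equal(gc, c(0.5, 1.0, 0.0))
  bad <- tibble::tibble(chrom = "chrT", start = 20L, end = 30L)
  expect_error(gc_content_from_fasta(fa, bad), "beyond")
  expect_error(gc_content_from_fasta(fa, tibble::tibble(
    chrom = "chrX", start = 0L, end = 4L)), "absent")
})
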