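test_that("MatrixMarket round-trip preserves counts exactly", {
  # hand-built toy: entries (1,1)=2 and (3,2)=1
  pcm <- toy_pcm(matrix(c(2, 0, 0, 0, 0, 1), 3, 2))
  expect_equal(as.matrix(pcm$counts),
               matrix(c(2, 0, 0, 0, 0, 1), 3, 2),
               ignore_attr = TRUE)

  dir <- withr::local_tempdir()
  write_peak_cell_matrix(pcm, dir)
  back <- read_peak_cell_matrix(file.path(dir, "matrix.mtx"),
                                file.path(dir, "matrix.peaks.bed"),
                                file.path(dir, "matrix.barcodes.txt"))
  expect_identical(as.matrix(back$counts), as.matrix(pcm$counts))
  expect_identical(back$barcodes, pcm$barcodes)

  # random 50x20: bitwise-equal non-zero set after write/read
  rnd <- random_pcm(50, 20, density = 0.2, seed = 99)
  write_peak_cell_matrix(rnd, dir, prefix = "rnd")
  back <- read_peak_cell_matrix(file.path(dir, "rnd.mtx"),
                                file.path(dir, "rnd.peaks.bed"),
                                file.path(dir, "rnd.barcodes.txt"))
  expect_identical(Matrix::which(back$counts != 0),
                   Matrix::which(rnd$counts != 0))
  expect_identical(as.matrix(back$counts), as.matrix(rnd$counts))
})

test_that("reader fails loudly on dimension mismatches and bad BED", {
  dir <- withr::local_tempdir()
  pcm <- toy_pcm(matrix(1, 4, 2))
  write_peak_cell_matrix(pcm, dir)
  # drop one BED row: 3 rows vs 4 declared in the mtx header
  bed <- readLines(file.path(dir, "matrix.peaks.bed"))
  writeLines(bed[1:3], file.path(dir, "matrix.peaks.bed"))
  expect_error(read_peak_cell_matrix(file.path(dir, "matrix.mtx"),
                                     file.path(dir, "matrix.peaks.bed"),
                                     file.path(dir, "matrix.barcodes.txt")),
               "dimension mismatch.*4 x 2.*3 BED")

  writeLines(c("chr1\t0\t100", "chr1\t200"), file.path(dir, "bad.bed"))
  expect_error(traitprop:::read_bed_peaks(file.path(dir, "bad.bed")), "line 2")
})

test_that("variant filter keeps strictly PP > threshold, order preserved", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "v.tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                                  id = c("a", "b", "c"),
                                  pp = c(0.5, 0.001, 0.0009)), path)
  v <- read_finemapped_variants(path)
  expect_identical(v$id, "a")          # 0.001 is not > 0.001

  readr::write_tsv(tibble::tibble(chrom = character(), pos = integer(),
                                  id = character(), pp = double()), path)
  expect_warning(v0 <- read_finemapped_variants(path), "empty")
  expect_identical(nrow(v0), 0L)

  # brute-force agreement on 100 random records at threshold 0.05
  set.seed(3)
  tbl <- tibble::tibble(chrom = "chr1", pos = seq_len(100),
                        id = sprintf("v%03d", 1:100), pp = runif(100))
  readr::write_tsv(tbl, path)
  v <- read_finemapped_variants(path, pp_threshold = 0.05)
  expect_identical(nrow(v), sum(tbl$pp > 0.05))
  expect_identical(v$id, tbl$id[tbl$pp > 0.05])
})

test_that("variant validation rejects bad PP and de-duplicates ids", {
  expect_error(validate_variants(tibble::tibble(
    chrom = "chr1", pos = 1L, id = "x", pp = 1.2)), "\\[0, 1\\]")
  expect_warning(v <- validate_variants(tibble::tibble(
    chrom = "chr1", pos = c(1L, 2L), id = c("x", "x"), pp = c(0.5, 0.9))),
    "duplicate")
  expect_identical(v$pos, 1L)          # first occurrence kept
})

test_that("variant-peak overlap follows BED/VCF coordinate conventions", {
  peaks <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  inside <- tibble::tibble(chrom = "chr1", pos = 101L, id = "in", pp = 0.4)
  expect_equal(overlap_variants_peaks(inside, peaks), 0.4)
  outside <- tibble::tibble(chrom = "chr1", pos = 100L, id = "out", pp = 0.4)
  expect_error(overlap_variants_peaks(outside, peaks),
               "no accessible causal variants")
  # end boundary: 1-based pos 200 -> 0-based 199, still inside [100, 200)
  edge <- tibble::tibble(chrom = "chr1", pos = 200L, id = "e", pp = 0.2)
  expect_equal(overlap_variants_peaks(edge, peaks), 0.2)
})

test_that("overlap weights match the quadratic oracle and are order-invariant", {
  set.seed(11)
  peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                          start = sample(0:500, 10))
  peaks$end <- peaks$start + sample(50:200, 10, TRUE)
  variants <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                             pos = sample(1:700, 20),
                             id = sprintf("v%02d", 1:20),
                             pp = runif(20))
  w_ref <- oracle_overlap(variants, peaks)
  expect_equal(overlap_variants_peaks(variants, peaks), w_ref)

  # permuting variants leaves the weights unchanged; permuting peaks
  # permutes the weights identically
  pv <- sample(nrow(variants))
  expect_equal(overlap_variants_peaks(variants[pv, ], peaks), w_ref)
  pp_ <- sample(nrow(peaks))
  expect_equal(overlap_variants_peaks(variants, peaks[pp_, ]), w_ref[pp_])

  # total weight never exceeds total retained PP
  expect_lte(sum(w_ref), sum(variants$pp) + 1e-12)
})

test_that("sparsity metrics equal explicit zero counting", {
  m <- matrix(1, 4, 3)
  m[, 2] <- 0                       # all-zero cell
  m[1, 2] <- 0
  pcm <- toy_pcm(m)
  sp <- sparsity_metrics(pcm)
  expect_equal(unname(sp$cell[2]), 1.0)
  expect_equal(sparsity_metrics(toy_pcm(matrix(1, 3, 3)))$peak, rep(0, 3))

  rnd <- random_pcm(30, 10, density = 0.25, seed = 5)
  sp <- sparsity_metrics(rnd)
  dense <- as.matrix(rnd$counts)
  expect_equal(sp$peak, apply(dense, 1, function(r) mean(r == 0)))
  expect_equal(unname(sp$cell),
               unname(apply(dense, 2, function(cc) mean(cc == 0))))
})
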