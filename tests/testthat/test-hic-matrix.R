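test_that("digest_genome cuts at recognition sites", {
  b <- digest_genome(c(chr1 = "AAAGATCAAAAA"), site = "GATC", cut_offset = 0)
  expect_equal(b$start, c(0, 3))
  expect_equal(b$end, c(3, 12))
  expect_equal(b$bin_id, 1:2)

  # no site -> whole-chromosome fragment
  b <- digest_genome(c(chr1 = "AAAA"), site = "GATC")
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(0, 4))

  # cut at position 0 yields an empty leading fragment, which is dropped
  b <- digest_genome(c(chr1 = "GATCGATC"), site = "GATC")
  expect_equal(b$start, c(0, 4))
  expect_equal(b$end, c(4, 8))
})

test_that("digestion is case-insensitive and N never matches", {
  b_lower <- digest_genome(c(c1 = "aaagatcaaaaa"))
  expect_equal(b_lower$start, c(0, 3))
  # an N inside the site spoils the match
  b <- digest_genome(c(c1 = "AAAGANCAAAAA"))
  expect_equal(nrow(b), 1L)
  expect_error(digest_genome(Biostrings::DNAStringSet()), "empty")
  expect_error(digest_genome(c(c1 = "ACGT"), site = ""), "non-empty")
})

test_that("digest fragments tile each chromosome exactly", {
  g <- simulate_genome(c(cA = 5000, cB = 3000), seed = 11)
  bins <- digest_genome(g)
  expect_silent(validate_bins(bins))
  lens <- tapply(bins$end - bins$start, bins$chrom, sum)
  expect_equal(as.numeric(lens[c("cA", "cB")]), c(5000, 3000))
})

test_that("annotate_pairs computes site distances and drops unknown chroms", {
  bins <- tile_bins(c(c1 = 1140), 570)  # borders at 0, 570, 1140
  pairs <- tibble::tibble(
    chrom1 = c("c1", "c1", "cX"), pos1 = c(570, 100, 5), strand1 = "+",
    mapq1 = 60,
    chrom2 = c("c1", "c1", "c1"), pos2 = c(0, 1000, 10), strand2 = "-",
    mapq2 = 60
  )
  ann <- annotate_pairs(pairs, bins)
  expect_equal(nrow(ann), 2L)
  expect_equal(attr(ann, "n_dropped_unknown_chrom"), 1L)
  expect_equal(ann$site_dist1, c(0, 100))   # exact cut site; min(100, 470)
  expect_equal(ann$site_dist2, c(0, 140))
  expect_equal(ann$bin1, c(2L, 1L))
})

test_that("filter_pairs applies the rules in order with exact bookkeeping", {
  bins <- tile_bins(c(c1 = 100000), 1000)
  mk <- function(pos1, pos2, mapq1 = 60, dangling = FALSE) {
    tibble::tibble(chrom1 = "c1", pos1 = pos1, strand1 = "+", mapq1 = mapq1,
                   chrom2 = "c1", pos2 = pos2, strand2 = "-", mapq2 = 60,
                   dangling = dangling)
  }
  pairs <- dplyr::bind_rows(
    mk(100, 5000, mapq1 = 10),     # low_mapq
    mk(200, 900),                  # 700 bp apart -> too_close
    mk(300, 6000),                 # clean
    mk(300, 6000),                 # exact duplicate of the previous
    mk(400, 7000)                  # clean
  )
  res <- filter_pairs(annotate_pairs(pairs, bins))
  expect_equal(nrow(res$pairs), 2L)
  st <- setNames(res$stats$n, res$stats$reason)
  expect_equal(unname(st[c("low_mapq", "too_close", "duplicate",
                           "dangling_end", "far_from_site", "kept")]),
               c(1L, 1L, 1L, 0L, 0L, 2L))

  # dangling flag and site distance
  pairs2 <- dplyr::bind_rows(mk(100, 5000, dangling = TRUE),
                             mk(55000, 90000))  # mate1 is 5 kb from a site
  bins2 <- tile_bins(c(c1 = 100000), 10000)
  res2 <- filter_pairs(annotate_pairs(pairs2, bins2))
  st2 <- setNames(res2$stats$n, res2$stats$reason)
  expect_equal(unname(st2["dangling_end"]), 1L)
  expect_equal(unname(st2["far_from_site"]), 1L)
  expect_equal(nrow(res2$pairs), 0L)
})

test_that("filter_pairs is idempotent and handles empty input", {
  bins <- simulate_bins(300, 570, seed = 5)
  pairs <- simulate_pairs(bins, n_clean = 40, n_low_mapq = 5, n_close = 5,
                          n_duplicate = 5, seed = 6)
  ann <- annotate_pairs(pairs, bins)
  res1 <- filter_pairs(ann)
  res2 <- filter_pairs(res1$pairs)
  expect_equal(nrow(res2$pairs), nrow(res1$pairs))
  expect_equal(sum(res2$stats$n[res2$stats$reason %in%
                                  c("low_mapq", "too_close", "duplicate",
                                    "dangling_end", "far_from_site")]), 0L)

  empty <- filter_pairs(ann[0, ])
  expect_equal(nrow(empty$pairs), 0L)
  expect_true(all(empty$stats$n == 0L))
})

test_that("bin_pairs conserves pair counts symmetrically", {
  bins <- tile_bins(c(c1 = 10000), 1000)
  pairs <- tibble::tibble(
    chrom1 = "c1", pos1 = c(2500, 100, 150), strand1 = "+", mapq1 = 60,
    chrom2 = "c1", pos2 = c(6500, 900, 950), strand2 = "-", mapq2 = 60
  )
  m <- bin_pairs(annotate_pairs(pairs, bins), bins)
  expect_equal(as.numeric(m$counts[3, 7]), 1)
  expect_equal(as.numeric(m$counts[7, 3]), 1)
  expect_equal(as.numeric(m$counts[1, 1]), 2)  # two pairs within bin 1
  expect_equal(matrix_total(m), 3)

  set.seed(9)
  bins2 <- simulate_bins(100, 570, seed = 2)
  rnd <- simulate_pairs(bins2, n_clean = 10, seed = 3)
  m2 <- bin_pairs(annotate_pairs(rnd, bins2), bins2)
  expect_equal(matrix_total(m2), 10)
  expect_true(Matrix::isSymmetric(m2$counts))
})

test_that("matrix round trip through triplet TSV is lossless", {
  bins <- simulate_bins(40, 500, model = "fixed")
  sim <- simulate_matrix(bins, n_tads = 2, depth = 20, edge_margin = 2000,
                         dropout = 0.1, seed = 7)
  m <- mask_low_bins(sim$matrix, 5)
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path)
  m2 <- read_matrix(path)
  expect_equal(m2$bins, m$bins)
  expect_identical(as.matrix(m2$counts), as.matrix(m$counts))
  expect_equal(m2$mask, m$mask)
  expect_null(m2$biases)

  mc <- ice_correct(m)
  write_matrix(mc, path)
  m3 <- read_matrix(path)
  expect_equal(m3$biases, mc$biases, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".bins.bed")))
})

test_that("matrix reader canonicalizes triplets and rejects bad input", {
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "m.tsv")
  bins <- tile_bins(c(c1 = 1500), 500)
  readr::write_tsv(dplyr::mutate(bins, mask = 1, bias = NA),
                   paste0(path, ".bins.bed"), col_names = FALSE)
  writeLines(c("bin_i\tbin_j\tcount", "2\t1\t5"), path)
  m <- read_matrix(path)
  expect_equal(as.numeric(m$counts[1, 2]), 5)

  writeLines(c("bin_i\tbin_j\tcount", "1\t2\t5", "2\t1\t4"), path)
  expect_error(read_matrix(path), "duplicate")
  writeLines(c("bin_i\tbin_j\tcount", "1\t2"), path)
  expect_error(read_matrix(path), "line 2")
  writeLines(c("bin_i\tbin_j\tcount", "1\tx\t5"), path)
  expect_error(read_matrix(path), "line 2")

  # overlapping bin sidecar violates the tiling invariant
  bad <- tibble::tibble(chrom = "c1", start = c(0, 400), end = c(500, 900),
                        bin_id = 1:2, mask = 1, bias = NA)
  readr::write_tsv(bad, paste0(path, ".bins.bed"), col_names = FALSE)
  writeLines(c("bin_i\tbin_j\tcount", "1\t2\t5"), path)
  expect_error(read_matrix(path), "overlap|gap")
  unlink(dir, recursive = TRUE)
})
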