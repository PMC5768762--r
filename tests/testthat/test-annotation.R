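test_that("mean_over_intervals is length-weighted with uncovered = 0", {
  track <- tibble::tibble(chrom = "c1", start = c(0, 500),
                          end = c(500, 1000), value = c(2, 2))
  iv <- tibble::tibble(chrom = "c1", start = 0, end = 1000)
  expect_equal(mean_over_intervals(track, iv), 2)

  track2 <- tibble::tibble(chrom = "c1", start = 500, end = 1000, value = 4)
  expect_equal(mean_over_intervals(track2, iv), 2)  # half 0, half 4

  # interval outside the covered region
  iv2 <- tibble::tibble(chrom = "c1", start = 5000, end = 6000)
  expect_equal(mean_over_intervals(track2, iv2), 0)
  iv3 <- tibble::tibble(chrom = "cX", start = 0, end = 100)
  expect_equal(mean_over_intervals(track2, iv3), 0)
})

test_that("classify_tads recovers one-hot archetypes and maps labels", {
  sim <- simulate_tad_marks(20, noise_sd = 0, seed = 71)
  out <- classify_tads(sim$marks, k = 5)
  expect_equal(out$label, sim$label)

  # noisy mixture, larger cohort
  sim2 <- simulate_tad_marks(200, noise_sd = 0.1, seed = 72)
  out2 <- classify_tads(sim2$marks, k = 5)
  expect_gte(mean(out2$label == sim2$label), 0.95)

  # all-zero signal -> everything inactive
  zero <- tibble::tibble(H3K36me3 = rep(0, 8), H3K4me3 = 0, H3K9me3 = 0,
                         H3K27me3 = 0)
  expect_true(all(classify_tads(zero, k = 5)$label == "inactive"))
  expect_error(classify_tads(zero[1:3, ], k = 5), "fewer TADs")
})

test_that("classify_tads labels are invariant under row permutation", {
  sim <- simulate_tad_marks(60, noise_sd = 0.1, seed = 73)
  out <- classify_tads(sim$marks, k = 5)
  perm <- sample(60)
  out_p <- classify_tads(sim$marks[perm, ], k = 5)
  expect_equal(out_p$label, out$label[perm])
})

test_that("tad_runs summarizes consecutive same-class TADs", {
  r <- tad_runs(c("active", "active", "PcG", "active"))
  expect_equal(r$label, c("active", "PcG", "active"))
  expect_equal(r$run_length, c(2L, 1L, 1L))
})

test_that("histone separation matrix is a valid correlation matrix", {
  set.seed(74)
  tads <- tibble::tibble(chrom = "c1",
                         start = seq(20000, 320000, by = 40000))
  tads$end <- tads$start + 25000
  # identical profile in every TAD -> all correlations 1
  seg <- tibble::tibble(chrom = "c1", start = seq(0, 399000, 1000),
                        end = seq(1000, 400000, 1000))
  seg$value <- 1 + (seg$start %/% 1000) %% 2
  cc <- histone_separation(tads, seg)
  expect_equal(dim(cc), c(45L, 45L))
  expect_equal(unname(diag(cc)), rep(1, 45))
  expect_equal(cc, t(cc))
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)

  # independent noise -> off-diagonal correlations near 0
  segn <- seg
  segn$value <- rnorm(nrow(segn))
  ccn <- histone_separation(tads, segn)
  off <- ccn[upper.tri(ccn)]
  expect_lt(mean(abs(off) > 3 / sqrt(nrow(tads))), 0.2)
})

test_that("nearest_distance handles inside, outside and missing peaks", {
  peaks <- tibble::tibble(chrom = "c1", start = c(40, 450), end = c(60, 520))
  pts <- tibble::tibble(chrom = c("c1", "c1", "c2"), pos = c(100, 500, 7))
  d <- nearest_distance(pts, peaks)$distance
  expect_equal(d[1], 40)   # min(|100-60|, |100-450|)
  expect_equal(d[2], 0)    # inside the second peak
  expect_true(is.na(d[3]))
})

# exact two-sided hypergeometric tail oracle for a 2x2 table
fisher_oracle <- function(n11, n10, n01, n00) {
  m <- n11 + n10; n <- n01 + n00; k <- n11 + n01
  x <- max(0, k - n):min(m, k)
  d <- dhyper(x, m, n, k)
  sum(d[d <= dhyper(n11, m, n, k) * (1 + 1e-7)])
}

test_that("overlap_fisher reproduces the cross-product OR and exact p", {
  # construct 100 1-kb genome bins: 10 with boundary+peak, 2 boundary only,
  # 3 peak only, 85 neither
  boundaries <- tibble::tibble(chrom = "c1",
                               pos = c(0:9, 10:11) * 1000 + 500)
  peaks <- tibble::tibble(chrom = "c1",
                          start = c(0:9, 12:14) * 1000 + 100)
  peaks$end <- peaks$start + 200
  out <- overlap_fisher(boundaries, peaks, c(c1 = 100000), bin_width = 1000)
  expect_equal(c(out$n_both, out$n_boundary_only, out$n_peak_only,
                 out$n_neither), c(10, 2, 3, 85))
  expect_equal(out$odds_ratio, 10 * 85 / (2 * 3))
  expect_equal(out$p_value, fisher_oracle(10, 2, 3, 85), tolerance = 1e-9)
})

test_that("strength_by_context groups boundaries by flanking TAD classes", {
  doms <- tibble::tibble(
    chrom = "c1",
    start = c(0, 100, 200, 300, 400),
    end = c(100, 200, 300, 400, 500),
    label = c("active", "inactive", "active", "active", "PcG")
  )
  set.seed(75)
  bd <- tibble::tibble(chrom = "c1", pos = c(100, 200, 300, 400),
                       score = rnorm(4))
  out <- strength_by_context(bd, doms)
  expect_setequal(unique(out$groups$context),
                  c("active-active", "active-inactive", "PcG-active"))
  expect_equal(nrow(out$groups), 4L)  # group sizes conserved
  expect_equal(nrow(out$comparisons), 3L)

  # clearly shifted score distributions separate two contexts
  doms2 <- tibble::tibble(chrom = "c1", start = 0:19 * 100,
                          end = 1:20 * 100,
                          label = rep(rep(c("active", "inactive"), each = 2), 5))
  bd2 <- tibble::tibble(chrom = "c1", pos = 1:19 * 100)
  # active-active junctions (every 4th boundary) carry much lower scores
  bd2$score <- ifelse(seq_len(19) %% 4 == 1, -3, 0) + rnorm(19, sd = 0.3)
  out2 <- strength_by_context(bd2, doms2)
  cmp <- out2$comparisons
  aa <- cmp[cmp$context1 == "active-active" | cmp$context2 == "active-active", ]
  expect_true(all(aa$p < 0.01))

  # single context -> no comparisons
  doms3 <- doms2; doms3$label <- "active"
  out3 <- strength_by_context(bd2, doms3)
  expect_equal(nrow(out3$comparisons), 0L)
})

test_that("pausing index is max promoter over median body coverage", {
  # + strand gene with TSS 1000: promoter [800, 1050), body [1050, end)
  track <- tibble::tibble(
    chrom = "c1",
    start = c(800, 900, 1000, 1050, 1500, 2000, 2500),
    end = c(900, 1000, 1050, 1500, 2000, 2500, 2850),
    value = c(1, 5, 3, 1, 1, 2, 1)
  )
  genes <- tibble::tibble(chrom = "c1", start = 1000, end = 2850,
                          strand = "+")
  expect_equal(pausing_index(track, genes)$pausing_index, 5)

  # uniform coverage -> index 1; positive rescaling leaves it unchanged
  flat <- tibble::tibble(chrom = "c1", start = 0, end = 5000, value = 3)
  expect_equal(pausing_index(flat, genes)$pausing_index, 1)
  flat10 <- dplyr::mutate(flat, value = value * 10)
  expect_equal(pausing_index(flat10, genes)$pausing_index, 1)

  # zero body median -> undefined
  promoter_only <- tibble::tibble(chrom = "c1", start = 800, end = 1050,
                                  value = 4)
  expect_true(is.na(pausing_index(promoter_only, genes)$pausing_index))

  # - strand gene: promoter downstream of the right end
  genes_m <- tibble::tibble(chrom = "c1", start = 1000, end = 2850,
                            strand = "-")
  tr_m <- tibble::tibble(chrom = "c1", start = c(1000, 2600),
                         end = c(2600, 2900), value = c(2, 9))
  # promoter [2800, 3050) has max 9 (0 outside track); body [1000, 2800)
  expect_equal(pausing_index(tr_m, genes_m)$pausing_index, 9 / 2)
})
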