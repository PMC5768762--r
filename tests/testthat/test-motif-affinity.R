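test_that("pwm construction applies pseudocounts and normalizes", {
  pwm <- pwm_from_counts(matrix(c(8, 0, 0, 0), 4, 1), pseudocount = 1)
  expect_equal(colSums(unclass(pwm)), 1)
  expect_true(all(unclass(pwm) > 0))
  expect_equal(unname(unclass(pwm)[1, 1]), 9 / 12)
  expect_error(pwm_from_counts(matrix(1, 3, 2)), "4 rows")
})

test_that("read_pwm parses JASPAR-style and plain tables", {
  f <- tempfile()
  writeLines(c(">MA0001 testmotif", "A [ 4 19 0 ]", "C [ 16 0 20 ]",
               "G [ 0 1 0 ]", "T [ 0 0 0 ]"), f)
  pwm <- read_pwm(f)
  expect_equal(attr(pwm, "width"), 3L)
  expect_equal(unname(unclass(pwm)[2, 1]), 17 / 24)
  writeLines(c("4 19 0", "16 0 20", "0 1 0", "0 0 0"), f)
  expect_equal(unclass(read_pwm(f)), unclass(pwm), ignore_attr = TRUE)
  unlink(f)
})

test_that("trap_score matches the closed form for a width-1 motif", {
  eps <- 1e-12
  p <- matrix(c(1 - 3 * eps, eps, eps, eps), 4, 1,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- structure(p, id = "A1", width = 1L, class = c("pwm", "matrix"))
  ln_R0 <- 0.584 * 1 - 5.66
  expected_fwd <- plogis(ln_R0)               # E = 0 on the A strand
  expect_equal(trap_score("A", pwm, both_strands = FALSE),
               log(expected_fwd), tolerance = 1e-9)
  # the reverse strand reads T and adds its mismatch term
  e_rev <- log((1 - 3 * eps) / eps) / 0.7
  expect_equal(trap_score("A", pwm),
               log(expected_fwd + plogis(ln_R0 - e_rev)), tolerance = 1e-9)
})

test_that("trap_score equals the brute-force double-strand window sum", {
  set.seed(82)
  pwm <- test_pwm()
  for (rep in 1:30) {
    L <- sample(20:80, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    expect_equal(trap_score(s, pwm), naive_trap(s, pwm), tolerance = 1e-10)
  }
  # sequences with Ns: N windows contribute 0 on both routes
  s <- "ACGTNNACGTACGTAN"
  expect_equal(trap_score(s, pwm), naive_trap(s, pwm), tolerance = 1e-10)
})

test_that("trap_score edge cases and monotonicity", {
  pwm <- test_pwm(width = 4)
  expect_error(trap_score("ACG", pwm), "shorter")
  expect_equal(trap_score("NNNNNN", pwm), -Inf)
  set.seed(83)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    # concatenation only gains windows: occupancy can only grow
    expect_gte(trap_score(paste0(a, b), pwm), trap_score(a, pwm))
    expect_gte(trap_score(paste0(a, b), pwm), trap_score(b, pwm))
  }
})

test_that("promoter sets split by boundary distance and drop N-rich ones", {
  set.seed(84)
  genome <- simulate_genome(c(c1 = 40000), seed = 84)
  genes <- tibble::tibble(
    chrom = "c1",
    start = c(10000, 10600, 20000, 30000),
    end = c(12000, 12600, 22000, 32000),
    strand = c("+", "+", "+", "-"),
    name = c("near", "near2", "mid", "far")
  )
  boundaries <- tibble::tibble(chrom = "c1", pos = c(10300, 21200))
  # gene "mid": TSS 20000, nearest boundary 1200 bp -> excluded band
  sets <- build_promoter_sets(genes, boundaries, genome)
  expect_true(all(c("near", "near2") %in% sets$boundary$name))
  expect_false("mid" %in% c(sets$boundary$name, sets$background$name))
  expect_true("far" %in% sets$background$name)
  expect_equal(unique(nchar(sets$boundary$seq)), 250L)

  # repeat masking: promoter of "near" overlaps a 40-bp repeat -> 16% N
  repeats <- tibble::tibble(chrom = "c1", start = 9850, end = 9890)
  sets2 <- build_promoter_sets(genes, boundaries, genome, repeats = repeats)
  expect_false("near" %in% sets2$boundary$name)
  expect_true("near2" %in% sets2$boundary$name)
})

test_that("minus-strand promoters are reverse-complemented", {
  genome <- c(c1 = paste(rep("A", 300), collapse = ""))
  genes <- tibble::tibble(chrom = "c1", start = 10, end = 260,
                          strand = "-", name = "g")
  sets <- build_promoter_sets(genes, tibble::tibble(chrom = "c1", pos = 260),
                              genome)
  expect_equal(unique(strsplit(sets$boundary$seq, "")[[1]]), "T")
})

test_that("enrichment_test detects planted motifs and reports direction", {
  pwm <- test_pwm(width = 8, seed = 85)
  sim <- simulate_promoters(pwm, n_boundary = 60, n_background = 150,
                            plant_rate = 0.8, background_rate = 0.05,
                            seed = 86)
  sc <- dplyr::bind_rows(
    dplyr::mutate(trap_scores(sim$boundary, pwm), set = "boundary"),
    dplyr::mutate(trap_scores(sim$background, pwm), set = "background")
  )
  out <- enrichment_test(sc)
  expect_lt(out$q, 0.01)
  expect_gt(out$delta_median, 0)

  # identical distributions -> p = 1
  same <- tibble::tibble(motif = "m", set = rep(c("boundary", "background"),
                                                each = 4),
                         score = rep(c(1, 2, 3, 4), 2))
  expect_equal(enrichment_test(same)$p, 1, tolerance = 1e-6)
})

test_that("motif presence thresholds follow the built-in table", {
  expect_true(motif_present(-4.9, "Beaf-32"))
  expect_true(motif_present(-5.0, "Beaf-32"))   # equal counts as present
  expect_false(motif_present(-4.5, "CTCF"))
  expect_equal(motif_present(c(-4.6, -4.8), c("ZIPIC", "ZIPIC")),
               c(TRUE, FALSE))
  expect_error(motif_present(0, "nosuch"), "threshold")
  # monotone in score
  s <- seq(-8, 0, by = 0.5)
  pres <- motif_present(s, rep("M1BP", length(s)))
  expect_true(all(diff(pres) >= 0))
})

test_that("boundary classifier separates, ranks features and errors cleanly", {
  set.seed(87)
  n <- 300
  x <- matrix(rnorm(n * 10), n, 10)
  colnames(x) <- paste0("f", 1:10)
  y <- rep(c(TRUE, FALSE), n / 2)
  x[, 3] <- ifelse(y, 2, -2) + rnorm(n, sd = 0.2)
  fit <- boundary_classifier(x, y)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 1)
  imp <- fit$importance
  expect_equal(imp$feature[which.max(imp$importance)], "f3")
  expect_equal(max(imp$importance), 100)
  expect_true(all(imp$importance >= 0 & imp$importance <= 100))
  expect_error(boundary_classifier(x, rep(TRUE, n)), "single class")

  g <- glance(fit)
  expect_equal(g$sensitivity, 1)
  expect_equal(tidy(fit)$feature[1], "f3")
})

test_that("correlated features are pre-filtered before fitting", {
  set.seed(88)
  n <- 200
  base <- rnorm(n)
  x <- cbind(f1 = base, f2 = base + rnorm(n, sd = 0.05),
             f3 = rnorm(n), f4 = rnorm(n))
  y <- base + rnorm(n, sd = 0.5) > 0
  fit <- boundary_classifier(x, y)
  expect_false("f2" %in% fit$features_kept)  # cor(f1, f2) ~ 1
  expect_true(all(c("f1", "f3", "f4") %in% fit$features_kept))
})
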