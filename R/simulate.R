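#' Simulate a genome sequence
#'
#' Uniform random ACGT sequences, one per chromosome. Deterministic under
#' `seed`.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param gc GC content.
#' @param seed Optional RNG seed.
#' @return Named character vector of sequences.
#' @export
simulate_genome <- function(chrom_sizes, gc = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(chrom_sizes, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Simulate a fragment bin table
#'
#' Draws fragment lengths i.i.d. from a fixed-length or geometric model.
#' The geometric model (`1 + Geom(1/mean_length)`) reproduces the ragged
#' fragment sizes of a 4-cutter digestion with the configured mean
#' (default 570 bp, the DpnII fragment mean).
#'
#' @param n_bins Number of fragments.
#' @param mean_length Mean fragment length in bp.
#' @param model `"fixed"` or `"geometric"`.
#' @param chrom Chromosome name.
#' @param seed Optional RNG seed.
#' @return A bin table tibble.
#' @export
simulate_bins <- function(n_bins, mean_length = 570,
                          model = c("geometric", "fixed"),
                          chrom = "chrS", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model)
  lens <- switch(model,
    fixed = rep(as.integer(mean_length), n_bins),
    geometric = 1L + stats::rgeom(n_bins, prob = 1 / mean_length)
  )
  ends <- cumsum(as.numeric(lens))
  tibble(chrom = chrom, start = c(0, head(ends, -1)), end = ends,
         bin_id = seq_len(n_bins))
}

#' Simulate a contact matrix with planted TADs
#'
#' Expected counts follow a power-law distance decay with a within-domain
#' enrichment: `mu_ij = depth * (|i-j|+1)^(-alpha) * (1 + gamma *
#' same_tad(i,j))`; observed counts are Poisson around `mu`, symmetric.
#' Planted boundaries sit on bin borders (the first bin of each new
#' domain), evenly spaced with a uniform jitter, and are kept clear of the
#' chromosome ends by `edge_margin` bp so every analysis scale fits.
#'
#' @param bins A single-chromosome bin table.
#' @param n_tads Number of planted domains; `gamma = 0` gives a
#'   structure-free matrix regardless.
#' @param alpha Distance-decay exponent (> 0).
#' @param gamma Within-TAD enrichment (>= 0).
#' @param depth Expected background count at distance 0 scale (the
#'   distance-1 background mean is `depth / 2^alpha`).
#' @param edge_margin Boundary-free margin at each chromosome end, bp.
#' @param jitter Jitter of boundary placement as a fraction of the mean
#'   domain width.
#' @param bias_sd Log-normal standard deviation of per-fragment visibility
#'   (unequal restriction-site cutting efficiency); 0 disables.
#' @param dropout Fraction of fragments that are essentially never cut
#'   (visibility multiplied by `dropout_factor`); these form the low mode
#'   of the bimodal coverage distribution that the masking threshold
#'   separates.
#' @param dropout_factor Visibility multiplier of dropout fragments.
#' @param dispersion Negative-binomial size parameter; `NULL` (default)
#'   draws Poisson counts, a finite value adds overdispersion
#'   (variance = mu + mu^2 / dispersion).
#' @param boundary_clear Dropout-free zone around each planted boundary,
#'   in bp. Boundary elements are accessible, well-digested sites (in
#'   flies they are mostly active promoters), whereas uncut fragments sit
#'   in repetitive or heterochromatic regions, so the two do not
#'   co-locate.
#' @param seed Optional RNG seed.
#' @return List: `matrix` (a `contact_matrix`), `boundaries` (tibble
#'   `bin_id`, `chrom`, `pos`), `tad_of` (per-bin domain id),
#'   `visibility` (the true per-bin bias) and `dropout_bins`.
#' @export
simulate_matrix <- function(bins, n_tads = 20, alpha = 1, gamma = 5,
                            depth = 100, edge_margin = 45000, jitter = 0.2,
                            bias_sd = 0.2, dropout = 0.05,
                            dropout_factor = 0.02, dispersion = NULL,
                            boundary_clear = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(alpha > 0, gamma >= 0, length(unique(bins$chrom)) == 1L)
  n <- nrow(bins)
  chrom_end <- max(bins$end)
  interior <- which(bins$start >= edge_margin &
                      bins$start <= chrom_end - edge_margin)
  if (length(interior) < n_tads) stop("too few interior bins for n_tads")
  b_bins <- integer(0)
  if (n_tads > 1L) {
    anchor <- seq(min(interior), max(interior), length.out = n_tads + 1L)
    anchor <- anchor[-c(1, n_tads + 1L)]
    spacing <- diff(range(interior)) / n_tads
    jit <- runif(n_tads - 1L, -jitter * spacing, jitter * spacing)
    b_bins <- sort(unique(pmin(max(interior),
                               pmax(min(interior), round(anchor + jit)))))
  }
  tad_of <- findInterval(seq_len(n), b_bins) + 1L
  idx <- seq_len(n)
  dist1 <- abs(outer(idx, idx, "-")) + 1
  same <- outer(tad_of, tad_of, "==")
  vis <- exp(rnorm(n, 0, bias_sd))
  b_pos <- bins$start[b_bins]
  near_boundary <- vapply(seq_len(n), function(i) {
    length(b_pos) > 0 &&
      min(abs(c(bins$start[i], bins$end[i]) - rep(b_pos, each = 2))) <
        boundary_clear
  }, logical(1))
  drop_pool <- which(!near_boundary)
  drop_bins <- sort(drop_pool[sample.int(length(drop_pool),
                                         min(length(drop_pool),
                                             round(dropout * n)))])
  vis[drop_bins] <- vis[drop_bins] * dropout_factor
  mu <- depth * dist1^(-alpha) * (1 + gamma * same) * outer(vis, vis)
  counts <- matrix(0, n, n)
  up <- upper.tri(mu, diag = TRUE)
  counts[up] <- if (is.null(dispersion)) {
    rpois(sum(up), mu[up])
  } else {
    stats::rnbinom(sum(up), size = dispersion, mu = mu[up])
  }
  counts <- counts + t(counts)
  diag(counts) <- diag(counts) / 2
  list(
    matrix = contact_matrix(bins, counts),
    boundaries = tibble(bin_id = b_bins, chrom = bins$chrom[b_bins],
                        pos = bins$start[b_bins]),
    tad_of = tad_of,
    visibility = vis,
    dropout_bins = drop_bins
  )
}

#' Simulate read pairs with planted filter artifacts
#'
#' Emits clean pairs plus configurable numbers of each filter-violating
#' class (low mapping quality, intra-chromosomal mates closer than 800 bp,
#' exact duplicates, dangling ends, mates farther than 1500 bp from a
#' restriction site), with a `truth` column naming the planted class so
#' filter bookkeeping can be checked exactly. Clean mates sit near
#' fragment borders on distinct fragments at least `min_separation` bp
#' apart; the far-from-site class needs at least one fragment longer than
#' about twice `max_site_distance`.
#'
#' @param bins A single-chromosome bin table.
#' @param n_clean,n_low_mapq,n_close,n_duplicate,n_dangling,n_far Counts
#'   per class.
#' @param min_separation,max_site_distance The filter parameters the
#'   artifacts are planted against.
#' @param seed Optional RNG seed.
#' @return A pairs tibble with an extra `truth` column, in shuffled order.
#' @export
simulate_pairs <- function(bins, n_clean = 100, n_low_mapq = 0, n_close = 0,
                           n_duplicate = 0, n_dangling = 0, n_far = 0,
                           min_separation = 800, max_site_distance = 1500,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(unique(bins$chrom)) == 1L)
  chrom <- bins$chrom[1]
  n_anchor <- n_clean + n_low_mapq + n_close + n_dangling + n_far
  # anchor fragments sampled without replacement -> mate-1 coordinates
  # unique; an anchor needs a later fragment starting >= min_separation
  # + offsets away so the clean mate-2 target always exists
  usable <- which(bins$start + 100 + min_separation + 100 <=
                    bins$start[nrow(bins)])
  if (length(usable) < n_anchor) stop("too few fragments for requested pairs")
  anchors <- sample(usable, n_anchor)

  long <- which(bins$end - bins$start > 2 * max_site_distance + 200)
  mk_pair <- function(f1, truth, k) {
    pos1 <- bins$start[f1] +
      sample(0:min(99, bins$end[f1] - bins$start[f1] - 1), 1)
    if (truth == "too_close") {
      pos2 <- pos1 + sample(seq_len(min_separation - 1L), 1)
    } else if (truth == "far_from_site") {
      if (!length(long)) {
        stop("no fragment long enough to plant a far-from-site mate; ",
             "use a bin table with fragments > ",
             2 * max_site_distance + 200, " bp")
      }
      f2 <- long[sample.int(length(long), 1)]
      # unique offset per pair keeps planted far pairs from duplicating
      pos2 <- bins$start[f2] + max_site_distance + 1 + (k %% 90)
    } else {
      target <- pos1 + min_separation + 100
      f2 <- which(bins$start >= target)[1]
      if (is.na(f2)) f2 <- nrow(bins)
      pos2 <- bins$start[f2] +
        sample(0:min(99, bins$end[f2] - bins$start[f2] - 1), 1)
    }
    tibble(
      chrom1 = chrom, pos1 = pos1, strand1 = "+",
      mapq1 = if (truth == "low_mapq") 5 else 60,
      chrom2 = chrom, pos2 = pos2, strand2 = "-", mapq2 = 60,
      dangling = truth == "dangling_end",
      truth = truth
    )
  }

  classes <- rep(c("clean", "low_mapq", "too_close", "dangling_end",
                   "far_from_site"),
                 c(n_clean, n_low_mapq, n_close, n_dangling, n_far))
  rows <- purrr::pmap(list(anchors, classes, seq_along(classes)), mk_pair)
  out <- bind_rows(rows)
  if (n_duplicate > 0L) {
    cleans <- which(out$truth == "clean")
    if (length(cleans) < 1L) stop("duplicates require at least one clean pair")
    src <- out[cleans[sample.int(length(cleans), n_duplicate, replace = TRUE)], ]
    src$truth <- "duplicate"
    out <- bind_rows(out, src)
  }
  out[sample(nrow(out)), ]
}

.archetypes <- local({
  a <- rbind(
    active36 = c(1, 0, 0, 0),
    active4  = c(0, 1, 0, 0),
    HP1      = c(0, 0, 1, 0),
    PcG      = c(0, 0, 0, 1),
    inactive = c(0, 0, 0, 0)
  )
  colnames(a) <- c("H3K36me3", "H3K4me3", "H3K9me3", "H3K27me3")
  a
})

#' Simulate TAD-by-mark signal with planted chromatin classes
#'
#' Each TAD is assigned one of five archetypes (H3K36me3-only,
#' H3K4me3-only, H3K9me3-only, H3K27me3-only, or no mark) and its mark
#' signal is the one-hot archetype profile plus Gaussian noise.
#'
#' @param n_tads Number of TADs.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Optional RNG seed.
#' @return List: `marks` (tibble, TADs x 4 marks), `archetype` (character
#'   per TAD) and `label` (the chromatin class each archetype maps to).
#' @export
simulate_tad_marks <- function(n_tads, noise_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- sample(rep(rownames(.archetypes), length.out = n_tads))
  x <- .archetypes[arch, , drop = FALSE] +
    matrix(rnorm(n_tads * 4, sd = noise_sd), n_tads, 4)
  colnames(x) <- colnames(.archetypes)
  label <- c(active36 = "active", active4 = "active", HP1 = "HP1",
             PcG = "PcG", inactive = "inactive")[arch]
  list(marks = as_tibble(x), archetype = arch, label = unname(label))
}

#' Simulate per-mark signal tracks over TADs
#'
#' Converts a TAD-by-mark matrix into piecewise-constant bedGraph-style
#' tracks, one per mark (each TAD is one constant segment).
#'
#' @param tads Tibble of TAD intervals (`chrom`, `start`, `end`).
#' @param marks Tibble/matrix of per-TAD mark values (see
#'   [simulate_tad_marks()]).
#' @return Named list of signal-track tibbles.
#' @export
simulate_tracks <- function(tads, marks) {
  marks <- as.data.frame(marks)
  stopifnot(nrow(marks) == nrow(tads))
  lapply(setNames(names(marks), names(marks)), function(mk) {
    tibble(chrom = tads$chrom, start = tads$start, end = tads$end,
           value = marks[[mk]])
  })
}

#' Simulate promoter sequences with planted motif instances
#'
#' Generates random promoter-length sequences for a "boundary" and a
#' "background" set and plants the motif consensus at a random position
#' in a configurable fraction of each set.
#'
#' @param pwm A `pwm` object whose consensus is planted.
#' @param n_boundary,n_background Set sizes.
#' @param plant_rate Planting rate in the boundary set.
#' @param background_rate Planting rate in the background set.
#' @param seq_len Sequence length (bp).
#' @param seed Optional RNG seed.
#' @return List: `boundary`, `background` (named character vectors) and
#'   `truth` (tibble `seq_id`, `set`, `planted`).
#' @export
simulate_promoters <- function(pwm, n_boundary = 60, n_background = 150,
                               plant_rate = 0.8, background_rate = 0.05,
                               seq_len = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cons <- paste(.base_order[apply(unclass(pwm), 2, which.max)], collapse = "")
  m <- nchar(cons)
  gen_set <- function(nm, n, rate) {
    planted <- runif(n) < rate
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(.base_order, seq_len, replace = TRUE)
      if (planted[i]) {
        at <- sample(seq_len - m + 1L, 1)
        s[at:(at + m - 1L)] <- strsplit(cons, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0(nm, "_", seq_len(n))
    list(seqs = seqs, planted = planted)
  }
  b <- gen_set("boundary", n_boundary, plant_rate)
  g <- gen_set("background", n_background, background_rate)
  list(
    boundary = b$seqs, background = g$seqs,
    truth = tibble(
      seq_id = c(names(b$seqs), names(g$seqs)),
      set = rep(c("boundary", "background"), c(n_boundary, n_background)),
      planted = c(b$planted, g$planted)
    )
  )
}
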