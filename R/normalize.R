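#' Low-count threshold from the bimodal coverage distribution
#'
#' Restriction sites are cut with unequal efficiency, so per-bin total
#' counts are a mixture of a low mode (uncut / repetitive bins) and the
#' main coverage mode. The threshold is the total-count value at the
#' deepest local minimum of a smoothed histogram of `log1p(bin totals)`
#' between the two modes, identified as the pair of histogram peaks with
#' the most prominent valley between them. When no prominently separated
#' mode pair exists (a unimodal distribution) the 5th percentile of the
#' nonzero totals is returned instead.
#'
#' @param m A `contact_matrix` with at least two bins of nonzero total.
#' @param n_breaks Number of histogram bins in log1p space.
#' @param smooth Width (bins) of the moving-average smoother.
#' @return The threshold on the per-bin total-count scale.
#' @export
count_threshold <- function(m, n_breaks = 100L, smooth = 3L) {
  totals <- bin_totals(m)
  if (sum(totals > 0) < 2L) stop("matrix has fewer than two nonzero bins")
  lt <- log1p(totals)
  breaks <- seq(0, max(lt) * (1 + 1e-9), length.out = n_breaks + 1L)
  h <- tabulate(findInterval(lt, breaks, rightmost.closed = TRUE),
                nbins = n_breaks)
  sm <- stats::filter(h, rep(1 / smooth, smooth), sides = 2)
  sm[is.na(sm)] <- h[is.na(sm)]
  sm <- as.numeric(sm)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2

  k <- length(sm)
  is_max <- sm > c(-Inf, sm[-k]) & sm >= c(sm[-1], -Inf)
  peaks <- which(is_max & sm > 0)
  # the two modes are the peak pair with the most prominent valley between
  # them (valley at most half the smaller peak); bumps inside one cluster
  # never qualify, so a unimodal histogram falls through to the percentile
  best <- NULL; best_score <- 0
  if (length(peaks) >= 2L) {
    for (a in seq_len(length(peaks) - 1L)) {
      for (b in (a + 1L):length(peaks)) {
        lo <- peaks[a]; hi <- peaks[b]
        if (hi - lo < 2L) next
        valley <- min(sm[(lo + 1L):(hi - 1L)])
        small <- min(sm[lo], sm[hi])
        if (valley > small / 2) next
        score <- small - valley
        if (score > best_score) {
          best <- c(lo, hi); best_score <- score
        }
      }
    }
  }
  if (!is.null(best)) {
    between <- (best[1] + 1L):(best[2] - 1L)
    vmin <- min(sm[between])
    cand <- between[sm[between] == vmin]
    pick <- cand[ceiling(length(cand) / 2)]  # centre of the valley floor
    return(expm1(mids[pick]))
  }
  unname(quantile(totals[totals > 0], 0.05))
}

#' Mask bins with low total counts
#'
#' Bins whose total count is strictly below the threshold get `mask =
#' FALSE`; counts are untouched (masking is logical and downstream
#' operations skip masked bins).
#'
#' @param m A `contact_matrix`.
#' @param threshold Total-count cutoff, e.g. from [count_threshold()].
#' @return The matrix with its mask updated.
#' @export
mask_low_bins <- function(m, threshold) {
  m$mask <- bin_totals(m) >= threshold
  m
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Equalizes bin visibility by repeatedly dividing counts by the outer
#' product of per-bin bias estimates until the coefficient of variation of
#' the unmasked row sums falls below `tol`. Corrected counts are rescaled
#' so the matrix total is preserved; the accumulated per-bin biases are
#' stored on the result (NA for masked bins).
#'
#' @param m A `contact_matrix` with low-count bins already masked.
#' @param tol Convergence tolerance on the row-sum coefficient of
#'   variation.
#' @param max_iter Maximum number of iterations.
#' @return The corrected `contact_matrix` with `biases` set.
#' @export
ice_correct <- function(m, tol = 1e-5, max_iter = 500L) {
  keep <- which(m$mask)
  if (length(keep) < 2L) stop("fewer than two unmasked bins; cannot correct")
  x <- as.matrix(m$counts[keep, keep, drop = FALSE])
  if (all(x == 0)) stop("unmasked submatrix is all zero; cannot correct")
  total0 <- (sum(x) + sum(diag(x))) / 2
  bias <- rep(1, length(keep))
  cv <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(x)
    if (any(s == 0)) {
      stop("unmasked bin with zero row sum; mask low-count bins first")
    }
    mu <- mean(s)
    cv <- sd(s) / mu
    if (cv < tol) break
    db <- s / mu
    bias <- bias * db
    x <- x / outer(db, db)
  }
  if (cv >= tol) {
    stop(sprintf(
      "ICE did not converge in %d iterations (row-sum CV = %.3g)",
      max_iter, cv))
  }
  # preserve the original total count
  total1 <- (sum(x) + sum(diag(x))) / 2
  x <- x * (total0 / total1)
  bias <- bias * sqrt(total1 / total0)

  counts <- m$counts
  counts[keep, keep] <- x
  biases <- rep(NA_real_, nrow(m$bins))
  biases[keep] <- bias
  contact_matrix(m$bins, counts, mask = m$mask, biases = biases)
}

#' Per-distance z-score transform
#'
#' Standardizes every contact against the distribution of all contacts at
#' the same genomic distance. Distance is stratified by bin-index offset
#' (matrix diagonal), the natural unit for a fragment-resolution matrix;
#' statistics use the population standard deviation over unmasked entries
#' of each diagonal. Constant diagonals (sd = 0) map to z = 0; entries
#' touching a masked bin are NA. Inter-chromosomal entries are not
#' standardized (NA): the score is a within-chromosome quantity.
#'
#' @param m A corrected `contact_matrix` (a raw matrix is accepted; using
#'   corrected counts is the default analysis route).
#' @param mode Distance stratification: `"diagonal"` (bin-index offset,
#'   the natural unit for fragment-resolution matrices) or `"genomic"`
#'   (bands of genomic distance between bin starts, for strongly
#'   heterogeneous fragment sizes).
#' @param band_width Band width in bp for `mode = "genomic"`; defaults to
#'   the mean bin width.
#' @return A `zscore_matrix` object: list with `bins`, dense matrix `z`,
#'   and the inherited `mask`.
#' @export
zscore_transform <- function(m, mode = c("diagonal", "genomic"),
                             band_width = NULL) {
  mode <- match.arg(mode)
  n <- nrow(m$bins)
  x <- as.matrix(m$counts)
  chrom_of <- m$bins$chrom
  if (is.null(band_width)) band_width <- mean(m$bins$end - m$bins$start)
  z <- matrix(NA_real_, n, n)
  few <- 0L
  for (cn in unique(chrom_of)) {
    sel <- which(chrom_of == cn)
    nz <- length(sel)
    xs <- x[sel, sel, drop = FALSE]
    msk <- m$mask[sel]
    ok <- outer(msk, msk, "&")
    zs <- matrix(NA_real_, nz, nz)
    idx <- seq_len(nz)
    starts <- m$bins$start[sel]
    strata <- if (mode == "diagonal") {
      lapply(0:(nz - 1L), function(d) {
        i <- idx[seq_len(nz - d)]
        (i + d - 1L) * nz + i
      })
    } else {
      dist_band <- floor(abs(outer(starts, starts, "-")) / band_width)
      ut <- which(upper.tri(dist_band, diag = TRUE))
      split(ut, dist_band[ut])
    }
    for (lin in strata) {
      use <- ok[lin]
      if (!any(use)) next
      v <- xs[lin][use]
      if (length(v) < 2L) {
        few <- few + 1L
        zv <- rep(0, length(v))
      } else {
        mu <- mean(v)
        sdv <- sqrt(mean((v - mu)^2))
        zv <- if (sdv == 0) rep(0, length(v)) else (v - mu) / sdv
      }
      zvals <- rep(NA_real_, length(lin))
      zvals[use] <- zv
      zs[lin] <- zvals
      # mirror to the lower triangle
      i <- ((lin - 1L) %% nz) + 1L
      j <- ((lin - 1L) %/% nz) + 1L
      zs[(i - 1L) * nz + j] <- zvals
    }
    z[sel, sel] <- zs
  }
  if (few > 0L) {
    warning(few, " diagonal(s) had fewer than 2 unmasked entries; set to 0")
  }
  structure(list(bins = m$bins, z = z, mask = m$mask),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("<zscore_matrix> ", nrow(x$bins), " bins; ",
      sum(!x$mask), " masked bin(s)\n", sep = "")
  invisible(x)
}
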