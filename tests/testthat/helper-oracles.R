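# matrix whose per-bin totals equal `totals` (counts on the diagonal only)
matrix_with_totals <- function(totals) {
  n <- length(totals)
  bins <- tile_bins(c(c1 = n * 100), 100)
  contact_matrix(bins, Matrix::Diagonal(n, x = totals))
}

# independent naive diamond extraction: loop over all bin pairs and keep
# entries whose bins intersect the two half-open windows around pos(l)
naive_diamond <- function(zm, l, w) {
  bins <- zm$bins
  pos <- bins$start[l]
  cb <- bins[bins$chrom == bins$chrom[l], ]
  if (pos - w < min(cb$start) || pos + w > max(cb$end)) return(NULL)
  vals <- c()
  for (i in cb$bin_id) {
    for (j in cb$bin_id) {
      in_up <- bins$start[i] < pos && bins$end[i] > pos - w
      in_down <- bins$start[j] < pos + w && bins$end[j] > pos
      if (in_up && in_down && !is.na(zm$z[i, j])) {
        vals <- c(vals, zm$z[i, j])
      }
    }
  }
  vals
}

rand_zmatrix <- function(n, seed, width = 100, masked = integer()) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n); z <- (z + t(z)) / 2
  mask <- rep(TRUE, n); mask[masked] <- FALSE
  z[!mask, ] <- NA; z[, !mask] <- NA
  structure(list(bins = tile_bins(c(c1 = n * width), width), z = z,
                 mask = mask),
            class = "zscore_matrix")
}

# exhaustive-enumeration oracle for the two-sided rank-sum p-value
exact_ranksum_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  all_u <- apply(utils::combn(m + n, m), 2, function(idx) {
    sum(seq_len(m + n)[idx]) - m * (m + 1) / 2
  })
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

test_pwm <- function(width = 6, seed = 81, sharp = 100) {
  set.seed(seed)
  counts <- matrix(rexp(4 * width), 4, width)
  counts[cbind(sample(4, width, replace = TRUE), seq_len(width))] <- sharp
  pwm_from_counts(counts, id = "test")
}

# literal per-window double-strand TRAP sum, scalar loops throughout
naive_trap <- function(seq, pwm, lambda = 0.7, ln_R0 = NULL) {
  p <- unclass(pwm)
  m <- ncol(p)
  if (is.null(ln_R0)) ln_R0 <- 0.584 * m - 5.66
  score_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    total <- 0
    for (start in seq_len(length(chars) - m + 1)) {
      E <- 0
      ok <- TRUE
      for (j in seq_len(m)) {
        b <- chars[start + j - 1]
        if (!b %in% rownames(p)) { ok <- FALSE; break }
        E <- E + log(max(p[, j]) / p[b, j])
      }
      if (ok) {
        E <- E / lambda
        r <- exp(ln_R0 - E)
        total <- total + r / (1 + r)
      }
    }
    total
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                     collapse = ""))
  unname(log(score_strand(seq) + score_strand(rc)))
}
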