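#' Diamond submatrix values at a bin
#'
#' The "diamond" at bin `l` collects the z-scores of all contacts between
#' the region `w` bp upstream of the bin's start position and the region
#' `w` bp downstream of it. With variable-width fragment bins, a bin
#' belongs to the upstream set when its interval intersects the half-open
#' window `[pos(l) - w, pos(l))` and to the downstream set when it
#' intersects `[pos(l), pos(l) + w)`; the two sets partition the bins
#' around the prospective boundary point, so bin `l` belongs to the
#' downstream set only and the diamond at a domain junction contains
#' cross-domain contacts exclusively. Entries involving a masked bin are
#' excluded.
#'
#' @param zm A `zscore_matrix`.
#' @param l Bin id.
#' @param w Window length in bp.
#' @return Numeric vector of the defined diamond entries, or `NULL` when
#'   the window does not fit inside the chromosome (bin too close to an
#'   end).
#' @export
diamond_scores <- function(zm, l, w) {
  rng <- .diamond_range(zm$bins, l, w)
  if (is.null(rng)) return(NULL)
  v <- zm$z[rng$up, rng$down, drop = FALSE]
  v <- v[!is.na(v)]
  as.numeric(v)
}

# bin-id ranges of the upstream/downstream diamond sets, or NULL at edges
.diamond_range <- function(bins, l, w) {
  chrom <- bins$chrom[l]
  pos <- bins$start[l]
  cb <- bins[bins$chrom == chrom, ]
  chrom_start <- min(cb$start); chrom_end <- max(cb$end)
  if (pos - w < chrom_start || pos + w > chrom_end) return(NULL)
  # bins [s,e) intersecting the half-open window [a,b): s < b & e > a
  up <- cb$bin_id[cb$start < pos & cb$end > pos - w]
  down <- cb$bin_id[cb$start < pos + w & cb$end > pos]
  if (!length(up) || !length(down)) return(NULL)
  list(up = up, down = down)
}

#' Multi-scale TAD-separation score
#'
#' For every bin and every window length `w` the score(w) is the mean of
#' the diamond z-scores at that bin; the multi-scale score is the
#' arithmetic mean of the per-scale scores. A low score means the regions
#' flanking the bin make few contacts across it -- the signature of a TAD
#' boundary. Bins where any scale's window falls off the chromosome (or
#' has no defined diamond entry) are flagged invalid.
#'
#' @param zm A `zscore_matrix`.
#' @param w_list Window lengths in bp.
#' @return A tibble with one row per bin: `chrom`, `start`, `end`,
#'   `bin_id`, one `score_w<w>` column per scale, `score` (multi-scale
#'   mean) and `valid`.
#' @export
separation_track <- function(zm,
                             w_list = c(10000, 12000, 18000, 25000, 40000)) {
  bins <- zm$bins
  n <- nrow(bins)
  w_list <- sort(unique(w_list))
  # prefix sums over NA-zeroed z and its defined-entry indicator give each
  # diamond mean in O(1); diamonds are contiguous rectangles in bin index
  zz <- zm$z
  def <- !is.na(zz)
  zz[!def] <- 0
  prefix <- function(x) {
    p <- matrix(0, n + 1L, n + 1L)
    p[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
    p
  }
  cs <- prefix(zz)        # cs[i+1, j+1] = sum z[1..i, 1..j]
  cm <- prefix(def + 0)
  rect_sum <- function(P, r1, r2, c1, c2) {
    P[cbind(r2 + 1L, c2 + 1L)] - P[cbind(r1, c2 + 1L)] -
      P[cbind(r2 + 1L, c1)] + P[cbind(r1, c1)]
  }

  per_scale <- matrix(NA_real_, n, length(w_list))
  colnames(per_scale) <- paste0("score_w", w_list)
  for (k in seq_along(w_list)) {
    w <- w_list[k]
    for (cn_name in unique(bins$chrom)) {
      cb <- bins[bins$chrom == cn_name, ]
      chrom_start <- min(cb$start); chrom_end <- max(cb$end)
      fit <- cb$start - w >= chrom_start & cb$start + w <= chrom_end
      ids <- cb$bin_id[fit]
      if (!length(ids)) next
      pos <- cb$start[fit]
      # first/last bin ids of the up/down sets (contiguous within chrom);
      # a bin [s,e) intersects the half-open window [a,b) iff s < b, e > a
      up1 <- cb$bin_id[findInterval(pos - w, cb$end) + 1L]
      up2 <- ids - 1L
      dn1 <- ids
      dn2 <- cb$bin_id[findInterval(pos + w, cb$start, left.open = TRUE)]
      s <- rect_sum(cs, up1, up2, dn1, dn2)
      m <- rect_sum(cm, up1, up2, dn1, dn2)
      per_scale[ids, k] <- ifelse(m > 0, s / m, NA_real_)
    }
  }
  score <- rowMeans(per_scale)
  out <- bins
  out <- dplyr::bind_cols(out, as_tibble(per_scale))
  mutate(out, score = score, valid = !is.na(score))
}

#' Candidate boundaries: qualified local minima of the separation track
#'
#' Finds strict local minima of the multi-scale score whose depth --
#' the mean of the two flanking local maxima minus the minimum value --
#' is at least `delta_min`. Plateau minima resolve to the central bin
#' (left of centre on even plateaus). Flanking maxima are searched within
#' `max_search` bp on each side; if no interior local maximum exists
#' there, the largest score in the window is used.
#'
#' @param track A separation track tibble (see [separation_track()]).
#' @param delta_min Minimum local-minimum depth.
#' @param max_search Search range (bp) for the flanking maxima.
#' @return Tibble of candidates: `bin_id`, `chrom`, `pos` (bin start),
#'   `score`, `delta`.
#' @export
find_minima <- function(track, delta_min = 0.01, max_search = 200000) {
  out <- list()
  for (cn in unique(track$chrom)) {
    tb <- track[track$chrom == cn & track$valid, , drop = FALSE]
    s <- tb$score
    k <- length(s)
    if (k < 3L) next
    mins <- .plateau_extrema(s, minima = TRUE)
    maxs_idx <- .plateau_extrema(s, minima = FALSE)
    for (i in mins) {
      win_lo <- tb$start[i] - max_search
      win_hi <- tb$start[i] + max_search
      left_in <- which(tb$start >= win_lo & seq_len(k) < i)
      right_in <- which(tb$start <= win_hi & seq_len(k) > i)
      if (!length(left_in) || !length(right_in)) next
      lm <- maxs_idx[maxs_idx < i & maxs_idx %in% left_in]
      rm_ <- maxs_idx[maxs_idx > i & maxs_idx %in% right_in]
      left_max <- if (length(lm)) s[max(lm)] else max(s[left_in])
      right_max <- if (length(rm_)) s[min(rm_)] else max(s[right_in])
      delta <- (left_max + right_max) / 2 - s[i]
      if (delta >= delta_min) {
        out[[length(out) + 1L]] <- tibble(
          bin_id = tb$bin_id[i], chrom = cn, pos = tb$start[i],
          score = s[i], delta = delta
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(bin_id = integer(), chrom = character(), pos = numeric(),
                  score = numeric(), delta = numeric()))
  }
  arrange(bind_rows(out), .data$bin_id)
}

# indices of strict local minima/maxima with plateaus resolved to the
# central position (left of centre on ties); sequence ends never qualify
.plateau_extrema <- function(s, minima = TRUE) {
  if (minima) s <- -s
  k <- length(s)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- integer()
  for (g in seq_along(r$values)) {
    if (starts[g] == 1L || ends[g] == k) next
    if (s[starts[g] - 1L] < r$values[g] && s[ends[g] + 1L] < r$values[g]) {
      res <- c(res, starts[g] + floor((r$lengths[g] - 1L) / 2))
    }
  }
  res
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the smaller sample has at most `exact_max`
#' values and there are no ties; normal approximation with tie and
#' continuity correction otherwise. Degenerate input where every value in
#' both samples is identical returns p = 1.
#'
#' @param a,b Numeric value sets.
#' @param exact_max Largest min-sample size for the exact test.
#' @return The two-sided p-value.
#' @export
rank_sum_p <- function(a, b, exact_max = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  comb <- c(a, b)
  if (all(comb == comb[1])) return(1)
  has_ties <- anyDuplicated(comb) > 0L
  exact <- !has_ties && min(length(a), length(b)) <= exact_max
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Statistical significance of candidate boundaries
#'
#' Each candidate minimum at bin `i` is tested by comparing its diamond
#' z-scores with the diamonds at the bins containing `pos(i) - v` and
#' `pos(i) + v`; the larger of the two rank-sum p-values is the raw
#' p-value, Bonferroni-corrected by the number of candidates tested.
#' Diamond values are pooled over all scales in `w_list` (set
#' `pool_scales = FALSE` to use only the largest scale). Candidates whose
#' shifted neighbours fall off the chromosome, or whose diamonds have
#' fewer than `min_diamond_values` defined entries, are dropped with a
#' warning.
#'
#' @param zm A `zscore_matrix`.
#' @param candidates Tibble from [find_minima()].
#' @param v Shift in bp for the flanking comparison diamonds.
#' @param alpha Family-wise significance level on the corrected p-value.
#' @param w_list Scales whose diamonds are pooled.
#' @param pool_scales Pool all scales (default) or use `max(w_list)` only.
#' @param min_diamond_values Minimum defined diamond entries per tested
#'   diamond.
#' @return A boundary tibble: candidate columns plus `p_raw`, `p_adj`,
#'   `significant`.
#' @export
boundary_significance <- function(zm, candidates, v = 1000, alpha = 0.001,
                                  w_list = c(10000, 12000, 18000, 25000,
                                             40000),
                                  pool_scales = TRUE,
                                  min_diamond_values = 10L) {
  if (!pool_scales) w_list <- max(w_list)
  empty <- mutate(candidates[0, ], p_raw = numeric(), p_adj = numeric(),
                  significant = logical())
  if (nrow(candidates) == 0L) return(empty)
  bins <- zm$bins
  pooled <- function(l) {
    unlist(lapply(w_list, function(w) diamond_scores(zm, l, w)),
           use.names = FALSE)
  }
  bin_at <- function(chrom, pos) {
    cb <- bins[bins$chrom == chrom, ]
    hit <- cb$bin_id[cb$start <= pos & cb$end > pos]
    if (length(hit) == 1L) hit else NA_integer_
  }
  rows <- vector("list", nrow(candidates))
  n_dropped <- 0L
  for (r in seq_len(nrow(candidates))) {
    l <- candidates$bin_id[r]
    pos <- bins$start[l]
    lft <- bin_at(candidates$chrom[r], pos - v)
    rgt <- bin_at(candidates$chrom[r], pos + v)
    if (is.na(lft) || is.na(rgt)) { n_dropped <- n_dropped + 1L; next }
    d0 <- pooled(l); dl <- pooled(lft); dr <- pooled(rgt)
    if (is.null(d0) || is.null(dl) || is.null(dr) ||
        min(length(d0), length(dl), length(dr)) < min_diamond_values) {
      n_dropped <- n_dropped + 1L
      next
    }
    p_raw <- max(rank_sum_p(d0, dl), rank_sum_p(d0, dr))
    rows[[r]] <- mutate(candidates[r, ], p_raw = p_raw)
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " candidate(s) dropped: window off chromosome or ",
            "diamond too sparse")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- bind_rows(rows)
  n_tests <- nrow(out)
  mutate(out,
         p_adj = pmin(1, .data$p_raw * n_tests),
         significant = .data$p_adj < alpha)
}

#' Call TADs between consecutive significant boundaries
#'
#' Within each chromosome, consecutive significant boundaries delimit one
#' domain each; the regions before the first and after the last boundary
#' are not called.
#'
#' @param boundaries Boundary tibble from [boundary_significance()].
#' @return A tibble of domains: `chrom`, `start`, `end`.
#' @export
call_domains <- function(boundaries) {
  sig <- arrange(filter(boundaries, .data$significant),
                 .data$chrom, .data$pos)
  out <- sig |>
    group_by(.data$chrom) |>
    dplyr::reframe(start = head(.data$pos, -1), end = tail(.data$pos, -1))
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  select(out, "chrom", "start", "end")
}

#' Full boundary-calling pipeline on a contact matrix
#'
#' Convenience wrapper chaining the default analysis route: low-count
#' masking at the bimodal threshold, iterative correction, per-distance
#' z-scores, the multi-scale separation track, qualified local minima and
#' their significance.
#'
#' @param m A raw `contact_matrix`.
#' @param w_list,delta_min,v,alpha Passed to the respective steps.
#' @param threshold Low-count mask threshold; `NULL` = [count_threshold()].
#' @param correct Apply iterative correction before z-scoring (the default
#'   route); `FALSE` standardizes the raw masked counts instead.
#' @return A list of class `tad_calls`: `matrix` (corrected), `zscore`,
#'   `track`, `boundaries` (tibble), `domains` (tibble).
#' @export
call_tads <- function(m, w_list = c(10000, 12000, 18000, 25000, 40000),
                      delta_min = 0.01, v = 1000, alpha = 0.001,
                      threshold = NULL, correct = TRUE) {
  if (is.null(threshold)) threshold <- count_threshold(m)
  m <- mask_low_bins(m, threshold)
  if (correct) m <- ice_correct(m)
  zm <- zscore_transform(m)
  track <- separation_track(zm, w_list)
  cand <- find_minima(track, delta_min)
  bd <- boundary_significance(zm, cand, v = v, alpha = alpha,
                              w_list = w_list)
  structure(list(matrix = m, zscore = zm, track = track, boundaries = bd,
                 domains = call_domains(bd)),
            class = "tad_calls")
}

#' @export
print.tad_calls <- function(x, ...) {
  cat("<tad_calls> ", nrow(x$boundaries), " tested minima, ",
      sum(x$boundaries$significant), " significant boundaries, ",
      nrow(x$domains), " domains\n", sep = "")
  invisible(x)
}

#' @rdname tidy_tadscout
#' @method tidy tad_calls
#' @export
tidy.tad_calls <- function(x, ...) x$boundaries

#' Tidiers for tadscout result objects
#'
#' `tidy()` returns the per-boundary (or per-feature) table; `glance()`
#' returns a one-row summary.
#'
#' @param x A `tad_calls` or `boundary_model` object.
#' @param ... Unused.
#' @name tidy_tadscout
#' @method glance tad_calls
#' @export
glance.tad_calls <- function(x, ...) {
  tibble(
    n_bins = nrow(x$matrix$bins),
    n_masked = sum(!x$matrix$mask),
    n_candidates = nrow(x$boundaries),
    n_significant = sum(x$boundaries$significant),
    n_domains = nrow(x$domains),
    median_domain_size = median(x$domains$end - x$domains$start)
  )
}
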