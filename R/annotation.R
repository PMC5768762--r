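#' Read BED intervals / bedGraph signal
#'
#' Minimal readers for the plain-text interval formats the annotation
#' functions consume. `read_bed` returns `chrom`, `start`, `end` (plus
#' `name` when a 4th column exists); `read_bedgraph` returns a signal
#' track with a `value` column (piecewise-constant coverage).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_bed <- function(path) {
  out <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  names(out)[1:3] <- c("chrom", "start", "end")
  if (ncol(out) >= 4L) names(out)[4] <- "name"
  as_tibble(out)
}

#' @rdname read_bed
#' @export
read_bedgraph <- function(path) {
  out <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  .validate_track(out)
  out
}

.validate_track <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  for (b in split(track, track$chrom)) {
    if (is.unsorted(b$start) || any(b$start[-1] < b$end[-nrow(b)])) {
      stop("track intervals must be sorted and non-overlapping per chromosome")
    }
  }
  invisible(track)
}

# piecewise segments of a track clipped to [start, end), gaps filled with 0
.interval_segments <- function(tc, start, end) {
  if (end <= start) return(tibble(len = numeric(), value = numeric()))
  keep <- tc$end > start & tc$start < end
  s <- pmax(tc$start[keep], start)
  e <- pmin(tc$end[keep], end)
  v <- tc$value[keep]
  covered <- sum(e - s)
  len <- c(e - s, (end - start) - covered)
  val <- c(v, 0)
  sel <- len > 0
  tibble(len = len[sel], value = val[sel])
}

.weighted_median <- function(value, len) {
  o <- order(value)
  value <- value[o]; len <- len[o]
  cum <- cumsum(len)
  value[which(cum >= sum(len) / 2)[1]]
}

#' Length-weighted mean signal over intervals
#'
#' Averages a piecewise-constant signal track over each query interval;
#' stretches not covered by the track count as signal 0.
#'
#' @param track A signal track tibble (`chrom`, `start`, `end`, `value`).
#' @param intervals Tibble of query intervals (`chrom`, `start`, `end`).
#' @return Numeric vector of means, one per interval row.
#' @export
mean_over_intervals <- function(track, intervals) {
  .validate_track(track)
  by_chrom <- split(track, track$chrom)
  vapply(seq_len(nrow(intervals)), function(r) {
    tc <- by_chrom[[intervals$chrom[r]]]
    width <- intervals$end[r] - intervals$start[r]
    if (is.null(tc) || width <= 0) return(0)
    seg <- .interval_segments(tc, intervals$start[r], intervals$end[r])
    sum(seg$len * seg$value) / width
  }, numeric(1))
}

.mark_order <- c("H3K36me3", "H3K4me3", "H3K9me3", "H3K27me3")
.mark_label <- c(H3K36me3 = "active", H3K4me3 = "active",
                 H3K9me3 = "HP1", H3K27me3 = "PcG")

#' Classify TADs by chromatin-mark signal
#'
#' Column-standardizes the TAD-by-mark signal matrix, clusters TADs by
#' Euclidean distance with complete-linkage hierarchical clustering into
#' `k` clusters, and labels each cluster by its dominant mark (largest
#' mean standardized signal): H3K36me3 or H3K4me3 dominant = "active",
#' H3K9me3 = "HP1", H3K27me3 = "PcG"; a cluster with no mark above the
#' column average (max mean standardized signal <= 0) is "inactive".
#'
#' @param tad_by_mark Data frame / matrix with one row per TAD and the
#'   columns `H3K36me3`, `H3K4me3`, `H3K9me3`, `H3K27me3`.
#' @param k Number of clusters.
#' @return A tibble with `cluster` and `label` per TAD (row order kept).
#' @export
classify_tads <- function(tad_by_mark, k = 5L) {
  x <- as.matrix(as.data.frame(tad_by_mark)[, .mark_order])
  if (nrow(x) < k) stop("fewer TADs (", nrow(x), ") than clusters (", k, ")")
  sds <- apply(x, 2, sd)
  xs <- scale(x)
  xs[, sds == 0] <- 0
  cl <- cutree(hclust(dist(xs), method = "complete"), k = k)
  labels <- vapply(seq_len(k), function(g) {
    mu <- colMeans(xs[cl == g, , drop = FALSE])
    if (max(mu) <= 0) "inactive" else unname(.mark_label[names(which.max(mu))])
  }, character(1))
  tibble(cluster = cl, label = labels[cl])
}

#' Run lengths of consecutive same-class TADs
#'
#' @param labels Character vector of TAD class labels in genomic order.
#' @return Tibble with `label` and `run_length` per run.
#' @export
tad_runs <- function(labels) {
  r <- rle(as.character(labels))
  tibble(label = r$values, run_length = r$lengths)
}

#' Histone-mark separation profile across scaled TADs
#'
#' Each TAD is scaled to `body_bins` equal body bins and flanked on each
#' side by `flank_bins` fixed-width bins (default 1 kb each); the mean
#' signal per bin gives a TADs x (2*flank_bins + body_bins) matrix whose
#' column-pairwise Pearson correlation is returned. Within-TAD blocks of
#' high correlation separated at the boundary columns indicate that the
#' mark respects TAD limits.
#'
#' @param tads Tibble of TAD intervals (`chrom`, `start`, `end`).
#' @param track A signal track tibble.
#' @param body_bins,flank_bins Bin counts for body and each flank.
#' @param flank_bin_width Width (bp) of each flank bin.
#' @return The correlation matrix (default 45 x 45), with the per-TAD bin
#'   matrix in attribute `profile`.
#' @export
histone_separation <- function(tads, track, body_bins = 15L,
                               flank_bins = 15L, flank_bin_width = 1000) {
  n_cols <- 2L * flank_bins + body_bins
  prof <- matrix(NA_real_, nrow(tads), n_cols)
  for (r in seq_len(nrow(tads))) {
    s <- tads$start[r]; e <- tads$end[r]; chrom <- tads$chrom[r]
    left <- seq(s - flank_bins * flank_bin_width, s, length.out = flank_bins + 1)
    body <- seq(s, e, length.out = body_bins + 1)
    right <- seq(e, e + flank_bins * flank_bin_width, length.out = flank_bins + 1)
    starts <- c(head(left, -1), head(body, -1), head(right, -1))
    ends <- c(left[-1], body[-1], right[-1])
    prof[r, ] <- mean_over_intervals(track,
      tibble(chrom = chrom, start = starts, end = ends))
  }
  cc <- suppressWarnings(cor(prof))
  # constant columns (e.g. identical signal in every TAD) have undefined
  # Pearson r; two constant columns are taken as perfectly correlated,
  # a constant against a varying column as uncorrelated
  const <- apply(prof, 2, sd) == 0
  both_const <- outer(const, const, "&")
  cc[is.na(cc) & both_const] <- 1
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  attr(cc, "profile") <- prof
  cc
}

#' Distance of boundary points to the nearest peak
#'
#' @param points Tibble with `chrom` and `pos` (boundary positions).
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`).
#' @return `points` with a `distance` column (0 when inside a peak, `NA`
#'   when the chromosome has no peak).
#' @export
nearest_distance <- function(points, peaks) {
  by_chrom <- split(peaks, peaks$chrom)
  d <- vapply(seq_len(nrow(points)), function(r) {
    pk <- by_chrom[[points$chrom[r]]]
    if (is.null(pk) || nrow(pk) == 0L) return(NA_real_)
    p <- points$pos[r]
    inside <- any(pk$start <= p & pk$end > p)
    if (inside) return(0)
    min(pmin(abs(p - pk$start), abs(p - pk$end - 0)))
  }, numeric(1))
  mutate(points, distance = d)
}

#' Fisher's exact test of boundary/peak co-occurrence
#'
#' Discretizes the genome into fixed-width bins, cross-tabulates bins by
#' whether they contain a boundary and whether they overlap a peak, and
#' tests the 2x2 table with Fisher's exact test. The odds ratio reported
#' is the sample cross-product ratio (n11*n00)/(n10*n01).
#'
#' @param boundaries Tibble with `chrom`, `pos`.
#' @param peaks Tibble of peak intervals.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param bin_width Discretization bin width in bp.
#' @return One-row tibble: the table cells, `odds_ratio` and `p_value`
#'   (two-sided).
#' @export
overlap_fisher <- function(boundaries, peaks, chrom_sizes, bin_width = 1000) {
  gbins <- tile_bins(chrom_sizes, bin_width)
  has_b <- rep(FALSE, nrow(gbins))
  has_p <- rep(FALSE, nrow(gbins))
  for (cn in names(chrom_sizes)) {
    sel <- which(gbins$chrom == cn)
    b <- boundaries[boundaries$chrom == cn, ]
    if (nrow(b)) {
      idx <- findInterval(b$pos, gbins$start[sel])
      idx <- idx[idx >= 1 & idx <= length(sel)]
      has_b[sel[idx]] <- TRUE
    }
    p <- peaks[peaks$chrom == cn, ]
    for (r in seq_len(nrow(p))) {
      hit <- gbins$start[sel] < p$end[r] & gbins$end[sel] > p$start[r]
      has_p[sel[hit]] <- TRUE
    }
  }
  n11 <- sum(has_b & has_p); n10 <- sum(has_b & !has_p)
  n01 <- sum(!has_b & has_p); n00 <- sum(!has_b & !has_p)
  tab <- matrix(c(n11, n10, n01, n00), 2, 2)
  tibble(
    n_both = n11, n_boundary_only = n10, n_peak_only = n01, n_neither = n00,
    odds_ratio = (n11 * n00) / (n10 * n01),
    p_value = fisher.test(tab)$p.value
  )
}

#' Boundary strength grouped by flanking-TAD chromatin context
#'
#' Keys every interior boundary by the (unordered) pair of class labels of
#' its flanking TADs and compares the TAD-separation score distributions
#' between all context groups with the rank-sum test.
#'
#' @param boundaries Tibble with `chrom`, `pos` and `score`.
#' @param labeled_domains Tibble with `chrom`, `start`, `end`, `label`.
#' @return A list: `groups` (boundaries with a `context` column; only
#'   boundaries flanked by two labeled domains are kept) and
#'   `comparisons` (tibble `context1`, `context2`, `p`).
#' @export
strength_by_context <- function(boundaries, labeled_domains) {
  ctx <- vapply(seq_len(nrow(boundaries)), function(r) {
    d <- labeled_domains[labeled_domains$chrom == boundaries$chrom[r], ]
    left <- d$label[d$end == boundaries$pos[r]]
    right <- d$label[d$start == boundaries$pos[r]]
    if (length(left) != 1L || length(right) != 1L) return(NA_character_)
    paste(sort(c(left, right)), collapse = "-")
  }, character(1))
  groups <- mutate(boundaries, context = ctx)
  groups <- filter(groups, !is.na(.data$context))
  ctxs <- sort(unique(groups$context))
  comps <- list()
  if (length(ctxs) >= 2L) {
    for (i in seq_len(length(ctxs) - 1L)) {
      for (j in (i + 1L):length(ctxs)) {
        comps[[length(comps) + 1L]] <- tibble(
          context1 = ctxs[i], context2 = ctxs[j],
          p = rank_sum_p(groups$score[groups$context == ctxs[i]],
                         groups$score[groups$context == ctxs[j]])
        )
      }
    }
  }
  list(groups = groups,
       comparisons = if (length(comps)) bind_rows(comps)
                     else tibble(context1 = character(),
                                 context2 = character(), p = numeric()))
}

#' Pol-II pausing index per gene
#'
#' Ratio of the maximum Pol-II coverage over the promoter (200 bp upstream
#' to 50 bp downstream of the TSS, strand-aware) to the per-bp median
#' coverage over the gene body (50 bp downstream of the TSS to the gene
#' end). Genes whose body median is 0, or whose body is empty, get `NA`.
#'
#' @param polII A signal track tibble of Pol-II coverage.
#' @param genes Tibble with `chrom`, `start`, `end`, `strand` (and
#'   optionally `name`).
#' @param upstream,downstream Promoter extent around the TSS, in bp.
#' @return `genes` with `pausing_index` added.
#' @export
pausing_index <- function(polII, genes, upstream = 200, downstream = 50) {
  .validate_track(polII)
  by_chrom <- split(polII, polII$chrom)
  pi_val <- vapply(seq_len(nrow(genes)), function(r) {
    plus <- genes$strand[r] == "+"
    tss <- if (plus) genes$start[r] else genes$end[r]
    if (plus) {
      prom <- c(tss - upstream, tss + downstream)
      body <- c(tss + downstream, genes$end[r])
    } else {
      prom <- c(tss - downstream, tss + upstream)
      body <- c(genes$start[r], tss - downstream)
    }
    tc <- by_chrom[[genes$chrom[r]]]
    if (is.null(tc)) return(NA_real_)
    pseg <- .interval_segments(tc, prom[1], prom[2])
    bseg <- .interval_segments(tc, body[1], body[2])
    if (nrow(bseg) == 0L) return(NA_real_)
    med <- .weighted_median(bseg$value, bseg$len)
    if (is.na(med) || med == 0) return(NA_real_)
    max(pseg$value) / med
  }, numeric(1))
  mutate(genes, pausing_index = pi_val)
}
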