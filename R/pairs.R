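#' Read a pairs table from TSV
#'
#' Reads the tabular read-pair format consumed by the matrix builder:
#' columns `chrom1 pos1 strand1 mapq1 chrom2 pos2 strand2 mapq2` plus an
#' optional logical `dangling` column (dangling-end evidence is an
#' alignment-level call made upstream and carried through as a flag).
#'
#' @param path Path to a TSV file with a header line.
#' @return A pairs tibble.
#' @export
read_pairs <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom1", "pos1", "strand1", "mapq1",
           "chrom2", "pos2", "strand2", "mapq2")
  if (!all(req %in% names(out))) {
    stop("pairs file must have columns ", paste(req, collapse = ", "))
  }
  if (!"dangling" %in% names(out)) out$dangling <- FALSE
  out$dangling <- as.logical(out$dangling)
  out
}

# per-chromosome lookup tables for site distances and bin membership
.bin_lookup <- function(bins) {
  lapply(split(bins, bins$chrom), function(b) {
    list(
      starts = b$start,
      ends = b$end,
      bin_id = b$bin_id,
      # restriction-site positions = fragment borders, chromosome ends included
      sites = sort(unique(c(b$start, b$end))),
      len = max(b$end)
    )
  })
}

.nearest_site_dist <- function(pos, sites) {
  idx <- findInterval(pos, sites)
  left <- sites[pmax(idx, 1L)]
  right <- sites[pmin(idx + 1L, length(sites))]
  pmin(abs(pos - left), abs(pos - right))
}

#' Annotate read pairs with restriction-site distances and bin membership
#'
#' For each mate records the distance (bp) to the nearest fragment border
#' (restriction-site position; chromosome ends count as borders) and the id
#' of the bin containing it. Pairs on chromosomes absent from the bin table
#' are dropped; their count is kept in the `n_dropped_unknown_chrom`
#' attribute of the result.
#'
#' @param pairs A pairs tibble (see [read_pairs()]).
#' @param bins A bin table from [digest_genome()].
#' @return The annotated pairs tibble with columns `site_dist1`,
#'   `site_dist2`, `bin1`, `bin2` added.
#' @export
annotate_pairs <- function(pairs, bins) {
  validate_bins(bins)
  if (!"dangling" %in% names(pairs)) pairs$dangling <- FALSE
  lut <- .bin_lookup(bins)
  known <- pairs$chrom1 %in% names(lut) & pairs$chrom2 %in% names(lut)
  dropped <- sum(!known)
  pairs <- pairs[known, , drop = FALSE]
  annotate_mate <- function(chrom, pos) {
    dist <- rep(NA_real_, length(pos))
    bin <- rep(NA_integer_, length(pos))
    for (nm in unique(chrom)) {
      sel <- which(chrom == nm)
      l <- lut[[nm]]
      dist[sel] <- .nearest_site_dist(pos[sel], l$sites)
      in_range <- pos[sel] >= 0 & pos[sel] < l$len
      idx <- findInterval(pos[sel][in_range], l$starts)
      bin[sel[in_range]] <- l$bin_id[idx]
    }
    list(dist = dist, bin = bin)
  }
  m1 <- annotate_mate(pairs$chrom1, pairs$pos1)
  m2 <- annotate_mate(pairs$chrom2, pairs$pos2)
  out <- mutate(pairs,
    site_dist1 = m1$dist, site_dist2 = m2$dist,
    bin1 = m1$bin, bin2 = m2$bin
  )
  attr(out, "n_dropped_unknown_chrom") <- dropped
  out
}

.filter_reasons <- c("low_mapq", "too_close", "duplicate",
                     "dangling_end", "far_from_site")

#' Filter annotated read pairs
#'
#' Applies the standard Hi-C pair filters: minimum mapping quality on both
#' mates, minimum intra-chromosomal mate separation, duplicate removal
#' (identical mate coordinates and strands after mate ordering; first
#' occurrence kept), the dangling-end flag, and maximum distance of either
#' mate to a restriction site. Each pair is charged to the first rule it
#' violates, in that fixed order, so the per-reason counts are reproducible.
#'
#' @param pairs An annotated pairs tibble (see [annotate_pairs()]).
#' @param min_mapq Minimum mapping score; pairs with either mate below it
#'   are discarded.
#' @param min_separation Minimum intra-chromosomal separation (bp) between
#'   mate 5' positions.
#' @param max_site_distance Maximum distance (bp) of a mate to the nearest
#'   restriction site.
#' @return A list with `pairs` (the kept tibble) and `stats`, a tibble of
#'   discard counts per reason plus `kept` and `total` rows.
#' @export
filter_pairs <- function(pairs, min_mapq = 15, min_separation = 800,
                         max_site_distance = 1500) {
  n <- nrow(pairs)
  if (n == 0L) {
    stats <- tibble(reason = c(.filter_reasons, "kept", "total"),
                    n = 0L)
    return(list(pairs = pairs, stats = stats))
  }
  req <- c("site_dist1", "site_dist2")
  if (!all(req %in% names(pairs))) stop("pairs must be annotated first")

  # canonical mate order for the duplicate key
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom2 == pairs$chrom1 & pairs$pos2 < pairs$pos1)
  key1 <- ifelse(swap,
                 paste(pairs$chrom2, pairs$pos2, pairs$strand2),
                 paste(pairs$chrom1, pairs$pos1, pairs$strand1))
  key2 <- ifelse(swap,
                 paste(pairs$chrom1, pairs$pos1, pairs$strand1),
                 paste(pairs$chrom2, pairs$pos2, pairs$strand2))
  dup <- duplicated(paste(key1, key2, sep = "|"))

  intra <- pairs$chrom1 == pairs$chrom2
  sep <- abs(pairs$pos2 - pairs$pos1)

  reason <- rep(NA_character_, n)
  hit <- function(cond, r) {
    sel <- is.na(reason) & cond
    reason[sel] <<- r
  }
  hit(pairs$mapq1 < min_mapq | pairs$mapq2 < min_mapq, "low_mapq")
  hit(intra & sep < min_separation, "too_close")
  hit(dup, "duplicate")
  hit(pairs$dangling, "dangling_end")
  hit(pairs$site_dist1 > max_site_distance |
        pairs$site_dist2 > max_site_distance, "far_from_site")

  kept <- pairs[is.na(reason), , drop = FALSE]
  counts <- table(factor(reason, levels = .filter_reasons))
  stats <- tibble(
    reason = c(.filter_reasons, "kept", "total"),
    n = c(as.integer(counts), nrow(kept), n)
  )
  list(pairs = kept, stats = stats)
}

#' Accumulate filtered pairs into a contact matrix
#'
#' Each pair increments the symmetric count between the bins containing its
#' two mates; the matrix total (upper triangle plus diagonal counted once)
#' equals the number of binned pairs. Mates falling outside every bin are
#' dropped and counted in the `n_dropped_unbinned` attribute.
#'
#' @param pairs A kept, annotated pairs tibble (from [filter_pairs()]).
#' @param bins The bin table the annotation used.
#' @return A [contact_matrix()] object.
#' @export
bin_pairs <- function(pairs, bins) {
  validate_bins(bins)
  if (!all(c("bin1", "bin2") %in% names(pairs))) {
    pairs <- annotate_pairs(pairs, bins)
  }
  ok <- !is.na(pairs$bin1) & !is.na(pairs$bin2)
  dropped <- sum(!ok)
  i <- pmin(pairs$bin1[ok], pairs$bin2[ok])
  j <- pmax(pairs$bin1[ok], pairs$bin2[ok])
  n <- nrow(bins)
  upper <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  counts <- upper + Matrix::t(upper)
  Matrix::diag(counts) <- Matrix::diag(counts) / 2
  m <- contact_matrix(bins, counts)
  attr(m, "n_dropped_unbinned") <- dropped
  m
}
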