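#' Coerce a genome to a DNAStringSet
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector of
#' sequences, or the path to a FASTA file.
#'
#' @param genome Genome in any of the accepted forms.
#' @return A named `DNAStringSet`.
#' @export
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (length(genome) > 0L && is.null(names(genome))) {
      stop("genome sequences must be named")
    }
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("cannot interpret `genome` as sequences")
}

#' In silico restriction digestion of a genome
#'
#' Cuts every chromosome at each occurrence of the enzyme recognition
#' sequence and returns the resulting restriction fragments as a bin table.
#' These variable-width fragments are the rows/columns of the fragment
#' resolution contact matrix. Matching is case-insensitive and ambiguous
#' bases (N etc.) never match, so runs of Ns produce no cuts.
#'
#' @param genome Genome (see [as_genome()]).
#' @param site Recognition sequence, e.g. `"GATC"` for DpnII.
#' @param cut_offset Offset of the cut within the site, in bp from its 5'
#'   end; DpnII cuts 5' of GATC, i.e. offset 0.
#' @return A bin table: tibble with columns `chrom`, `start`, `end`
#'   (0-based, half-open) and `bin_id` (1-based, consecutive over all
#'   chromosomes). Fragments tile each chromosome without gaps; zero-length
#'   fragments are dropped. A chromosome without any site yields a single
#'   whole-chromosome fragment.
#' @examples
#' digest_genome(c(chr1 = "AAAGATCAAAAA"), site = "GATC")
#' @export
digest_genome <- function(genome, site = "GATC", cut_offset = 0L) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop("empty genome")
  site <- toupper(site)
  if (!nzchar(site)) stop("`site` must be a non-empty sequence")
  if (cut_offset < 0L || cut_offset > nchar(site)) {
    stop("`cut_offset` must lie within the recognition site")
  }
  pat <- Biostrings::DNAString(site)
  frags <- purrr::map2(names(genome), as.list(genome), function(nm, seq) {
    len <- length(seq)
    if (len == 0L) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    m <- Biostrings::matchPattern(pat, seq, fixed = TRUE)
    cuts <- BiocGenerics::start(m) - 1L + as.integer(cut_offset)
    breaks <- sort(unique(c(0L, cuts, len)))
    tibble(
      chrom = nm,
      start = breaks[-length(breaks)],
      end = breaks[-1]
    )
  })
  out <- bind_rows(frags)
  out <- filter(out, .data$end > .data$start)
  if (nrow(out) == 0L) stop("digestion produced no fragments")
  mutate(out, bin_id = row_number())
}

#' Validate a bin table
#'
#' Checks the bin-table invariants: within each chromosome intervals are
#' sorted, non-overlapping and tile the chromosome without gaps; every bin
#' has positive width; `bin_id` is 1..n in row order.
#'
#' @param bins A bin table tibble.
#' @return `bins`, invisibly, if valid; otherwise an error.
#' @export
validate_bins <- function(bins) {
  req <- c("chrom", "start", "end", "bin_id")
  if (!all(req %in% names(bins))) {
    stop("bin table must have columns ", paste(req, collapse = ", "))
  }
  if (any(bins$end <= bins$start)) stop("bin table has empty or inverted bins")
  if (!identical(as.integer(bins$bin_id), seq_len(nrow(bins)))) {
    stop("bin_id must be 1..n in row order")
  }
  by_chrom <- split(bins, bins$chrom)
  for (b in by_chrom) {
    if (is.unsorted(b$start, strictly = TRUE)) {
      stop("bins not sorted within chromosome ", b$chrom[1])
    }
    if (any(b$start[-1] != b$end[-nrow(b)])) {
      stop("bins overlap or leave gaps on chromosome ", b$chrom[1])
    }
  }
  invisible(bins)
}

#' Fixed-width binning helper
#'
#' Convenience constructor for a uniform bin table (used by the simulator
#' and in examples); fragments from a real digestion come from
#' [digest_genome()] instead.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param width Bin width in bp; the last bin of a chromosome may be
#'   shorter.
#' @return A bin table tibble.
#' @export
tile_bins <- function(chrom_sizes, width) {
  stopifnot(width > 0, !is.null(names(chrom_sizes)))
  out <- purrr::imap(chrom_sizes, function(len, nm) {
    starts <- seq(0L, len - 1L, by = width)
    tibble(chrom = nm, start = as.integer(starts),
           end = as.integer(pmin(starts + width, len)))
  })
  mutate(bind_rows(out), bin_id = row_number())
}
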