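#' Write boundary, domain and track outputs
#'
#' `write_boundaries_bed` writes BED6+3 (name = rank by p, score =
#' -log10 p_adj capped at 1000, then delta, p_raw, p_adj columns);
#' `write_domains_bed` writes BED3; `write_track_bedgraph` writes the
#' multi-scale separation score as bedGraph over valid bins.
#'
#' @param boundaries,domains,track The respective tibbles.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundaries_bed <- function(boundaries, path) {
  b <- arrange(boundaries, .data$p_adj, .data$p_raw)
  out <- tibble(
    chrom = b$chrom, start = b$pos, end = b$pos + 1,
    name = paste0("boundary_", seq_len(nrow(b))),
    score = round(pmin(1000, -log10(pmax(b$p_adj, 1e-300))), 3),
    strand = ".",
    delta = b$delta, p_raw = b$p_raw, p_adj = b$p_adj
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_bed
#' @export
write_domains_bed <- function(domains, path) {
  readr::write_tsv(select(domains, "chrom", "start", "end"), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_bed
#' @export
write_track_bedgraph <- function(track, path) {
  t <- filter(track, .data$valid)
  readr::write_tsv(select(t, "chrom", "start", "end", "score"), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
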