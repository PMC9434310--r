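#' Partition chromosomes into core + flank analysis segments
#'
#' Each chromosome's SNPs are tiled by non-overlapping cores of
#' `core_size` contiguous SNPs (the last core takes the remainder), and each
#' core gets overlapping flanking buffers of up to `flank_size` SNPs on each
#' side, clipped at chromosome boundaries. The flanks are included in the
#' per-segment regression to absorb LD with neighbouring cores, but only
#' core SNPs seed LD windows. Indices are 1-based, inclusive, in panel
#' coordinates; a flank clipped to nothing at a chromosome edge is encoded
#' by `flank_start == core_start` (or `flank_end == core_end`).
#'
#' @param panel a [genotype_panel()] (only its `snp_map` is used).
#' @param core_size SNPs per non-overlapping core (default 1000).
#' @param flank_size SNPs per flank on each side of the core (default 250).
#' @return A tibble with one row per segment: `segment`, `chrom`,
#'   `core_start`, `core_end`, `flank_start`, `flank_end` (full segment
#'   extent = core plus clipped flanks), `start`, `end` (aliases of the full
#'   extent), `n_core`, `n_total`.
#' @export
make_segments <- function(panel, core_size = 1000, flank_size = 250) {
  stopifnot(core_size >= 1, flank_size >= 0)
  sm <- panel$snp_map
  out <- lapply(unique(sm$chrom), function(ch) {
    idx <- which(sm$chrom == ch)
    if (length(idx) == 0) return(NULL)
    lo <- idx[1]
    hi <- idx[length(idx)]
    starts <- seq.int(lo, hi, by = core_size)
    ends <- pmin(starts + core_size - 1, hi)
    tibble::tibble(
      chrom = ch,
      core_start = starts,
      core_end = ends,
      flank_start = pmax(starts - flank_size, lo),
      flank_end = pmin(ends + flank_size, hi)
    )
  })
  seg <- dplyr::bind_rows(out)
  seg <- dplyr::mutate(
    seg,
    segment = dplyr::row_number(),
    start = .data$flank_start,
    end = .data$flank_end,
    n_core = .data$core_end - .data$core_start + 1L,
    n_total = .data$flank_end - .data$flank_start + 1L,
    .before = 1
  )
  seg[, c("segment", "chrom", "core_start", "core_end", "flank_start",
          "flank_end", "start", "end", "n_core", "n_total")]
}

#' Export segments as an audit TSV
#'
#' Writes one row per segment with the chromosome, base-pair span of the
#' core, and the core/flank index spans.
#'
#' @param segments output of [make_segments()].
#' @param panel the panel the segments index into.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, panel, path) {
  sm <- panel$snp_map
  tab <- dplyr::mutate(
    segments,
    core_bp_start = sm$pos[.data$core_start],
    core_bp_end = sm$pos[.data$core_end]
  )
  readr::write_tsv(tab, path)
  invisible(path)
}
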