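#' Pearson correlation between two SNP dosage columns
#'
#' Correlation of (imputed) dosage columns `i` and `j`. A zero-variance
#' column yields 0 by convention, so monomorphic SNPs can never pass a
#' positive LD threshold.
#'
#' @param X numeric dosage matrix (individuals x SNPs), imputed.
#' @param i,j column indices.
#' @return The correlation, in \[-1, 1\].
#' @export
snp_cor <- function(X, i, j) {
  xi <- X[, i]
  xj <- X[, j]
  si <- sd(xi)
  sj <- sd(xj)
  if (si < 1e-12 || sj < 1e-12) return(0)
  cor(xi, xj)
}

# pass/fail walk in one direction; returns included indices (excluding seed).
# candidates: index vector ordered outward from the seed.
walk_direction <- function(X, seed, candidates, threshold) {
  if (length(candidates) == 0) return(integer(0))
  last_pass <- 0L
  fails <- 0L
  for (t in seq_along(candidates)) {
    if (abs(snp_cor(X, seed, candidates[t])) >= threshold) {
      last_pass <- t
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails == 2L) break
    }
  }
  if (last_pass == 0L) return(integer(0))
  candidates[seq_len(last_pass)]
}

#' Seed-anchored LD window around one core SNP
#'
#' Starting at a core-segment seed SNP, candidates are tested sequentially
#' outward in both directions with the rule `|Corr(x_seed, x_candidate)| >=
#' threshold`. A single failing SNP is still included when the next SNP
#' beyond it passes (one-SNP gap allowance for brief LD loss or mapping
#' error); two consecutive failures end the walk in that direction and
#' neither failing SNP is included. The walk may extend into the segment's
#' flanks but never beyond the segment, and flank SNPs never act as seeds.
#'
#' The absolute correlation is used so window membership does not depend on
#' arbitrary allele coding.
#'
#' @param X imputed centered dosage matrix in panel coordinates.
#' @param segment one row of [make_segments()] (list or one-row data frame).
#' @param seed panel index of the seed SNP; must lie in the segment core.
#' @param threshold LD inclusion threshold (default 0.1).
#' @return Integer vector of member panel indices (a contiguous run
#'   containing the seed).
#' @export
define_window <- function(X, segment, seed, threshold = 0.1) {
  stopifnot(threshold > 0)
  if (seed < segment$core_start || seed > segment$core_end) {
    stop("seed SNP ", seed, " is outside the segment core [",
         segment$core_start, ", ", segment$core_end, "]", call. = FALSE)
  }
  left <- if (seed > segment$flank_start)
    walk_direction(X, seed, seq.int(seed - 1L, segment$flank_start), threshold)
  else integer(0)
  right <- if (seed < segment$flank_end)
    walk_direction(X, seed, seq.int(seed + 1L, segment$flank_end), threshold)
  else integer(0)
  sort(c(left, seed, right))
}

#' Enumerate LD windows for every core SNP
#'
#' Builds one window per core SNP across all segments, then removes
#' exact-duplicate member sets (keeping the first seed in map order). Raw
#' and deduplicated counts are attached as the `"window_counts"` attribute.
#'
#' @param X imputed centered dosage matrix in panel coordinates.
#' @param panel the [genotype_panel()] (for the SNP map).
#' @param segments output of [make_segments()].
#' @param threshold LD inclusion threshold (default 0.1).
#' @param dedup drop duplicate member sets (default `TRUE`).
#' @return A tibble with one row per window: `window`, `segment`, `seed`
#'   (panel index), `seed_id`, `chrom`, `start_idx`, `end_idx`, `n_snps`,
#'   `bp_start`, `bp_end`, `first_id`, `last_id`.
#' @export
enumerate_windows <- function(X, panel, segments, threshold = 0.1,
                              dedup = TRUE) {
  sm <- panel$snp_map
  rows <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    seg <- segments[s, ]
    seeds <- seq.int(seg$core_start, seg$core_end)
    res <- lapply(seeds, function(j) {
      mem <- define_window(X, seg, j, threshold)
      c(j, mem[1], mem[length(mem)])
    })
    res <- do.call(rbind, res)
    rows[[s]] <- tibble::tibble(segment = seg$segment, seed = res[, 1],
                                start_idx = res[, 2], end_idx = res[, 3])
  }
  win <- dplyr::bind_rows(rows)
  n_raw <- nrow(win)
  if (dedup) {
    win <- win[!duplicated(win[, c("start_idx", "end_idx")]), ]
  }
  win <- dplyr::mutate(
    win,
    window = dplyr::row_number(),
    seed_id = sm$id[.data$seed],
    chrom = sm$chrom[.data$seed],
    n_snps = .data$end_idx - .data$start_idx + 1L,
    bp_start = sm$pos[.data$start_idx],
    bp_end = sm$pos[.data$end_idx],
    first_id = sm$id[.data$start_idx],
    last_id = sm$id[.data$end_idx]
  )
  win <- win[, c("window", "segment", "seed", "seed_id", "chrom",
                 "start_idx", "end_idx", "n_snps", "bp_start", "bp_end",
                 "first_id", "last_id")]
  attr(win, "window_counts") <- c(raw = n_raw, dedup = nrow(win))
  win
}

#' Export windows as BED plus a member TSV
#'
#' Writes a 0-based half-open BED of window base-pair spans and a TSV
#' listing each window's member SNP identifiers.
#'
#' @param windows output of [enumerate_windows()].
#' @param panel the panel the windows index into.
#' @param bed_path,members_path output paths.
#' @return `bed_path`, invisibly.
#' @export
write_windows_bed <- function(windows, panel, bed_path, members_path = NULL) {
  bed <- data.frame(chrom = windows$chrom,
                    start = windows$bp_start - 1L,
                    end = windows$bp_end,
                    name = paste0("window_", windows$window))
  utils::write.table(bed, bed_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(members_path)) {
    mem <- dplyr::mutate(
      windows[, c("window", "seed_id")],
      members = purrr::map2_chr(windows$start_idx, windows$end_idx,
                                ~ paste(panel$snp_map$id[.x:.y],
                                        collapse = ","))
    )
    readr::write_tsv(mem, members_path)
  }
  invisible(bed_path)
}
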