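#' Posterior draws of a window's local (co)variances
#'
#' For retained draw `s`, the local quantities are
#' `V1 = Var(X_w beta_w1)`, `V2 = Var(X_w beta_w2)` and
#' `Cov = Cov(X_w beta_w1, X_w beta_w2)` — sample (co)variances over
#' individuals of the two genetic score vectors (denominator `n - 1`).
#' These are computed through the algebraically identical quadratic forms
#' `beta_w1' S_w beta_w2` with `S_w` the sample covariance matrix of the
#' member dosages, which avoids forming the score vectors per draw.
#'
#' @param Xw centered dosage matrix of the window's member SNPs
#'   (individuals x members).
#' @param beta1,beta2 retained effect draws for the member SNPs
#'   (draws x members), taken from the window's own segment fit.
#' @return A tibble with one row per draw: `v1`, `v2`, `cov`.
#' @export
window_cov_draws <- function(Xw, beta1, beta2) {
  Xw <- as.matrix(Xw)
  beta1 <- rbind(beta1)
  beta2 <- rbind(beta2)
  if (ncol(beta1) != ncol(Xw) || ncol(beta2) != ncol(Xw)) {
    stop("effect-draw columns (", ncol(beta1), ") do not match window SNPs (",
         ncol(Xw), ")", call. = FALSE)
  }
  Sw <- cov(Xw)
  A1 <- beta1 %*% Sw
  tibble::tibble(
    v1 = rowSums(A1 * beta1),
    v2 = rowSums((beta2 %*% Sw) * beta2),
    cov = rowSums(A1 * beta2)
  )
}

#' Summarize local (co)variance draws for one window
#'
#' Posterior mean, SD, and equal-tailed credible region (empirical
#' quantiles, R's default type-7 interpolation) for each of `(V1, V2, Cov)`,
#' plus the significance flag: a window is significant when its covariance
#' credible region excludes zero (`cr_low > 0` or `cr_high < 0`).
#'
#' @param draws output of [window_cov_draws()] (>= 2 rows).
#' @param level credible level (default 0.95).
#' @return A one-row tibble with `<q>_mean`, `<q>_sd`, `<q>_lo`, `<q>_hi`
#'   for `q` in `v1`, `v2`, `cov`, and `significant`.
#' @export
summarize_window <- function(draws, level = 0.95) {
  if (nrow(draws) < 2) stop("need at least 2 draws", call. = FALSE)
  if (!all(vapply(draws[c("v1", "v2", "cov")], function(x) all(is.finite(x)),
                  logical(1)))) {
    stop("non-finite (co)variance draws", call. = FALSE)
  }
  a <- (1 - level) / 2
  smry <- function(x, nm) {
    q <- quantile(x, c(a, 1 - a), names = FALSE)
    setNames(c(mean(x), sd(x), q[1], q[2]),
             paste0(nm, c("_mean", "_sd", "_lo", "_hi")))
  }
  out <- c(smry(draws$v1, "v1"), smry(draws$v2, "v2"), smry(draws$cov, "cov"))
  res <- tibble::as_tibble(as.list(out))
  res$significant <- res$cov_lo > 0 | res$cov_hi < 0
  res
}

#' Local (co)variance estimates for every window
#'
#' Applies [window_cov_draws()] + [summarize_window()] to each window of a
#' window table, pulling the member-SNP effect draws from the corresponding
#' segment fits.
#'
#' @param windows output of [enumerate_windows()].
#' @param X imputed centered dosage matrix in panel coordinates.
#' @param fits list of `mt_fit` objects indexed by segment number, fit on
#'   columns `flank_start:flank_end` of the segment.
#' @param segments the segment table the fits correspond to.
#' @param level credible level (default 0.95).
#' @return The `windows` tibble augmented with the [summarize_window()]
#'   columns.
#' @export
estimate_windows <- function(windows, X, fits, segments, level = 0.95) {
  stats <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    seg <- segments[segments$segment == w$segment, ]
    fit <- fits[[w$segment]]
    local <- seq.int(w$start_idx, w$end_idx) - seg$flank_start + 1L
    draws <- window_cov_draws(X[, w$start_idx:w$end_idx, drop = FALSE],
                              fit$beta1[, local, drop = FALSE],
                              fit$beta2[, local, drop = FALSE])
    summarize_window(draws, level)
  })
  dplyr::bind_cols(windows, dplyr::bind_rows(stats))
}

#' Collapse significant windows into distinct loci
#'
#' Significant windows that share at least one member SNP are merged by
#' transitive closure into loci; since windows are contiguous index runs on
#' one chromosome this is an interval-overlap sweep. Each locus reports its
#' representative window (largest `|posterior mean Cov|`) and the direction
#' of that covariance.
#'
#' @param estimates output of [estimate_windows()], already restricted to
#'   significant windows (rows with `significant == TRUE`; others error).
#' @return A tibble with one row per locus: `locus`, `chrom`, `start_idx`,
#'   `end_idx`, `bp_start`, `bp_end`, `n_windows`, `n_snps`,
#'   `rep_window`, `cov_mean`, `cov_lo`, `cov_hi` (representative window's
#'   values), `direction` (+1/-1).
#' @export
merge_significant_windows <- function(estimates) {
  if (nrow(estimates) == 0) {
    return(tibble::tibble(locus = integer(), chrom = integer(),
                          start_idx = integer(), end_idx = integer(),
                          bp_start = integer(), bp_end = integer(),
                          n_windows = integer(), n_snps = integer(),
                          rep_window = integer(), cov_mean = double(),
                          cov_lo = double(), cov_hi = double(),
                          direction = double()))
  }
  if (!all(estimates$significant)) {
    stop("merge_significant_windows expects only significant windows",
         call. = FALSE)
  }
  est <- dplyr::arrange(estimates, .data$chrom, .data$start_idx,
                        .data$end_idx)
  grp <- integer(nrow(est))
  g <- 0L
  cur_end <- -Inf
  cur_chrom <- NA_integer_
  for (i in seq_len(nrow(est))) {
    if (is.na(cur_chrom) || est$chrom[i] != cur_chrom ||
        est$start_idx[i] > cur_end) {
      g <- g + 1L
      cur_chrom <- est$chrom[i]
      cur_end <- est$end_idx[i]
    } else {
      cur_end <- max(cur_end, est$end_idx[i])
    }
    grp[i] <- g
  }
  est$locus <- grp
  loci <- dplyr::group_by(est, .data$locus)
  loci <- dplyr::summarise(
    loci,
    chrom = dplyr::first(.data$chrom),
    start_idx = min(.data$start_idx),
    end_idx = max(.data$end_idx),
    bp_start = min(.data$bp_start),
    bp_end = max(.data$bp_end),
    n_windows = dplyr::n(),
    ri = which.max(abs(.data$cov_mean)),
    rep_window = .data$window[ri],
    rep_cov_mean = .data$cov_mean[ri],
    rep_cov_lo = .data$cov_lo[ri],
    rep_cov_hi = .data$cov_hi[ri],
    .groups = "drop"
  )
  loci$ri <- NULL
  names(loci) <- sub("^rep_cov_", "cov_", names(loci))
  loci$n_snps <- loci$end_idx - loci$start_idx + 1L
  loci$direction <- sign(loci$cov_mean)
  dplyr::arrange(loci, .data$chrom, .data$bp_start)
}

#' Write window and locus report tables
#'
#' Writes a TSV of all window estimates and a TSV of the condensed loci.
#' (Co)variance estimates, SDs and credible bounds are multiplied by
#' `scale` (default `1e4`) for readability, mirroring the convention of
#' reporting trait (co)variances x 1E4; the scale factor is recorded in a
#' header comment. Values are printed at 6 significant digits.
#'
#' @param estimates output of [estimate_windows()].
#' @param loci output of [merge_significant_windows()].
#' @param dir output directory (created if needed).
#' @param scale multiplier applied to (co)variance columns (default 1e4).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(estimates, loci, dir, scale = 1e4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num_cols <- grep("^(v1|v2|cov)_", names(estimates), value = TRUE)
  fmt <- function(tab, cols) {
    for (cc in cols) tab[[cc]] <- signif(tab[[cc]] * scale, 6)
    tab
  }
  win_path <- file.path(dir, "windows.tsv")
  loci_path <- file.path(dir, "loci.tsv")
  hdr <- paste0("# (co)variance columns scaled by ", format(scale), "\n")
  writeLines(sub("\n$", "", hdr), win_path)
  readr::write_tsv(fmt(estimates, num_cols), win_path, append = TRUE,
                   col_names = TRUE)
  writeLines(sub("\n$", "", hdr), loci_path)
  loci_cols <- intersect(c("cov_mean", "cov_lo", "cov_hi"), names(loci))
  readr::write_tsv(fmt(loci, loci_cols), loci_path, append = TRUE,
                   col_names = TRUE)
  invisible(c(windows = win_path, loci = loci_path))
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path a `windows.tsv` or `loci.tsv` path.
#' @return A tibble with the scaled columns as written.
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
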