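#' Genome-wide plot of local covariance estimates
#'
#' One point per LD window at its seed position, posterior mean local
#' covariance (scaled for readability) on the y axis, windows whose 95%
#' credible region excludes zero highlighted.
#'
#' @param estimates output of [estimate_windows()].
#' @param scale y-axis multiplier (default 1e4, the reporting convention).
#' @return A ggplot object.
#' @export
plot_local_cov <- function(estimates, scale = 1e4) {
  dat <- dplyr::mutate(estimates, y = .data$cov_mean * scale,
                       mb = .data$bp_start / 1e6)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mb, y = .data$y,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)",
                  y = sprintf("local covariance (x %g)", scale),
                  colour = "95% CR excludes 0") +
    ggplot2::theme_minimal()
}

#' Forest plot of condensed loci
#'
#' Representative-window covariance estimates with credible regions for each
#' distinct locus, ordered by covariance magnitude.
#'
#' @param loci output of [merge_significant_windows()].
#' @param scale multiplier (default 1e4).
#' @return A ggplot object.
#' @export
plot_loci <- function(loci, scale = 1e4) {
  dat <- dplyr::mutate(
    loci,
    label = sprintf("chr%d:%.2f-%.2fMb (%d SNPs)", .data$chrom,
                    .data$bp_start / 1e6, .data$bp_end / 1e6, .data$n_snps))
  dat$label <- factor(dat$label,
                      levels = dat$label[order(abs(dat$cov_mean))])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cov_mean * scale,
                                    y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$cov_lo * scale,
                                         xmax = .data$cov_hi * scale),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("local covariance (x %g) with 95%% CR", scale),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior-inclusion plot for a segment fit
#'
#' @param object an `mt_fit`.
#' @param ... unused.
#' @return A ggplot object showing per-SNP posterior inclusion
#'   probabilities by trait.
#' @export
autoplot.mt_fit <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$snp, y = .data$inclusion)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$snp, yend = 0),
                          linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$trait)) +
    ggplot2::labs(x = "SNP (segment coordinates)",
                  y = "posterior inclusion probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
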