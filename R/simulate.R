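#' Simulation settings for block-LD genotypes and bivariate traits
#'
#' Describes a genotype panel with linkage-disequilibrium blocks and a pair
#' of quantitative traits with planted sparse effects. The defaults are a
#' study condition used throughout the package's calibration experiments:
#' 1,000 individuals, 600 SNPs in 20-SNP LD blocks with latent AR(1)
#' correlation 0.9, MAF drawn in (0.05, 0.5), one pleiotropic causal block
#' in the middle of the panel with 10 causal SNPs whose effect pairs are
#' drawn from `N(0, Sigma_loc)` with strong positive effect correlation,
#' and residual covariance `R_true` with correlation 0.2 — giving the
#' causal window a local covariance that is a substantial (well above 5%)
#' share of the total trait covariance.
#'
#' @param n_individuals sample size (default 1000).
#' @param n_snps panel size (default 600).
#' @param block_length SNPs per LD block (default 20; the last block takes
#'   any remainder).
#' @param within_block_rho latent AR(1) correlation inside a block, in
#'   \[0, 1) (default 0.9).
#' @param maf_range per-SNP minor allele frequencies are drawn uniformly in
#'   this interval (default `c(0.05, 0.5)`).
#' @param causal_blocks list of causal-block descriptors, each a list with
#'   `block` (block id), `n_causal`, and `Sigma_loc` (2x2 per-SNP
#'   effect-pair covariance). `NULL` plants no effects. The default plants
#'   one pleiotropic block in the middle of the panel.
#' @param R_true 2x2 residual covariance (default unit variances,
#'   covariance 0.2).
#' @param chrom chromosome label for the map (default 1).
#' @param bp_spacing base-pair spacing of the uniform position grid
#'   (default 3000, so typical multi-SNP windows span tens of kb).
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000, n_snps = 600,
                       block_length = 20, within_block_rho = 0.9,
                       maf_range = c(0.05, 0.5),
                       causal_blocks = list(list(
                         block = 15, n_causal = 10,
                         Sigma_loc = 0.02 * matrix(c(1, 0.9, 0.9, 1), 2))),
                       R_true = matrix(c(1, 0.2, 0.2, 1), 2),
                       chrom = 1L, bp_spacing = 3000L, seed = 1L) {
  stopifnot(n_individuals >= 2, n_snps >= 1, block_length >= 1,
            within_block_rho >= 0, within_block_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  R_true <- as.matrix(R_true)
  stopifnot(nrow(R_true) == 2, isTRUE(all.equal(R_true, t(R_true))),
            min(eigen(R_true, only.values = TRUE)$values) >= 0)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps),
              block_length = as.integer(block_length),
              within_block_rho = within_block_rho,
              maf_range = maf_range, causal_blocks = causal_blocks,
              R_true = R_true, chrom = as.integer(chrom),
              bp_spacing = as.integer(bp_spacing), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sim_block_ids <- function(config) {
  ((seq_len(config$n_snps) - 1L) %/% config$block_length) + 1L
}

#' Simulate a block-LD genotype panel
#'
#' For each individual and each LD block, two latent Gaussian AR(1) vectors
#' (one per haplotype) are thresholded at the per-SNP cut point
#' `qnorm(1 - maf)` and summed to a dosage in \{0, 1, 2\}. Within-block
#' dosage correlation rises with `within_block_rho`; blocks are mutually
#' independent. Positions lie on a uniform `bp_spacing` grid; the block id
#' of every SNP is kept in the map's `block` column.
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel()] whose `snp_map` carries a `block` column
#'   and per-SNP `maf` used for thresholding.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  p <- config$n_snps
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  if (any(maf <= 0 | maf >= 1)) stop("degenerate MAF", call. = FALSE)
  thr <- qnorm(1 - maf)
  blocks <- sim_block_ids(config)
  rho <- config$within_block_rho
  hap <- function() {
    Z <- matrix(rnorm(n * p), n, p)
    if (rho > 0 && p >= 2) {
      s <- sqrt(1 - rho^2)
      for (j in 2:p) {
        if (blocks[j] == blocks[j - 1]) {
          Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
        }
      }
    }
    Z
  }
  dos <- (hap() > matrix(thr, n, p, byrow = TRUE)) +
    (hap() > matrix(thr, n, p, byrow = TRUE))
  snp_map <- tibble::tibble(
    id = sprintf("snp_%05d", seq_len(p)),
    chrom = config$chrom,
    pos = seq_len(p) * config$bp_spacing,
    a1 = "A", a2 = "B",
    block = blocks, maf = maf
  )
  genotype_panel(dos * 1, snp_map,
                 sample_ids = sprintf("ind_%05d", seq_len(n)))
}

#' Simulate bivariate traits with planted sparse effects
#'
#' Instantiates the generative model `Y = X beta + E` on a simulated panel:
#' for each causal block, `n_causal` SNPs are chosen at random and their
#' effect pairs drawn from `N(0, Sigma_loc)`; all other effects are zero.
#' Error rows are `N(0, R_true)` and are column-centered before adding, so
#' `Y` is exactly column-centered and `Y - E == X beta` holds exactly
#' (with `X` the centered dosages).
#'
#' @param panel output of [simulate_genotypes()] for the same `config`.
#' @param config the [sim_config()].
#' @return A list with `Y` (centered `n x 2` trait matrix) and `truth`, a
#'   `sim_truth` object holding `beta` (`p x 2`), `causal` (indices), `E`
#'   (the centered errors), `X` reference note, and the config.
#' @export
simulate_traits <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  p <- config$n_snps
  n <- config$n_individuals
  blocks <- sim_block_ids(config)
  beta <- matrix(0, p, 2)
  causal <- integer(0)
  for (cb in config$causal_blocks %||% list()) {
    in_block <- which(blocks == cb$block)
    if (length(in_block) == 0) stop("causal block ", cb$block,
                                    " does not exist", call. = FALSE)
    if (cb$n_causal > length(in_block)) {
      stop("causal count ", cb$n_causal, " exceeds block size ",
           length(in_block), call. = FALSE)
    }
    pick <- sort(sample(in_block, cb$n_causal))
    L <- chol(as.matrix(cb$Sigma_loc) + 1e-12 * diag(2))
    beta[pick, ] <- matrix(rnorm(2 * cb$n_causal), cb$n_causal, 2) %*% L
    causal <- c(causal, pick)
  }
  Xc <- impute_center(panel)
  LR <- chol(config$R_true + 1e-12 * diag(2))
  E <- matrix(rnorm(2 * n), n, 2) %*% LR
  E <- sweep(E, 2, colMeans(E))
  Y <- Xc %*% beta + E
  colnames(Y) <- c("trait1", "trait2")
  truth <- structure(
    list(beta = beta, causal = causal, E = E, config = config),
    class = "sim_truth")
  list(Y = Y, truth = truth)
}

#' True local (co)variances of a window under the simulation truth
#'
#' Evaluates the same sample (co)variance functional used by the estimator,
#' `Var/Cov(X_w beta_true)`, at the planted effects — the quantity the
#' window's posterior should concentrate on.
#'
#' @param X imputed centered dosage matrix of the panel.
#' @param truth the `sim_truth` from [simulate_traits()].
#' @param start_idx,end_idx window member index range (panel coordinates).
#' @return A one-row tibble with `v1`, `v2`, `cov`.
#' @export
true_window_cov <- function(X, truth, start_idx, end_idx) {
  idx <- seq.int(start_idx, end_idx)
  window_cov_draws(X[, idx, drop = FALSE],
                   matrix(truth$beta[idx, 1], 1),
                   matrix(truth$beta[idx, 2], 1))
}
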