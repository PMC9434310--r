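#' Genotype panel container
#'
#' Bundles an individuals-by-SNPs dosage matrix with its SNP map. Dosages are
#' counts of the A1 allele in \{0, 1, 2\} with `NA` for missing calls. The SNP
#' map must be sorted by (chromosome, position), strictly increasing within
#' each chromosome, and everything downstream (segments, windows, loci) is
#' expressed in this coordinate frame.
#'
#' @param dosages numeric matrix, `n_individuals x n_snps`, values in
#'   \{0, 1, 2, NA\} (fractional values are allowed after imputation/centering
#'   but not at construction).
#' @param snp_map data frame with columns `id`, `chrom` (integer 1-22),
#'   `pos` (base pairs), and optionally `a1`, `a2` allele labels.
#' @param sample_ids character vector of individual identifiers; defaults to
#'   rownames of `dosages` or `ind_1 ... ind_n`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `snp_map` (tibble), `sample_ids`.
#' @export
genotype_panel <- function(dosages, snp_map, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  snp_map <- tibble::as_tibble(snp_map)
  stopifnot(all(c("id", "chrom", "pos") %in% names(snp_map)))
  if (ncol(dosages) != nrow(snp_map)) {
    stop("snp_map rows (", nrow(snp_map), ") != dosage columns (",
         ncol(dosages), ")", call. = FALSE)
  }
  bad <- dosages[!is.na(dosages) & !(dosages %in% c(0, 1, 2))]
  if (length(bad) > 0) {
    stop("dosages must be in {0, 1, 2, NA} at construction", call. = FALSE)
  }
  ord <- order(snp_map$chrom, snp_map$pos)
  if (!identical(ord, seq_len(nrow(snp_map)))) {
    stop("snp_map must be sorted by (chrom, pos)", call. = FALSE)
  }
  if (any(duplicated(snp_map[, c("chrom", "pos")]))) {
    stop("snp_map positions must be strictly increasing within chromosome",
         call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("ind_", seq_len(nrow(dosages)))
  }
  stopifnot(length(sample_ids) == nrow(dosages))
  colnames(dosages) <- snp_map$id
  rownames(dosages) <- sample_ids
  structure(
    list(dosages = dosages, snp_map = snp_map,
         sample_ids = as.character(sample_ids)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " SNPs, chromosomes ",
      paste(range(x$snp_map$chrom), collapse = "-"), "\n", sep = "")
  nmiss <- sum(is.na(x$dosages))
  cat("  missing calls: ", nmiss, " (",
      format(100 * nmiss / length(x$dosages), digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Per-SNP quality-control summary
#'
#' Minor allele frequency and missing-call rate for every SNP, computed from
#' the observed (non-missing) dosages. MAF is `min(p, 1 - p)` where `p` is
#' the A1 allele frequency.
#'
#' @param panel a [genotype_panel()].
#' @return A tibble with one row per SNP: `id`, `chrom`, `pos`, `maf`,
#'   `miss_rate`.
#' @export
snp_qc_stats <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- panel$dosages
  n <- nrow(G)
  nmiss <- colSums(is.na(G))
  p_a1 <- colMeans(G, na.rm = TRUE) / 2
  p_a1[nmiss == n] <- NA_real_
  dplyr::mutate(
    panel$snp_map[, c("id", "chrom", "pos")],
    maf = pmin(p_a1, 1 - p_a1),
    miss_rate = nmiss / n
  )
}

#' Filter SNPs on minor allele frequency and missing-call rate
#'
#' Retains SNPs with MAF >= `maf_min` and missing fraction <= `miss_max`
#' (defaults mirror the usual biobank thresholds: drop MAF < 1% or
#' missingness > 5%). SNP order is preserved. Kept/dropped counts are
#' attached as the `"qc_counts"` attribute and reported via `message()`.
#'
#' @inheritParams snp_qc_stats
#' @param maf_min minimum minor allele frequency, in \[0, 0.5\].
#' @param miss_max maximum missing-call fraction, in \[0, 1\].
#' @param quiet suppress the log message.
#' @return The filtered `genotype_panel`.
#' @export
qc_filter <- function(panel, maf_min = 0.01, miss_max = 0.05, quiet = FALSE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  st <- snp_qc_stats(panel)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$miss_rate <= miss_max
  if (!any(keep)) stop("qc_filter removed every SNP", call. = FALSE)
  out <- genotype_panel(panel$dosages[, keep, drop = FALSE],
                        panel$snp_map[keep, ], panel$sample_ids)
  counts <- c(kept = sum(keep), dropped = sum(!keep))
  attr(out, "qc_counts") <- counts
  if (!quiet) {
    message("qc_filter: kept ", counts[["kept"]], " SNPs, dropped ",
            counts[["dropped"]], " (maf_min=", maf_min,
            ", miss_max=", miss_max, ")")
  }
  out
}

#' Mean-impute missing dosages and center columns
#'
#' Missing cells are replaced by the per-SNP mean of the observed dosages,
#' then every column is mean-centered. Dosages are deliberately not
#' variance-standardized: the local (co)variance formulas are built on
#' `Var(X_w beta_w)`, which is centering-invariant, and per-allele effect
#' scales are preserved. Monomorphic columns (zero variance after
#' imputation) are retained with a warning; they contribute nothing to any
#' window (co)variance.
#'
#' @inheritParams snp_qc_stats
#' @return A numeric matrix of centered dosages (no `NA`s), with the SNP ids
#'   as column names and a `"monomorphic"` attribute flagging zero-variance
#'   columns.
#' @export
impute_center <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- panel$dosages
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G))
  if (length(idx) > 0) {
    G[idx] <- mu[((idx - 1) %/% nrow(G)) + 1]
  }
  Gc <- sweep(G, 2, colMeans(G))
  mono <- apply(Gc, 2, function(x) all(abs(x) < 1e-12))
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP column(s) retained (zero variance)",
            call. = FALSE)
  }
  attr(Gc, "monomorphic") <- unname(mono)
  Gc
}

#' Preadjust a pair of raw traits for covariates
#'
#' Optionally log-transforms each trait, then regresses it on an intercept
#' plus the supplied covariates (typically age, sex, and leading genotype
#' principal components) by ordinary least squares, returning the residuals.
#' The two traits are adjusted independently; residuals are mean-zero and
#' orthogonal to every covariate column.
#'
#' @param raw numeric matrix or data frame, `n x 2`, the raw trait values
#'   (strictly positive when `log_transform = TRUE`).
#' @param covariates numeric matrix or data frame of covariates (no
#'   intercept column; one is added). May be `NULL` for intercept-only
#'   adjustment.
#' @param log_transform take `log()` of each trait first (default `TRUE`).
#' @return A numeric `n x 2` matrix of preadjusted trait residuals, carrying
#'   the original column names.
#' @export
preadjust_traits <- function(raw, covariates = NULL, log_transform = TRUE) {
  raw <- as.matrix(raw)
  stopifnot(ncol(raw) == 2)
  if (anyNA(raw)) stop("raw traits contain missing values; supply complete cases",
                       call. = FALSE)
  if (log_transform) {
    bad <- which(raw <= 0)
    if (length(bad) > 0) {
      stop("non-positive trait value at row ",
           ((bad[1] - 1) %% nrow(raw)) + 1, "; cannot log-transform",
           call. = FALSE)
    }
    raw <- log(raw)
  }
  n <- nrow(raw)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.matrix(covariates)
    if (anyNA(covariates)) stop("covariates contain missing values", call. = FALSE)
    stopifnot(nrow(covariates) == n)
    Z <- cbind(`(Intercept)` = 1, covariates)
  }
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    drop_cols <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  res <- raw - Z %*% qr.coef(qz, raw)
  dimnames(res) <- dimnames(raw)
  res
}
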