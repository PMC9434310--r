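#' Fit the bivariate spike-and-slab model to one segment
#'
#' Runs the Gibbs sampler for `Y = 1 mu' + X beta + E` on the centered
#' dosages of one chromosomal segment (core plus flanks). Every block
#' (intercepts, per-SNP effect pairs with their inclusion indicators, slab
#' covariance `Sigma`, residual covariance `R`, inclusion probabilities
#' `pi`) is updated each iteration; draws after burn-in are retained at the
#' thinning interval. Chains are bit-reproducible for a given
#' `(data, config, seed)`.
#'
#' @param X numeric matrix of centered dosages for the segment's SNPs
#'   (individuals x SNPs), e.g. a column slice of [impute_center()] output.
#' @param Y numeric `n x 2` matrix of preadjusted traits, rows aligned with
#'   `X`.
#' @param config an [mt_config()].
#' @return An object of class `mt_fit`: retained draws `beta1`, `beta2`
#'   (draws x SNPs), `d1`, `d2` (indicators), `R`, `Sigma` (draws x 3:
#'   the (1,1), (1,2), (2,2) elements), `pi`, `mu`, plus the resolved
#'   `prior`, the `config`, and dimensions `n`, `m`.
#' @export
fit_segment <- function(X, Y, config = mt_config()) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(inherits(config, "mt_config"))
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  if (ncol(Y) != 2) stop("Y must have exactly 2 trait columns", call. = FALSE)
  if (nrow(Y) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("non-finite values in X or Y (impute/complete-case upstream)",
         call. = FALSE)
  }
  rc <- resolve_config(config, X, Y)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(config$seed)
  draws <- .mt_gibbs_fit(X, Y, rc$init, rc$prior,
                         config$n_iter, config$burn_in, config$thin)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  out <- list(beta1 = draws$beta1, beta2 = draws$beta2,
              d1 = draws$d1, d2 = draws$d2,
              R = draws$R, Sigma = draws$Sigma, pi = draws$pi, mu = draws$mu,
              prior = rc$prior, config = config,
              n = nrow(X), m = ncol(X),
              snp_ids = colnames(X),
              trait_names = colnames(Y) %||% c("trait1", "trait2"))
  colnames(out$R) <- colnames(out$Sigma) <- c("v11", "v12", "v22")
  class(out) <- "mt_fit"
  out
}

#' @export
print.mt_fit <- function(x, ...) {
  cat("<mt_fit> segment with", x$m, "SNPs,", x$n, "individuals,",
      nrow(x$beta1), "retained draws\n")
  cat("  posterior mean pi:", format(colMeans(x$pi), digits = 3), "\n")
  cat("  posterior mean R :", format(colMeans(x$R), digits = 3),
      "(v11, v12, v22)\n")
  invisible(x)
}

#' Tidy per-SNP posterior summaries of a segment fit
#'
#' @param x an `mt_fit`.
#' @param ... unused.
#' @return A tibble with one row per (SNP, trait): `snp`, `snp_id`, `trait`,
#'   `estimate` (posterior mean effect), `std.error` (posterior SD), and
#'   `inclusion` (posterior inclusion probability).
#' @export
tidy.mt_fit <- function(x, ...) {
  ids <- x$snp_ids %||% paste0("snp_", seq_len(x$m))
  one <- function(B, D, k) {
    tibble::tibble(
      snp = seq_len(x$m), snp_id = ids, trait = x$trait_names[k],
      estimate = colMeans(B), std.error = apply(B, 2, sd),
      inclusion = colMeans(D)
    )
  }
  dplyr::bind_rows(one(x$beta1, x$d1, 1), one(x$beta2, x$d2, 2))
}

#' One-row summary of a segment fit
#'
#' @param x an `mt_fit`.
#' @param ... unused.
#' @return A tibble with `n`, `m`, `retained_draws`, posterior means of
#'   `pi_1`, `pi_2`, the residual correlation, and the slab correlation.
#' @export
glance.mt_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, m = x$m, retained_draws = nrow(x$beta1),
    pi_1 = mean(x$pi[, 1]), pi_2 = mean(x$pi[, 2]),
    resid_cor = mean(x$R[, "v12"] / sqrt(x$R[, "v11"] * x$R[, "v22"])),
    slab_cor = mean(x$Sigma[, "v12"] /
                      sqrt(x$Sigma[, "v11"] * x$Sigma[, "v22"]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
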