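#' Configuration for the bivariate spike-and-slab sampler
#'
#' Collects the chain settings and priors of the multitrait model
#' `Y = 1 mu' + X beta + E`. Per-SNP effect pairs get independent
#' spike-and-slab priors: a point mass at zero with per-trait inclusion
#' probabilities `pi = (pi_1, pi_2)` and a bivariate Gaussian slab
#' `N(0, Sigma)`. `R` (residual covariance) and `Sigma` (slab covariance)
#' get inverse-Wishart priors, `pi_k` Beta priors, and the intercepts a very
#' flat Gaussian prior so the joint model is proper.
#'
#' When a scale matrix is left `NULL` it is resolved from the data at fit
#' time: the `R` scale is set so the prior mode assigns half of each trait's
#' sample variance to the error term, and the `Sigma` scale so the slab's
#' implied genomic variance (prior expected active SNPs x mean dosage
#' variance x slab variance) covers the other half.
#'
#' @param n_iter total Gibbs iterations (default 5000).
#' @param burn_in discarded initial iterations (default 250).
#' @param thin keep-every interval (default 10); the defaults retain 475
#'   draws.
#' @param nu_R,nu_Sigma inverse-Wishart degrees of freedom (> 1; default 5).
#' @param S_R,S_Sigma 2x2 inverse-Wishart scale matrices, or `NULL` to
#'   resolve from the data as described above.
#' @param pi_a,pi_b Beta prior counts for each trait's inclusion
#'   probability; the defaults `a = 0.1, b = 9.9` put the prior mean at 0.01
#'   with the weight of 10 pseudo-observations. Length-1 values are recycled
#'   to both traits.
#' @param mu_var prior variance of each intercept, or `NULL` for
#'   `1e6 x mean trait variance` (effectively flat), resolved at fit time.
#' @param update_mu,update_R,update_Sigma,update_pi set to `FALSE` to hold a
#'   block fixed at its initial value (used for sampler validation, e.g. the
#'   conjugate-ridge limit with `update_R = update_Sigma = FALSE` and
#'   `pi_init = 1, update_pi = FALSE`).
#' @param R_init,Sigma_init,pi_init optional initial values; defaults are
#'   the sample covariance of `Y`, the prior mean `S_Sigma / (nu_Sigma - 3)`,
#'   and the Beta prior mean.
#' @param seed integer RNG seed used by [fit_segment()].
#' @return An object of class `mt_config` (a list of the above).
#' @export
mt_config <- function(n_iter = 5000, burn_in = 250, thin = 10,
                      nu_R = 5, S_R = NULL, nu_Sigma = 5, S_Sigma = NULL,
                      pi_a = 0.1, pi_b = 9.9, mu_var = NULL,
                      update_mu = TRUE, update_R = TRUE,
                      update_Sigma = TRUE, update_pi = TRUE,
                      R_init = NULL, Sigma_init = NULL, pi_init = NULL,
                      seed = 1L) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1,
            nu_R > 1, nu_Sigma > 1, all(pi_a > 0), all(pi_b > 0))
  cfg <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin),
              nu_R = nu_R, S_R = S_R, nu_Sigma = nu_Sigma, S_Sigma = S_Sigma,
              pi_a = rep_len(pi_a, 2), pi_b = rep_len(pi_b, 2),
              mu_var = mu_var,
              update_mu = update_mu, update_R = update_R,
              update_Sigma = update_Sigma, update_pi = update_pi,
              R_init = R_init, Sigma_init = Sigma_init, pi_init = pi_init,
              seed = as.integer(seed))
  class(cfg) <- "mt_config"
  cfg
}

#' Number of retained posterior draws
#'
#' With `n_iter` total iterations, the first `burn_in` discarded and every
#' `thin`-th kept thereafter, `floor((n_iter - burn_in) / thin)` draws are
#' retained; the default chain (5000, 250, 10) retains 475.
#'
#' @param n_iter,burn_in,thin chain settings.
#' @return Integer count of retained draws.
#' @export
retained_draw_count <- function(n_iter, burn_in, thin) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  as.integer((n_iter - burn_in) %/% thin)
}

#' Draw from the (R, Sigma, pi) priors
#'
#' Independent draws from the inverse-Wishart and Beta priors of an
#' [mt_config()], for prior-predictive checks and sampler validation.
#' The inverse-Wishart is drawn by inverting [stats::rWishart()] draws.
#'
#' @param config an [mt_config()] with explicit (non-`NULL`) scale matrices.
#' @param n_draws number of independent draws.
#' @return A list with `R`, `Sigma` (arrays `2 x 2 x n_draws`) and `pi`
#'   (`n_draws x 2`).
#' @export
sample_prior <- function(config, n_draws) {
  stopifnot(inherits(config, "mt_config"))
  if (is.null(config$S_R) || is.null(config$S_Sigma)) {
    stop("sample_prior needs explicit S_R and S_Sigma scale matrices",
         call. = FALSE)
  }
  riw <- function(nu, S, k) {
    W <- stats::rWishart(k, df = nu, Sigma = solve(S))
    array(apply(W, 3, solve), dim = c(2, 2, k))
  }
  if (config$nu_R <= 3 || config$nu_Sigma <= 3) {
    warning("inverse-Wishart df <= 3: prior mean does not exist; ",
            "moment-based checks are not meaningful", call. = FALSE)
  }
  list(
    R = riw(config$nu_R, config$S_R, n_draws),
    Sigma = riw(config$nu_Sigma, config$S_Sigma, n_draws),
    pi = cbind(rbeta(n_draws, config$pi_a[1], config$pi_b[1]),
               rbeta(n_draws, config$pi_a[2], config$pi_b[2]))
  )
}

# materialize data-dependent prior scales / inits; returns the prior list the
# C++ core consumes plus the resolved initial state
resolve_config <- function(config, X, Y) {
  n <- nrow(X)
  m <- ncol(X)
  vy <- apply(Y, 2, var)
  if (any(vy <= 0)) stop("degenerate trait with zero variance", call. = FALSE)
  mean_vx <- mean(colSums(X^2)) / max(n - 1, 1)
  S_R <- config$S_R
  if (is.null(S_R)) {
    # IW mode = S / (nu + p + 1); target mode 0.5 * diag(vy)
    S_R <- diag(0.5 * vy) * (config$nu_R + 3)
  }
  S_Sigma <- config$S_Sigma
  if (is.null(S_Sigma)) {
    exp_active <- max(m * config$pi_a[1] / (config$pi_a[1] + config$pi_b[1]), 1)
    target <- 0.5 * vy / (exp_active * max(mean_vx, 1e-8))
    S_Sigma <- diag(target) * (config$nu_Sigma + 3)
  }
  mu_var <- config$mu_var
  if (is.null(mu_var)) mu_var <- 1e6 * mean(vy)
  R_init <- config$R_init
  if (is.null(R_init)) R_init <- cov(Y)
  Sigma_init <- config$Sigma_init
  if (is.null(Sigma_init)) Sigma_init <- S_Sigma / max(config$nu_Sigma - 3, 0.5)
  pi_init <- config$pi_init
  if (is.null(pi_init)) pi_init <- config$pi_a / (config$pi_a + config$pi_b)
  pi_init <- rep_len(pi_init, 2)
  list(
    prior = list(nu_R = config$nu_R, S_R = S_R,
                 nu_Sigma = config$nu_Sigma, S_Sigma = S_Sigma,
                 pi_a = config$pi_a, pi_b = config$pi_b, mu_var = mu_var,
                 update_mu = config$update_mu, update_R = config$update_R,
                 update_Sigma = config$update_Sigma,
                 update_pi = config$update_pi),
    init = list(mu = colMeans(Y), b = matrix(0, m, 2),
                d = matrix(0L, m, 2), R = unname(R_init),
                Sigma = unname(Sigma_init), pi = pi_init)
  )
}
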