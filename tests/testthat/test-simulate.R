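test_that("genotype simulation is deterministic with block-local LD", {
  cfg <- sim_config(n_individuals = 300, n_snps = 60, block_length = 10,
                    within_block_rho = 0.9, causal_blocks = NULL, seed = 7)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% 0:2))
  expect_equal(ncol(p1$dosages), 60)
  expect_true(all(diff(p1$snp_map$pos) == cfg$bp_spacing))
  expect_equal(p1$snp_map$block, rep(1:6, each = 10))
})

test_that("within-block dosage correlation tracks the latent AR(1) level", {
  base <- list(n_individuals = 10000, n_snps = 40, block_length = 10,
               causal_blocks = NULL, seed = 3)
  mean_adj_cor <- function(rho, cross = FALSE) {
    cfg <- do.call(sim_config, c(base, list(within_block_rho = rho)))
    X <- impute_center(simulate_genotypes(cfg))
    blocks <- rep(1:4, each = 10)
    pairs <- cbind(1:39, 2:40)
    same <- blocks[pairs[, 1]] == blocks[pairs[, 2]]
    use <- if (cross) !same else same
    mean(abs(apply(pairs[use, ], 1, function(ij) cor(X[, ij[1]], X[, ij[2]]))))
  }
  # rho = 0: adjacent SNPs essentially uncorrelated at n = 10,000
  expect_lt(mean_adj_cor(0), 0.05)
  # rho = 0.9: within-block LD clearly exceeds cross-block correlation
  expect_gt(mean_adj_cor(0.9), mean_adj_cor(0.9, cross = TRUE) + 0.2)
  expect_gt(mean_adj_cor(0.9), 0.3)
})

test_that("trait simulation plants effects with exact bookkeeping", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 80, block_length = 10,
                    within_block_rho = 0.8,
                    causal_blocks = list(list(
                      block = 4, n_causal = 6,
                      Sigma_loc = 0.05 * matrix(c(1, 0.8, 0.8, 1), 2))),
                    seed = 11)
  panel <- simulate_genotypes(cfg)
  st <- simulate_traits(panel, cfg)
  X <- impute_center(panel)
  # truth and data never disagree: Y - E == X beta exactly
  expect_equal(unname(st$Y - st$truth$E), unname(X %*% st$truth$beta),
               tolerance = 1e-12)
  expect_lt(max(abs(colMeans(st$Y))), 1e-10)
  expect_true(all(st$truth$causal %in% which(panel$snp_map$block == 4)))
  expect_equal(sum(rowSums(st$truth$beta != 0) > 0), 6)

  # realized genetic score covariance matches the stored-beta quadratic form
  g1 <- X %*% st$truth$beta[, 1]
  g2 <- X %*% st$truth$beta[, 2]
  tw <- true_window_cov(X, st$truth, 31, 40)
  full <- true_window_cov(X, st$truth, 1, 80)
  expect_equal(cov(g1[, 1], g2[, 1]), full$cov, tolerance = 1e-12)
  # causal block dominates the genome-wide genetic covariance
  expect_gt(abs(tw$cov), 0)

  # single causal SNP closed form
  cfg1 <- sim_config(n_individuals = 400, n_snps = 20, block_length = 5,
                     causal_blocks = list(list(
                       block = 2, n_causal = 1,
                       Sigma_loc = 0.1 * diag(2) + 0.05)),
                     seed = 12)
  pan1 <- simulate_genotypes(cfg1)
  st1 <- simulate_traits(pan1, cfg1)
  X1 <- impute_center(pan1)
  j <- st1$truth$causal
  tw1 <- true_window_cov(X1, st1$truth, j, j)
  expect_equal(tw1$cov,
               st1$truth$beta[j, 1] * st1$truth$beta[j, 2] * var(X1[, j]))
  # window with no causal SNPs -> exact zeros
  expect_equal(unlist(true_window_cov(X1, st1$truth, 16, 20)),
               c(v1 = 0, v2 = 0, cov = 0))
})

test_that("null simulation reproduces the residual covariance", {
  cfg <- sim_config(n_individuals = 4000, n_snps = 30, block_length = 10,
                    causal_blocks = NULL,
                    R_true = matrix(c(1, 0.3, 0.3, 1), 2), seed = 13)
  st <- simulate_traits(simulate_genotypes(cfg), cfg)
  expect_true(all(st$truth$beta == 0))
  expect_equal(cov(st$Y)[1, 2], 0.3, tolerance = 3 / sqrt(4000))
})

test_that("invalid causal specifications error", {
  cfg <- sim_config(n_snps = 20, block_length = 10,
                    causal_blocks = list(list(block = 1, n_causal = 15,
                                              Sigma_loc = diag(2))))
  panel <- simulate_genotypes(sim_config(n_snps = 20, block_length = 10,
                                         causal_blocks = NULL))
  expect_error(simulate_traits(panel, cfg), "exceeds block size")
  cfg2 <- sim_config(n_snps = 20, block_length = 10,
                     causal_blocks = list(list(block = 9, n_causal = 1,
                                               Sigma_loc = diag(2))))
  expect_error(simulate_traits(panel, cfg2), "does not exist")
})

test_that("simulated panels export through the PLINK writer unchanged", {
  cfg <- sim_config(n_individuals = 25, n_snps = 12, block_length = 4,
                    causal_blocks = NULL, seed = 21)
  panel <- simulate_genotypes(cfg)
  pref <- file.path(withr::local_tempdir(), "sim")
  write_plink(panel, pref)
  back <- read_plink(pref)
  expect_identical(unname(back$dosages), unname(panel$dosages))
})
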