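test_that("retained draw count follows burn-in and thinning", {
  expect_identical(retained_draw_count(5000, 250, 10), 475L)
  expect_identical(retained_draw_count(100, 0, 1), 100L)
  # explicit loop oracle
  kept <- 0L
  for (it in 1:1000) if (it > 200 && (it - 200) %% 7 == 0) kept <- kept + 1L
  expect_identical(retained_draw_count(1000, 200, 7), kept)
  expect_error(retained_draw_count(100, 100, 1), "exceed")
  expect_error(retained_draw_count(100, 0, 0), ">= 1")
  # the fitted object honours the same bookkeeping
  set.seed(1)
  f <- fit_segment(matrix(rnorm(60), 20, 3), matrix(rnorm(40), 20, 2),
                   mt_config(n_iter = 123, burn_in = 20, thin = 4))
  expect_equal(nrow(f$beta1), retained_draw_count(123, 20, 4))
})

test_that("sample_prior matches analytic Beta and inverse-Wishart moments", {
  cfg <- mt_config(nu_R = 6, S_R = diag(2), nu_Sigma = 6, S_Sigma = 2 * diag(2),
                   pi_a = 1, pi_b = 1)
  set.seed(2)
  d <- sample_prior(cfg, 4000)
  # Beta(1,1): mean 1/2
  expect_lt(abs(mean(d$pi) - 0.5), 3 * sd(d$pi) / sqrt(length(d$pi)))
  # IW(6, I) mean = I/(6 - 2 - 1)
  m11 <- d$R[1, 1, ]
  expect_lt(abs(mean(m11) - 1 / 3), 3 * sd(m11) / sqrt(length(m11)))
  expect_lt(abs(mean(d$R[1, 2, ])), 3 * sd(d$R[1, 2, ]) / sqrt(4000))
  m22 <- d$Sigma[2, 2, ]
  expect_lt(abs(mean(m22) - 2 / 3), 3 * sd(m22) / sqrt(length(m22)))
  # determinism under a fixed seed
  set.seed(9); a <- sample_prior(cfg, 5)
  set.seed(9); b <- sample_prior(cfg, 5)
  expect_identical(a, b)
  expect_warning(sample_prior(mt_config(nu_R = 2, S_R = diag(2),
                                        S_Sigma = diag(2)), 2),
                 "df <= 3")
})

test_that("chains are bit-reproducible and leave the global RNG intact", {
  set.seed(50)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- matrix(rnorm(80), 40, 2)
  f1 <- fit_segment(X, Y, fast_cfg(seed = 77))
  set.seed(123)
  nxt <- rnorm(1)
  set.seed(123)
  f2 <- fit_segment(X, Y, fast_cfg(seed = 77))
  expect_identical(f1$beta1, f2$beta1)
  expect_identical(f1$R, f2$R)
  expect_identical(f1$pi, f2$pi)
  expect_equal(rnorm(1), nxt)  # caller's RNG stream restored
  f3 <- fit_segment(X, Y, fast_cfg(seed = 78))
  expect_false(identical(f1$beta1, f3$beta1))
})

test_that("posterior draws respect the spike-and-slab structure", {
  set.seed(51)
  X <- matrix(rnorm(60 * 8), 60, 8)
  b <- matrix(0, 8, 2); b[2, ] <- c(0.8, 0.7)
  Y <- X %*% b + matrix(rnorm(120), 60, 2) * 0.6
  f <- fit_segment(X, Y, mt_config(n_iter = 600, burn_in = 100, thin = 2,
                                   seed = 5))
  # beta is zero exactly when its indicator is zero
  expect_true(all((f$beta1 == 0) == (f$d1 == 0)))
  expect_true(all((f$beta2 == 0) == (f$d2 == 0)))
  # R and Sigma draws are valid covariances (pd), pi in (0,1)
  expect_true(all(f$R[, "v11"] > 0 & f$R[, "v22"] > 0))
  expect_true(all(f$R[, "v12"]^2 < f$R[, "v11"] * f$R[, "v22"]))
  expect_true(all(f$Sigma[, "v12"]^2 < f$Sigma[, "v11"] * f$Sigma[, "v22"]))
  expect_true(all(f$pi > 0 & f$pi < 1))
  # the planted SNP is found
  expect_gt(mean(f$d1[, 2]), 0.95)
})

test_that("null data pulls the inclusion probabilities below their prior mean", {
  set.seed(52)
  n <- 500; m <- 50
  X <- matrix(rnorm(n * m), n, m)
  Y <- matrix(rnorm(2 * n), n, 2)
  f <- fit_segment(X, Y, mt_config(n_iter = 800, burn_in = 150, thin = 2,
                                   seed = 6))
  prior_mean <- 0.1 / (0.1 + 9.9)
  expect_lt(mean(f$pi[, 1]), prior_mean)
  expect_lt(mean(f$pi[, 2]), prior_mean)
  # per-SNP inclusion has no systematic excess over the pi draws
  expect_lt(mean(f$d1), mean(f$pi[, 1]) + 3 * sd(rowMeans(f$d1)) / sqrt(nrow(f$d1)))
})

test_that("duplicated traits drive the residual correlation toward 1", {
  set.seed(53)
  X <- matrix(rnorm(80 * 5), 80, 5)
  y <- X[, 3] * 0.5 + rnorm(80)
  Y <- cbind(y, y)
  f <- fit_segment(X, Y, mt_config(n_iter = 600, burn_in = 100, thin = 2,
                                   seed = 7))
  rc <- f$R[, "v12"] / sqrt(f$R[, "v11"] * f$R[, "v22"])
  expect_gt(mean(rc), 0.9)
  # effect estimates agree across the two identical traits
  expect_equal(colMeans(f$beta1), colMeans(f$beta2), tolerance = 0.05)
})

test_that("swapping trait columns swaps every posterior summary", {
  set.seed(54)
  X <- matrix(rnorm(120 * 6), 120, 6)
  b <- matrix(0, 6, 2); b[4, ] <- c(0.9, -0.5)
  Y <- X %*% b + matrix(rnorm(240), 120, 2) * 0.5
  cfg <- mt_config(n_iter = 1500, burn_in = 300, thin = 2, seed = 8)
  f <- fit_segment(X, Y, cfg)
  g <- fit_segment(X, Y[, 2:1], cfg)
  expect_equal(colMeans(f$beta1), colMeans(g$beta2), tolerance = 0.06)
  expect_equal(colMeans(f$beta2), colMeans(g$beta1), tolerance = 0.06)
  expect_equal(mean(f$pi[, 1]), mean(g$pi[, 2]), tolerance = 0.05)
  expect_equal(mean(f$R[, "v11"]), mean(g$R[, "v22"]), tolerance = 0.06)
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_segment(X, matrix(1, 10, 2), fast_cfg()), "zero variance")
  expect_error(fit_segment(X, matrix(rnorm(30), 10, 3), fast_cfg()),
               "2 trait columns")
  expect_error(fit_segment(X[1:2, ], matrix(rnorm(4), 2, 2), fast_cfg()),
               "at least 3")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(fit_segment(Xbad, matrix(rnorm(20), 10, 2), fast_cfg()),
               "non-finite")
})
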