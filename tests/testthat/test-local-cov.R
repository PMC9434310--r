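test_that("single-SNP and degenerate windows reduce to closed forms", {
  set.seed(31)
  x <- matrix(rnorm(80), ncol = 1)
  b1 <- matrix(rnorm(20), 20, 1)
  b2 <- matrix(rnorm(20), 20, 1)
  d <- window_cov_draws(x, b1, b2)
  expect_equal(d$cov, b1[, 1] * b2[, 1] * var(x[, 1]))
  expect_equal(d$v1, b1[, 1]^2 * var(x[, 1]))

  # identical effect vectors: Cov = V1 = V2 per draw
  X <- matrix(rnorm(300), 60, 5)
  B <- matrix(rnorm(50), 10, 5)
  dd <- window_cov_draws(X, B, B)
  expect_equal(dd$cov, dd$v1)
  expect_equal(dd$cov, dd$v2)
})

test_that("quadratic-form route equals the score-vector route", {
  set.seed(32)
  X <- matrix(rnorm(70 * 5), 70, 5)
  B1 <- matrix(rnorm(100), 20, 5)
  B2 <- matrix(rnorm(100), 20, 5)
  d <- window_cov_draws(X, B1, B2)
  for (s in 1:20) {
    g1 <- X %*% B1[s, ]
    g2 <- X %*% B2[s, ]
    expect_equal(d$v1[s], var(g1[, 1]), tolerance = 1e-10)
    expect_equal(d$v2[s], var(g2[, 1]), tolerance = 1e-10)
    expect_equal(d$cov[s], cov(g1[, 1], g2[, 1]), tolerance = 1e-10)
  }
  expect_error(window_cov_draws(X, B1[, 1:3], B2), "do not match")
})

test_that("every draw satisfies Cauchy-Schwarz |Cov| <= sqrt(V1 V2)", {
  set.seed(33)
  for (rep in 1:20) {
    X <- matrix(rnorm(50 * 4), 50, 4)
    d <- window_cov_draws(X, matrix(rnorm(60), 15, 4),
                          matrix(rnorm(60), 15, 4))
    expect_true(all(abs(d$cov) <= sqrt(d$v1 * d$v2) + 1e-12))
    expect_true(all(d$v1 >= 0 & d$v2 >= 0))
  }
})

test_that("(co)variances are scale-equivariant in the traits", {
  # scaling a trait scales its effect draws; V ~ c^2, Cov ~ c
  set.seed(34)
  X <- matrix(rnorm(200), 40, 5)
  B1 <- matrix(rnorm(25), 5, 5)
  B2 <- matrix(rnorm(25), 5, 5)
  base <- window_cov_draws(X, B1, B2)
  both <- window_cov_draws(X, 3 * B1, 3 * B2)
  one <- window_cov_draws(X, 3 * B1, B2)
  expect_equal(both$v1, 9 * base$v1)
  expect_equal(both$cov, 9 * base$cov)
  expect_equal(one$cov, 3 * base$cov)
  expect_equal(one$v1, 9 * base$v1)
  expect_equal(one$v2, base$v2)
})

test_that("summarize_window computes equal-tailed CRs and the exclusion rule", {
  d <- tibble::tibble(v1 = (1:100)^2 / 100, v2 = rep(1, 100), cov = 1:100)
  s <- summarize_window(d)
  # type-7 empirical quantiles of 1..100 at 2.5% / 97.5%
  expect_equal(s$cov_lo, 3.475)
  expect_equal(s$cov_hi, 97.525)
  expect_equal(s$cov_mean, 50.5)
  expect_true(s$significant)  # all draws positive -> cr_low > 0

  z <- tibble::tibble(v1 = rep(0, 10), v2 = rep(0, 10), cov = rep(0, 10))
  sz <- summarize_window(z)
  expect_equal(c(sz$cov_lo, sz$cov_hi), c(0, 0))
  expect_false(sz$significant)  # CR touching zero does not exclude it

  neg <- tibble::tibble(v1 = 1:50, v2 = 1:50, cov = -(1:50))
  expect_true(summarize_window(neg)$significant)
  expect_error(summarize_window(d[1, ]), "at least 2")
  d$cov[5] <- NaN
  expect_error(summarize_window(d), "non-finite")
})

test_that("locus condensation matches a union-find reference", {
  mk <- function(starts, ends, chrom = rep(1L, length(starts))) {
    k <- length(starts)
    tibble::tibble(
      window = seq_len(k), chrom = chrom, start_idx = starts,
      end_idx = ends, bp_start = starts * 1000L, bp_end = ends * 1000L,
      cov_mean = seq_len(k) * rep_len(c(1, -1), k), cov_lo = 1, cov_hi = 2,
      significant = TRUE)
  }
  # disjoint -> two loci; chained A-B, B-C -> one locus
  expect_equal(nrow(merge_significant_windows(mk(c(1, 10), c(3, 12)))), 2)
  chained <- merge_significant_windows(mk(c(1, 3, 5), c(3, 6, 9)))
  expect_equal(nrow(chained), 1)
  expect_equal(chained$n_windows, 3)
  # same indices on different chromosomes never merge
  expect_equal(nrow(merge_significant_windows(
    mk(c(1, 1), c(5, 5), chrom = c(1L, 2L)))), 2)

  set.seed(36)
  for (rep in 1:5) {
    k <- 50
    starts <- sample(1:400, k)
    ends <- starts + sample(0:30, k, replace = TRUE)
    chrom <- sample(1:3, k, replace = TRUE)
    got <- merge_significant_windows(mk(starts, ends, chrom))
    ref <- oracle_merge(starts, ends, chrom)
    expect_equal(nrow(got), length(unique(ref)))
    # each reference class maps into exactly one produced locus span
    for (cl in unique(ref)) {
      i <- which(ref == cl)
      hit <- got$chrom == chrom[i[1]] & got$start_idx <= min(starts[i]) &
        got$end_idx >= max(ends[i])
      expect_equal(sum(hit), 1)
    }
  }

  # representative window carries the largest |cov| and its direction
  rep_check <- merge_significant_windows(mk(c(1, 3), c(4, 6)))
  expect_equal(rep_check$rep_window, 2)
  expect_equal(rep_check$direction, -1)
  expect_equal(nrow(merge_significant_windows(mk(integer(0), integer(0)))), 0)
})

test_that("write_results scales by 1e4 and round-trips to print precision", {
  est <- tibble::tibble(
    window = 1:2, chrom = c(2L, 3L), start_idx = c(1L, 9L),
    end_idx = c(4L, 9L), n_snps = c(4L, 1L), bp_start = c(100L, 900L),
    bp_end = c(400L, 900L), first_id = c("rs1", "rs9"),
    last_id = c("rs4", "rs9"), seed_id = c("rs2", "rs9"),
    v1_mean = c(1.2e-4, 3e-5), v1_sd = c(1e-5, 2e-6),
    v1_lo = c(1e-4, 2e-5), v1_hi = c(1.4e-4, 4e-5),
    v2_mean = c(2e-4, 1e-5), v2_sd = c(1e-5, 1e-6),
    v2_lo = c(1.8e-4, 8e-6), v2_hi = c(2.2e-4, 1.2e-5),
    cov_mean = c(6.42e-4, -9e-6), cov_sd = c(5e-5, 3e-6),
    cov_lo = c(5.45e-4, -1.5e-5), cov_hi = c(7.65e-4, -4e-6),
    significant = c(TRUE, TRUE))
  loci <- merge_significant_windows(est)
  dir <- withr::local_tempdir()
  paths <- write_results(est, loci, dir)
  win <- read_results_tsv(paths[["windows"]])
  expect_equal(win$cov_mean, c(6.42, -0.09))  # 6.42e-4 prints as 6.42
  expect_equal(win$cov_lo, c(5.45, -0.15))
  expect_equal(win$v1_mean, signif(est$v1_mean * 1e4, 6))
  expect_equal(win$significant, est$significant)
  lr <- read_results_tsv(paths[["loci"]])
  expect_equal(nrow(lr), 2)
  expect_equal(lr$cov_mean, signif(loci$cov_mean * 1e4, 6))

  # empty significant set -> loci file with header only
  paths2 <- write_results(est, merge_significant_windows(est[0, ]), dir)
  expect_equal(nrow(read_results_tsv(paths2[["loci"]])), 0)
})
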