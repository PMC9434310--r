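# shared fixtures and independent reference implementations

# build a genotype_panel from a raw dosage matrix
make_panel <- function(dos, chrom = NULL, pos = NULL) {
  p <- ncol(dos)
  if (is.null(chrom)) chrom <- rep(1L, p)
  if (is.null(pos)) {
    pos <- stats::ave(seq_len(p), chrom, FUN = seq_along) * 1000L
  }
  genotype_panel(dos, tibble::tibble(
    id = paste0("rs", seq_len(p)), chrom = as.integer(chrom),
    pos = as.integer(pos), a1 = "A", a2 = "B"))
}

# random raw dosage panel with planted per-SNP MAF and missingness
random_raw_panel <- function(n, p, maf = NULL, miss = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.005, 0.5)
  if (is.null(miss)) miss <- runif(p, 0, 0.12)
  dos <- sapply(seq_len(p), function(j) {
    x <- rbinom(n, 2, maf[j])
    x[runif(n) < miss[j]] <- NA
    x
  })
  make_panel(dos)
}

# LD-window reference: compute the full pass/fail vector per direction, then
# keep candidates up to the last pass occurring before two consecutive fails
oracle_window <- function(X, segment, seed, threshold = 0.1) {
  one_dir <- function(cands) {
    if (length(cands) == 0) return(integer(0))
    pass <- vapply(cands, function(j) {
      si <- stats::sd(X[, seed]); sj <- stats::sd(X[, j])
      r <- if (si < 1e-12 || sj < 1e-12) 0 else stats::cor(X[, seed], X[, j])
      abs(r) >= threshold
    }, logical(1))
    stop_at <- length(cands) + 1L
    if (length(cands) >= 2) {
      ff <- which(!pass[-length(cands)] & !pass[-1])
      if (length(ff) > 0) stop_at <- ff[1]
    }
    keep_through <- which(pass[seq_len(min(stop_at, length(cands)))])
    if (length(keep_through) == 0) return(integer(0))
    cands[seq_len(max(keep_through))]
  }
  left <- if (seed > segment$flank_start)
    one_dir(seq.int(seed - 1L, segment$flank_start)) else integer(0)
  right <- if (seed < segment$flank_end)
    one_dir(seq.int(seed + 1L, segment$flank_end)) else integer(0)
  sort(c(left, seed, right))
}

# generic union-find partition of windows by shared-member transitive closure
oracle_merge <- function(starts, ends, chrom) {
  k <- length(starts)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && chrom[i] == chrom[j] &&
        max(starts[i], starts[j]) <= min(ends[i], ends[j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(k), find, integer(1))
}

# correlated-column toy panel: column j built from a seed vector with given
# target correlation by mixing in independent noise
correlated_columns <- function(n, r_targets, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  cbind(z, sapply(r_targets, function(r) {
    if (abs(r) < 1e-12) return(rnorm(n))
    sign(r) * (abs(r) * z + sqrt(1 - r^2) * rnorm(n))
  }))
}

fast_cfg <- function(...) mt_config(n_iter = 400, burn_in = 100, thin = 3, ...)
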