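#' Pipeline configuration
#'
#' Aggregates every setting of a discovery run. Exactly one of
#' `simulate` (a [sim_config()]) or `paths` (a list with `plink_prefix`,
#' `pheno`, `covar`; delimited tables with a header and a `sample_id`
#' column) must be supplied.
#'
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param paths list of input paths (see above), or `NULL` when simulating.
#' @param maf_min,miss_max QC thresholds passed to [qc_filter()].
#' @param core_size,flank_size segmentation sizes for [make_segments()].
#' @param model an [mt_config()]; its `seed` is overridden per segment by a
#'   deterministic child seed derived from `seed` and the segment's
#'   (chromosome, core start), so serial and per-segment-parallel runs
#'   agree and adding segments never perturbs other chains.
#' @param ld_threshold LD window threshold (default 0.1).
#' @param level credible level (default 0.95).
#' @param log_transform log-transform raw traits before preadjustment
#'   (file inputs only).
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            maf_min = 0.01, miss_max = 0.05,
                            core_size = 1000, flank_size = 250,
                            model = mt_config(), ld_threshold = 0.1,
                            level = 0.95, log_transform = TRUE,
                            out_dir = tempfile("localcov_run_"),
                            seed = 1L) {
  if (is.null(simulate) == is.null(paths)) {
    stop("supply exactly one of `simulate` or `paths`", call. = FALSE)
  }
  structure(list(simulate = simulate, paths = paths, maf_min = maf_min,
                 miss_max = miss_max, core_size = core_size,
                 flank_size = flank_size, model = model,
                 ld_threshold = ld_threshold, level = level,
                 log_transform = log_transform, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic child seed from (global seed, chromosome, core start);
# kept below 2^31 so it is a valid R integer seed
segment_seed <- function(global_seed, chrom, core_start) {
  h <- (as.double(global_seed) * 2654435761 + as.double(chrom) * 40503 +
          as.double(core_start) * 2246822519) %% 2147483647
  as.integer(h)
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    panel <- simulate_genotypes(sc)
    st <- simulate_traits(panel, sc)
    list(panel = panel, Y = st$Y, truth = st$truth)
  } else {
    p <- config$paths
    panel <- read_plink(p$plink_prefix)
    ph <- readr::read_tsv(p$pheno, show_col_types = FALSE)
    cv <- if (!is.null(p$covar)) readr::read_tsv(p$covar,
                                                 show_col_types = FALSE)
    ids <- panel$sample_ids
    ph <- ph[stats::complete.cases(ph), ]
    keep <- intersect(ids, ph$sample_id)
    if (!is.null(cv)) {
      cv <- cv[stats::complete.cases(cv), ]
      keep <- intersect(keep, cv$sample_id)
    }
    message("sample alignment: ", length(keep), " individuals in common")
    panel <- genotype_panel(panel$dosages[match(keep, ids), , drop = FALSE],
                            panel$snp_map, sample_ids = keep)
    raw <- as.matrix(ph[match(keep, ph$sample_id),
                        setdiff(names(ph), "sample_id")][, 1:2])
    Z <- if (!is.null(cv)) {
      as.matrix(cv[match(keep, cv$sample_id), setdiff(names(cv), "sample_id")])
    }
    Y <- preadjust_traits(raw, Z, log_transform = config$log_transform)
    list(panel = panel, Y = Y, truth = NULL)
  }
}

fit_all_segments <- function(X, Y, segments, model, global_seed) {
  fits <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    seg <- segments[s, ]
    cfg <- model
    cfg$seed <- segment_seed(global_seed, seg$chrom, seg$core_start)
    t0 <- Sys.time()
    fits[[seg$segment]] <- fit_segment(
      X[, seg$flank_start:seg$flank_end, drop = FALSE], Y, cfg)
    message(sprintf(
      "segment %d (chrom %d, core %d-%d): fit %d SNPs in %.1fs",
      seg$segment, seg$chrom, seg$core_start, seg$core_end, seg$n_total,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  fits
}

#' Run the full local-(co)variance discovery pipeline
#'
#' Executes input loading (or simulation), QC, imputation/centering,
#' segmentation, the per-segment spike-and-slab fits, LD-window
#' construction, window (co)variance estimation, significance calls, and
#' locus condensation; writes the window and locus TSVs, a windows BED, the
#' per-segment posterior draws, and a machine-readable JSON manifest of the
#' stage counts to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param keep_fits keep the segment fits in the returned object
#'   (default `TRUE`; they are always saved to disk).
#' @return Invisibly, a list with `panel`, `Y`, `X`, `segments`, `windows`,
#'   `estimates`, `loci`, `manifest`, `truth` (simulation only), `fits`
#'   (if kept), and the written `paths`.
#' @export
run_discovery <- function(config, keep_fits = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- load_inputs(config)
  panel <- qc_filter(inp$panel, config$maf_min, config$miss_max)
  X <- impute_center(panel)
  segments <- make_segments(panel, config$core_size, config$flank_size)
  fits <- fit_all_segments(X, inp$Y, segments, config$model, config$seed)
  windows <- enumerate_windows(X, panel, segments, config$ld_threshold)
  estimates <- estimate_windows(windows, X, fits, segments, config$level)
  sig <- estimates[estimates$significant, ]
  loci <- merge_significant_windows(sig)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_results(estimates, loci, config$out_dir)
  write_windows_bed(windows, panel, file.path(config$out_dir, "windows.bed"),
                    file.path(config$out_dir, "window_members.tsv"))
  saveRDS(fits, file.path(config$out_dir, "segment_fits.rds"))
  wc <- attr(windows, "window_counts")
  manifest <- list(
    n_individuals = nrow(panel$dosages),
    snps_input = ncol(inp$panel$dosages),
    snps_kept = ncol(panel$dosages),
    n_segments = nrow(segments),
    windows_raw = unname(wc["raw"]),
    windows_dedup = unname(wc["dedup"]),
    windows_significant = sum(estimates$significant),
    n_loci = nrow(loci),
    retained_draws = retained_draw_count(config$model$n_iter,
                                         config$model$burn_in,
                                         config$model$thin),
    ld_threshold = config$ld_threshold,
    level = config$level,
    seed = config$seed,
    dosage_coding = "count of A1 allele, mean-imputed, centered, unscaled",
    cov_scale_in_tsv = 1e4
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(panel = panel, Y = inp$Y, X = X, segments = segments,
              windows = windows, estimates = estimates, loci = loci,
              manifest = manifest, truth = inp$truth, paths = paths)
  if (keep_fits) out$fits <- fits
  invisible(out)
}

#' Re-run estimation on a second cohort with frozen discovery windows
#'
#' Refits the segment models on a validation cohort but evaluates the
#' (co)variances on the exact window member sets of a prior discovery run
#' (matched by first/last member SNP identifier), then reports which
#' discovery-significant windows replicate: significant in the validation
#' cohort with the same covariance sign.
#'
#' @param config a [pipeline_config()] describing the validation cohort.
#' @param frozen_windows the discovery `windows.tsv` path, or the discovery
#'   windows/estimates tibble itself.
#' @return Invisibly, a list with `estimates` (frozen windows evaluated on
#'   the validation cohort, plus `replicated` for discovery-significant
#'   windows), `discovery` (the frozen table), and `manifest`.
#' @export
run_validation <- function(config, frozen_windows) {
  stopifnot(inherits(config, "pipeline_config"))
  disc <- if (is.character(frozen_windows)) {
    read_results_tsv(frozen_windows)
  } else {
    frozen_windows
  }
  inp <- load_inputs(config)
  panel <- qc_filter(inp$panel, config$maf_min, config$miss_max)
  unknown <- setdiff(unique(c(disc$first_id, disc$last_id)),
                     panel$snp_map$id)
  if (length(unknown) > 0) {
    stop("frozen windows reference SNPs absent from the validation panel: ",
         paste(head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  X <- impute_center(panel)
  segments <- make_segments(panel, config$core_size, config$flank_size)
  fits <- fit_all_segments(X, inp$Y, segments, config$model, config$seed)
  idx <- match(disc$first_id, panel$snp_map$id)
  edx <- match(disc$last_id, panel$snp_map$id)
  win <- tibble::tibble(
    window = disc$window, chrom = disc$chrom,
    start_idx = idx, end_idx = edx,
    n_snps = edx - idx + 1L,
    segment = findInterval(idx, segments$flank_start)
  )
  # a frozen window must sit inside one refitted segment
  win$segment <- vapply(seq_len(nrow(win)), function(i) {
    s <- which(segments$flank_start <= win$start_idx[i] &
                 segments$flank_end >= win$end_idx[i])
    if (length(s) == 0) stop("frozen window ", win$window[i],
                             " spans no validation segment", call. = FALSE)
    s[1]
  }, integer(1))
  win$bp_start <- panel$snp_map$pos[win$start_idx]
  win$bp_end <- panel$snp_map$pos[win$end_idx]
  est <- estimate_windows(win, X, fits, segments, config$level)
  disc_sig <- if ("significant" %in% names(disc)) disc$significant else TRUE
  disc_sign <- if ("cov_mean" %in% names(disc)) sign(disc$cov_mean) else NA
  est$discovery_significant <- disc_sig
  est$replicated <- disc_sig & est$significant &
    sign(est$cov_mean) == disc_sign
  manifest <- list(n_windows = nrow(est),
                   discovery_significant = sum(disc_sig),
                   replicated = sum(est$replicated))
  invisible(list(estimates = est, discovery = disc, manifest = manifest))
}
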