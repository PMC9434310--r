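#' Read a PLINK 1 bed/bim/fam fileset
#'
#' Reads the binary SNP-major `.bed` payload together with its `.bim` SNP map
#' and `.fam` sample table into a [genotype_panel()]. Dosages are counts of
#' the bim A1 allele: the 2-bit codes `00 / 10 / 11` decode to 2 / 1 / 0
#' copies of A1 and `01` to missing. (Co)variance magnitudes downstream are
#' orientation-invariant, but effect signs follow this A1 convention.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must all exist.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss) > 0) {
    stop("missing PLINK file(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam)
  p <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", paths[1], call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major bed files are supported", call. = FALSE)
  }
  bps <- ceiling(n / 4)
  if (length(raw) - 3L != bps * p) {
    stop("bed payload size (", length(raw) - 3L, " bytes) inconsistent with ",
         n, " individuals x ", p, " SNPs from fam/bim", call. = FALSE)
  }
  payload <- as.integer(raw[-(1:3)])
  # 2-bit genotypes, individual-minor within each SNP's byte block
  codes <- matrix(NA_integer_, 4 * bps, p)
  blk <- matrix(payload, bps, p)
  for (s in 0:3) {
    codes[seq.int(s + 1, 4 * bps, by = 4), ] <-
      bitwAnd(bitwShiftR(blk, 2 * s), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies A1, 10 -> 1, 11 -> 0, 01 -> missing
  lut <- c(2, NA_real_, 1, 0)
  dos <- matrix(lut[codes + 1L], n, p)
  snp_map <- tibble::tibble(id = as.character(bim$id),
                            chrom = as.integer(bim$chrom),
                            pos = as.integer(bim$pos),
                            a1 = as.character(bim$a1),
                            a2 = as.character(bim$a2))
  genotype_panel(dos, snp_map, sample_ids = as.character(fam$V2))
}

#' Write a genotype panel as PLINK 1 bed/bim/fam
#'
#' Inverse of [read_plink()]; dosages must still be raw allele counts
#' (\{0, 1, 2, NA\}). Used by the simulator so its panels can feed any
#' PLINK-consuming tool unchanged.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- panel$dosages
  if (any(!is.na(G) & !(G %in% c(0, 1, 2)))) {
    stop("write_plink needs raw {0,1,2,NA} dosages (write before imputing)",
         call. = FALSE)
  }
  n <- nrow(G)
  p <- ncol(G)
  sm <- panel$snp_map
  a1 <- if ("a1" %in% names(sm)) sm$a1 else rep("A", p)
  a2 <- if ("a2" %in% names(sm)) sm$a2 else rep("B", p)
  utils::write.table(
    data.frame(sm$chrom, sm$id, 0, sm$pos, a1, a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code
  code <- matrix(1L, n, p)  # missing
  code[!is.na(G) & G == 2] <- 0L
  code[!is.na(G) & G == 1] <- 2L
  code[!is.na(G) & G == 0] <- 3L
  bps <- ceiling(n / 4)
  padded <- matrix(3L, 4 * bps, p)  # pad codes are ignored on read
  padded[seq_len(n), ] <- code
  bytes <- matrix(0L, bps, p)
  for (s in 0:3) {
    bytes <- bytes + bitwShiftL(padded[seq.int(s + 1, 4 * bps, by = 4), ,
                                       drop = FALSE], 2 * s)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
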