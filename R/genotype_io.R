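# PLINK 1 binary genotype I/O and column standardization.
#
# The .bed codec follows the PLINK 1 specification: magic bytes 0x6C 0x1B,
# mode byte 0x01 (SNP-major), 2 bits per sample per SNP packed low-to-high
# within each byte, each SNP's block padded to a whole byte.  Two-bit codes
# (counting A1 copies): 00 = 2, 01 = missing, 10 = 1, 11 = 0.

# 256 x 4 lookup: dosage of field k (low-to-high) in byte value v.
.bed_lut <- local({
  map <- c(2L, NA_integer_, 1L, 0L)  # code 0,1,2,3
  v <- 0:255
  cbind(map[bitwAnd(v, 3L) + 1L],
        map[bitwAnd(bitwShiftR(v, 2L), 3L) + 1L],
        map[bitwAnd(bitwShiftR(v, 4L), 3L) + 1L],
        map[bitwAnd(bitwShiftR(v, 6L), 3L) + 1L])
})

new_genotype_panel <- function(calls, samples, snps) {
  stopifnot(is.matrix(calls), nrow(samples) == nrow(calls),
            nrow(snps) == ncol(calls))
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique within a panel")
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_panel")
}

#' Read a PLINK 1 binary genotype file set
#'
#' Reads `prefix.bed`, `prefix.bim` and `prefix.fam` into a genotype panel:
#' an N x M matrix of A1 allele counts (0/1/2, `NA` for missing) plus
#' sample and SNP metadata.  Only SNP-major `.bed` files (mode byte 0x01)
#' are supported.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return An object of class `genotype_panel` with elements `calls`
#'   (integer matrix, samples x SNPs), `samples` (data frame with `fid`,
#'   `iid`) and `snps` (data frame with `chrom`, `id`, `cm`, `pos`, `a1`,
#'   `a2`).
#' @seealso [write_plink()], [standardize()]
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)

  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  if (ncol(fam_df) < 2) stop("malformed .fam: fewer than 2 columns")
  samples <- data.frame(fid = fam_df[[1]], iid = fam_df[[2]],
                        stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bim_df) != 6) stop("malformed .bim: expected 6 columns")
  snps <- data.frame(chrom = bim_df[[1]], id = bim_df[[2]],
                     cm = as.numeric(bim_df[[3]]), pos = as.integer(bim_df[[4]]),
                     a1 = bim_df[[5]], a2 = bim_df[[6]],
                     stringsAsFactors = FALSE)
  n <- nrow(samples)
  m <- nrow(snps)

  raw <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("unsupported .bed mode byte (only SNP-major 0x01 is supported)")
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) != 3 + bps * m)
    stop(".bed size mismatch: expected ", 3 + bps * m, " bytes (3 + ceil(N/4)*M), got ",
         length(raw))

  body <- as.integer(raw[-(1:3)]) + 1L
  calls <- matrix(NA_integer_, nrow = 4 * bps, ncol = m)
  for (k in 1:4)
    calls[seq.int(k, 4 * bps, by = 4L), ] <- .bed_lut[body, k]
  calls <- calls[seq_len(n), , drop = FALSE]
  dimnames(calls) <- list(NULL, snps$id)
  new_genotype_panel(calls, samples, snps)
}

#' Write a genotype panel as PLINK 1 binary files
#'
#' Writes `prefix.bed` (SNP-major), `prefix.bim` and `prefix.fam`.
#' Round-trips exactly through [read_plink()].
#'
#' @param panel A `genotype_panel`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  n <- nrow(calls); m <- ncol(calls)
  bps <- ceiling(n / 4)

  # dosage -> 2-bit code: 2->0, NA->1, 1->2, 0->3
  code <- matrix(3L, nrow = 4 * bps, ncol = m)  # pad fields encode 0 copies
  cc <- calls
  v <- integer(length(cc))
  v[which(cc == 2L)] <- 0L
  v[which(is.na(cc))] <- 1L
  v[which(cc == 1L)] <- 2L
  v[which(cc == 0L)] <- 3L
  code[seq_len(n), ] <- v
  shift <- c(1L, 4L, 16L, 64L)  # 2-bit left shifts as multipliers
  bytes <- matrix(0L, nrow = bps, ncol = m)
  for (k in 1:4)
    bytes <- bytes + code[seq.int(k, 4 * bps, by = 4L), , drop = FALSE] * shift[k]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)

  fam <- cbind(panel$samples$fid, panel$samples$iid, "0", "0", "0", "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  s <- panel$snps
  bim <- cbind(s$chrom, s$id, format(s$cm %||% 0, trim = TRUE), s$pos, s$a1, s$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Standardize a genotype panel
#'
#' Drops monomorphic and all-missing SNPs, mean-imputes remaining missing
#' calls, and centers/scales each SNP column so that `sum(x) == 0` and
#' `sum(x^2) == N` exactly (population variance divisor `N`).  With this
#' convention the genetic relatedness matrix `K = X X'/M` satisfies
#' `tr(K) = N`, which the method-of-moments normal equations rely on.
#'
#' @param panel A `genotype_panel`.
#' @return An object of class `std_geno`: `matrix` (N x M numeric),
#'   `snp_ids`, `snps` (metadata for surviving SNPs), `n`, `m`, `freqs`
#'   (per-SNP counted-allele frequency), `obs_ct` (per-SNP observed call
#'   count), `missing_idx` (list of row indices imputed per SNP, only for
#'   SNPs with missingness), and `dropped` (ids of removed SNPs).
#' @export
standardize <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  n <- nrow(calls)
  if (n < 2) stop("at least 2 samples are required")
  obs <- colSums(!is.na(calls))
  mu <- colMeans(calls, na.rm = TRUE)
  # population variance over observed calls
  v <- colMeans(calls^2, na.rm = TRUE) - mu^2
  keep <- obs > 0 & v > 0
  dropped <- colnames(calls)[!keep] %||% panel$snps$id[!keep]
  if (!any(keep)) stop("no SNPs survive standardization (all monomorphic or missing)")
  if (length(dropped))
    message("standardize: dropped ", length(dropped), " monomorphic/all-missing SNP(s)")

  x <- calls[, keep, drop = FALSE]
  storage.mode(x) <- "double"
  mu <- mu[keep]
  miss <- which(is.na(x), arr.ind = TRUE)
  missing_idx <- list()
  if (nrow(miss)) {
    x[miss] <- mu[miss[, 2]]
    missing_idx <- split(miss[, 1], factor(miss[, 2], levels = seq_len(ncol(x))))
    missing_idx <- lapply(missing_idx, as.integer)
  }
  x <- sweep(x, 2, colMeans(x), "-")
  sd_pop <- sqrt(colSums(x^2) / n)
  x <- sweep(x, 2, sd_pop, "/")
  dimnames(x) <- NULL

  structure(list(matrix = x,
                 snp_ids = panel$snps$id[keep],
                 snps = panel$snps[keep, , drop = FALSE],
                 samples = panel$samples,
                 n = n, m = ncol(x),
                 freqs = unname(mu) / 2,
                 obs_ct = as.integer(obs[keep]),
                 missing_idx = missing_idx,
                 dropped = dropped),
            class = "std_geno")
}

#' Subset the SNP columns of a standardized panel
#'
#' Keeps the already-standardized columns as they are (no re-centering);
#' used for jackknife/leave-block-out computations.
#'
#' @param geno A `std_geno` object.
#' @param idx Integer indices of SNP columns to keep.
#' @return A `std_geno` with the selected SNPs.
#' @export
subset_snps <- function(geno, idx) {
  stopifnot(inherits(geno, "std_geno"))
  out <- geno
  out$matrix <- geno$matrix[, idx, drop = FALSE]
  out$snp_ids <- geno$snp_ids[idx]
  out$snps <- geno$snps[idx, , drop = FALSE]
  out$m <- length(idx)
  out$freqs <- geno$freqs[idx]
  out$obs_ct <- geno$obs_ct[idx]
  if (length(geno$missing_idx))
    out$missing_idx <- geno$missing_idx[as.character(idx)]
  out
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("PLINK genotype panel:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs\n")
  nm <- sum(is.na(x$calls))
  if (nm) cat("  missing calls:", nm, "\n")
  invisible(x)
}

#' @export
print.std_geno <- function(x, ...) {
  cat("Standardized genotypes:", x$n, "samples x", x$m, "SNPs",
      "(sum x = 0, sum x^2 = N per column)\n")
  if (length(x$dropped)) cat("  dropped monomorphic/all-missing:", length(x$dropped), "\n")
  invisible(x)
}

#' Read a phenotype file (FID IID PHENO)
#'
#' Accepts a whitespace-separated table with or without a header line;
#' `NA` values are allowed.
#'
#' @param path File path.
#' @return Data frame with columns `fid`, `iid`, `pheno`.
#' @export
read_pheno <- function(path) {
  first <- readLines(path, n = 1)
  toks <- strsplit(trimws(first), "\\s+")[[1]]
  has_header <- length(toks) >= 3 &&
    is.na(suppressWarnings(as.numeric(toks[3]))) && toupper(toks[3]) != "NA"
  df <- utils::read.table(path, header = has_header,
                          colClasses = c("character", "character", "numeric"),
                          na.strings = c("NA", "-9"))
  names(df) <- c("fid", "iid", "pheno")
  df
}

#' Write a phenotype file (FID IID PHENO)
#'
#' @param y Numeric phenotype vector.
#' @param samples Data frame with `fid` and `iid` (same order as `y`).
#' @param path Output path.
#' @param header Write a `FID IID PHENO` header line? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_pheno <- function(y, samples, path, header = TRUE) {
  stopifnot(length(y) == nrow(samples))
  df <- data.frame(FID = samples$fid, IID = samples$iid,
                   PHENO = sprintf("%.17g", y))
  df$PHENO[is.na(y)] <- "NA"
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = header, sep = " ")
  invisible(path)
}
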