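# Per-SNP marginal linear-regression summary statistics and the adjusted
# z-score vector z_j = (beta_j / se_j) * sqrt(N_j) / N, which reconstructs
# X'y / y'y from summary data when X and y are standardized.

#' Run a marginal GWAS on standardized genotypes
#'
#' For each SNP `j`, fits the simple regression of the standardized
#' phenotype on the standardized dosage over the `N_j` samples with
#' observed calls: `beta_j = x_j'y / x_j'x_j`,
#' `se_j = sqrt(RSS_j / (N_j - 2) / x_j'x_j)`.  Regressions are on
#' centered variables (equivalent to including an intercept); no
#' covariates.  Mean-imputed entries (0 after centering) contribute
#' nothing to `x'y`/`x'x`; the residual sum of squares excludes the
#' unobserved samples.
#'
#' @param geno A `std_geno` object.
#' @param y Standardized phenotype (mean 0, `sum(y^2) = N`).
#' @param se_method `"ols"` (exact residual-based standard error, the
#'   default, matching PLINK output) or `"approx"` (the large-sample
#'   approximation `se_j = sqrt(y'y / (N * N_j))` under which the
#'   adjusted z-vector equals `X'y / y'y` exactly).
#' @return A `gwas_sumstats` object: data frame `table` with columns
#'   `chrom`, `pos`, `id`, `a1`, `a2`, `obs_ct`, `beta`, `se`, plus
#'   `n_total` (study N) and `snp_ids`.
#' @export
run_gwas <- function(geno, y, se_method = c("ols", "approx")) {
  stopifnot(inherits(geno, "std_geno"))
  se_method <- match.arg(se_method)
  n <- geno$n
  if (length(y) != n) stop("phenotype length does not match sample count")
  if (abs(mean(y)) > 1e-6 || abs(sum(y^2) / n - 1) > 1e-6)
    stop("phenotype must be standardized: mean 0 and sum(y^2) = N ",
         "(see standardize_phenotype())")
  x <- geno$matrix
  w <- unname(drop(crossprod(x, y)))  # x_j'y, unchanged by mean imputation
  xx <- colSums(x^2)                  # = N by construction
  if (any(xx <= 0)) stop("constant SNP column encountered; run standardize() first")
  beta <- w / xx
  obs <- geno$obs_ct
  yy <- sum(y^2)
  yy_obs <- rep(yy, geno$m)
  if (length(geno$missing_idx)) {
    y2miss <- vapply(geno$missing_idx,
                     function(ix) sum(y[ix]^2), numeric(1))
    yy_obs <- yy - y2miss
  }
  if (se_method == "ols") {
    rss <- pmax(yy_obs - beta * w, 0)
    se <- sqrt(rss / (obs - 2) / xx)
    degenerate <- rss < 1e-12 * yy
    if (any(degenerate)) {
      warning("perfect fit (RSS ~ 0, degenerate SE set to NA) for SNP(s): ",
              paste(geno$snp_ids[degenerate], collapse = ", "))
      se[degenerate] <- NA_real_
    }
  } else {
    se <- sqrt(yy / (n * obs))
  }
  s <- geno$snps
  tab <- data.frame(chrom = s$chrom, pos = s$pos, id = s$id,
                    a1 = s$a1, a2 = s$a2,
                    obs_ct = obs, beta = beta, se = se,
                    stringsAsFactors = FALSE, row.names = NULL)
  new_gwas_sumstats(tab, n_total = n)
}

new_gwas_sumstats <- function(table, n_total) {
  stopifnot(all(c("id", "obs_ct", "beta", "se") %in% names(table)))
  if (any(table$se <= 0, na.rm = TRUE)) {
    bad <- table$id[which(table$se <= 0)]
    stop("non-positive SE for SNP(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(table = table, n_total = as.integer(n_total),
                 snp_ids = table$id),
            class = "gwas_sumstats")
}

#' Adjusted z-score vector from GWAS summary statistics
#'
#' Computes `z_j = (beta_j / se_j) * sqrt(N_j) / N`.  When the SEs follow
#' the large-sample approximation `se_j = sqrt(y'y / (N N_j))` this equals
#' `x_j'y / y'y` exactly, the quantity the summary-statistics estimator
#' needs; with exact OLS SEs the two agree to `O(1/N)`.
#'
#' @param stats A `gwas_sumstats` object.
#' @param n_total Override for the study sample size `N` (defaults to the
#'   value stored in `stats`).
#' @return An `adjusted_z` object: `z` (numeric vector), `m`, `n`,
#'   `snp_ids`.
#' @export
adjusted_z <- function(stats, n_total = NULL) {
  stopifnot(inherits(stats, "gwas_sumstats"))
  n <- as.integer(n_total %||% stats$n_total)
  tab <- stats$table
  if (any(!is.finite(tab$se)) || any(tab$se <= 0)) {
    bad <- tab$id[!is.finite(tab$se) | tab$se <= 0]
    stop("invalid SE for SNP(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  z <- (tab$beta / tab$se) * sqrt(tab$obs_ct) / n
  if (any(!is.finite(z)))
    stop("non-finite adjusted z-scores produced")
  structure(list(z = z, m = nrow(tab), n = n, snp_ids = tab$id),
            class = "adjusted_z")
}

.glm_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "A1", "TEST",
               "OBS_CT", "BETA", "SE", "T_STAT", "P")

#' Write summary statistics in PLINK 2 `.glm.linear` format
#'
#' Emits the tab-separated header
#' `#CHROM POS ID REF ALT A1 TEST OBS_CT BETA SE T_STAT P` with one `ADD`
#' row per SNP.  `T_STAT` and `P` are derived from `beta/se` with
#' `obs_ct - 2` degrees of freedom.
#'
#' @param stats A `gwas_sumstats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "gwas_sumstats"))
  tab <- stats$table
  t_stat <- tab$beta / tab$se
  p <- 2 * stats::pt(-abs(t_stat), df = pmax(tab$obs_ct - 2, 1))
  out <- data.frame(tab$chrom %||% ".", tab$pos %||% ".", tab$id,
                    tab$a2 %||% ".", tab$a1 %||% ".", tab$a1 %||% ".",
                    "ADD", tab$obs_ct,
                    sprintf("%.17g", tab$beta), sprintf("%.17g", tab$se),
                    sprintf("%.17g", t_stat), sprintf("%.6g", p))
  names(out) <- .glm_cols
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.glm_cols, collapse = "\t"), con)
  utils::write.table(out, con, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read PLINK 2 `.glm.linear`-style summary statistics
#'
#' Requires a header line beginning `#CHROM` with at least the columns
#' `ID`, `OBS_CT`, `BETA`, `SE`; extra columns are ignored.  If a `TEST`
#' column is present, only `ADD` rows are consumed.
#'
#' @param path File path.
#' @param n_total Study sample size `N`; defaults to `max(OBS_CT)`.
#' @return A `gwas_sumstats` object.
#' @export
read_sumstats <- function(path, n_total = NULL) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#CHROM"))
    stop("not a .glm.linear file: header must begin with '#CHROM'")
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  required <- c("ID", "OBS_CT", "BETA", "SE")
  missing_cols <- setdiff(required, cols)
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         " (found: ", paste(cols, collapse = ", "), ")")
  df <- utils::read.table(path, header = FALSE, sep = "\t", skip = 1,
                          colClasses = "character", comment.char = "")
  if (ncol(df) != length(cols))
    stop("column count mismatch between header and data rows")
  names(df) <- cols
  if ("TEST" %in% cols) df <- df[df$TEST == "ADD", , drop = FALSE]
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", ".")))
    if (length(bad))
      stop("non-numeric ", col, " at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    v
  }
  tab <- data.frame(chrom = sub("^#", "", df[["#CHROM"]]),
                    pos = if ("POS" %in% cols) suppressWarnings(as.integer(df$POS)) else NA_integer_,
                    id = df$ID,
                    a1 = if ("A1" %in% cols) df$A1 else NA_character_,
                    a2 = if ("REF" %in% cols) df$REF else NA_character_,
                    obs_ct = as.integer(num("OBS_CT")),
                    beta = num("BETA"), se = num("SE"),
                    stringsAsFactors = FALSE)
  new_gwas_sumstats(tab, n_total = n_total %||% max(tab$obs_ct))
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat("GWAS summary statistics:", nrow(x$table), "SNPs, N =", x$n_total, "\n")
  invisible(x)
}
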