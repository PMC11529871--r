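# Synthetic genotype panels and polygenic phenotypes.
#
# Phenotypes follow the additive model y = X beta + e with standardized
# X and y; effect sizes are drawn from a sparse ("causal ratio" P)
# architecture or a two-group large/small mixture.

#' Architecture configuration for effect-size simulation
#'
#' @param h2 Target SNP heritability in `[0, 1]`.
#' @param causal_ratio Proportion `P` of SNPs with nonzero effect, in
#'   `(0, 1]`.  Ignored when `mixture` is given.
#' @param mixture Optional [mixture_config()].
#' @param seed Integer RNG seed.
#' @return An `architecture_config` list.
#' @export
architecture_config <- function(h2, causal_ratio = 1.0, mixture = NULL, seed = 1L) {
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (causal_ratio <= 0 || causal_ratio > 1) stop("causal_ratio must lie in (0, 1]")
  if (!is.null(mixture) && !inherits(mixture, "mixture_config"))
    stop("mixture must be created with mixture_config()")
  structure(list(h2 = h2, causal_ratio = causal_ratio,
                 mixture = mixture, seed = as.integer(seed)),
            class = "architecture_config")
}

#' Large/small-effect mixture configuration
#'
#' The first `floor(pi * M)` SNPs form a large-effect group carrying a
#' fraction `gamma` of the total SNP heritability; the remainder carry
#' `1 - gamma`.  Within each group SNPs are causal independently with
#' probability `alpha`; causal effects are normal with variance
#' `gamma * h2 / (pi * M * alpha)` (large) and
#' `(1 - gamma) * h2 / ((1 - pi) * M * alpha)` (small).
#'
#' @param pi Fraction of SNPs designated large-effect, in `(0, 1)`.
#' @param gamma Fraction of heritability carried by the large-effect
#'   group, in `[0, 1]`.
#' @param alpha Within-group causal probability, in `(0, 1]`.
#' @return A `mixture_config` list.
#' @export
mixture_config <- function(pi, gamma, alpha = 1.0) {
  if (pi <= 0 || pi >= 1) stop("pi must lie in (0, 1)")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(pi = pi, gamma = gamma, alpha = alpha),
            class = "mixture_config")
}

#' Simulate an unlinked biallelic genotype panel
#'
#' Per-SNP minor-allele frequencies are drawn uniformly on
#' `[maf_low, maf_high]`; calls are independent `Binomial(2, maf)` draws
#' per sample.  Deterministic given `seed`.
#'
#' @param n Sample count (>= 2).
#' @param m SNP count (>= 1).
#' @param maf_low,maf_high MAF bounds, `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Integer RNG seed.
#' @return A `genotype_panel` (see [read_plink()]).
#' @export
simulate_genotypes <- function(n, m, maf_low = 0.05, maf_high = 0.5, seed = 1L) {
  if (n < 2 || m < 1) stop("need n >= 2 and m >= 1")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("MAF bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  set.seed(seed)
  maf <- stats::runif(m, maf_low, maf_high)
  calls <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  .panel_from_calls(calls)
}

#' Simulate a genotype panel with block-correlated SNPs
#'
#' Generates linkage disequilibrium by thresholding two latent AR(1)
#' Gaussian haplotypes per individual: within blocks of `block_size`
#' consecutive SNPs the latent correlation between adjacent SNPs is
#' `rho`; blocks are independent.  Marginal allele frequencies still
#' follow `uniform(maf_low, maf_high)`.
#'
#' @inheritParams simulate_genotypes
#' @param block_size SNPs per correlated block.
#' @param rho Latent AR(1) correlation between adjacent SNPs, in `[0, 1)`.
#' @return A `genotype_panel`.
#' @export
simulate_genotypes_ld <- function(n, m, block_size = 10, rho = 0.5,
                                  maf_low = 0.05, maf_high = 0.5, seed = 1L) {
  if (n < 2 || m < 1) stop("need n >= 2 and m >= 1")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("MAF bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  set.seed(seed)
  maf <- stats::runif(m, maf_low, maf_high)
  thresh <- stats::qnorm(maf, lower.tail = FALSE)  # latent > thresh => allele
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), nrow = n)
    sc <- sqrt(1 - rho^2)
    if (m >= 2) {
      for (j in 2:m) {
        if ((j - 1) %% block_size != 0)  # j starts a new block every block_size
          z[, j] <- rho * z[, j - 1] + sc * z[, j]
      }
    }
    z
  }
  calls <- (hap() > rep(thresh, each = n)) + (hap() > rep(thresh, each = n))
  storage.mode(calls) <- "integer"
  .panel_from_calls(calls)
}

.panel_from_calls <- function(calls) {
  n <- nrow(calls); m <- ncol(calls)
  samples <- data.frame(fid = sprintf("F%d", seq_len(n)),
                        iid = sprintf("I%d", seq_len(n)),
                        stringsAsFactors = FALSE)
  snps <- data.frame(chrom = rep("1", m), id = sprintf("snp%d", seq_len(m)),
                     cm = 0, pos = seq_len(m), a1 = rep("A", m), a2 = rep("G", m),
                     stringsAsFactors = FALSE)
  colnames(calls) <- snps$id
  new_genotype_panel(calls, samples, snps)
}

#' Draw per-SNP effect sizes under a genetic architecture
#'
#' Baseline mode: each SNP is causal independently with probability
#' `causal_ratio`; causal effects are normal with variance
#' `h2 / (M * causal_ratio)` so the expected total genetic variance is
#' `h2` regardless of sparsity.  Mixture mode: see [mixture_config()].
#' If a positive-heritability draw yields zero causal SNPs, the causal
#' mask is redrawn (with a message).
#'
#' @param m SNP count.
#' @param cfg An [architecture_config()].
#' @return An `effect_vector`: `beta` (length-`m` numeric) and
#'   `causal_idx` (indices of nonzero effects).
#' @export
draw_effects <- function(m, cfg) {
  stopifnot(inherits(cfg, "architecture_config"))
  set.seed(cfg$seed)
  beta <- numeric(m)
  if (cfg$h2 == 0) {
    return(structure(list(beta = beta, causal_idx = integer(0)),
                     class = "effect_vector"))
  }
  if (is.null(cfg$mixture)) {
    p <- cfg$causal_ratio
    causal <- which(stats::runif(m) < p)
    tries <- 0
    while (length(causal) == 0) {
      tries <- tries + 1
      if (tries > 1000) stop("could not draw a nonzero causal set")
      causal <- which(stats::runif(m) < p)
    }
    if (tries > 0) message("draw_effects: redrew causal mask ", tries, " time(s)")
    beta[causal] <- stats::rnorm(length(causal), 0, sqrt(cfg$h2 / (m * p)))
  } else {
    mx <- cfg$mixture
    m_large <- floor(mx$pi * m)
    if (m_large < 1) stop("pi * m must be >= 1 for a mixture architecture")
    grp_large <- seq_len(m_large)
    var_large <- mx$gamma * cfg$h2 / (mx$pi * m * mx$alpha)
    var_small <- (1 - mx$gamma) * cfg$h2 / ((1 - mx$pi) * m * mx$alpha)
    draw_mask <- function() which(stats::runif(m) < mx$alpha)
    causal <- draw_mask()
    tries <- 0
    while (length(causal) == 0) {
      tries <- tries + 1
      if (tries > 1000) stop("could not draw a nonzero causal set")
      causal <- draw_mask()
    }
    if (tries > 0) message("draw_effects: redrew causal mask ", tries, " time(s)")
    is_large <- causal <= m_large
    beta[causal[is_large]] <- stats::rnorm(sum(is_large), 0, sqrt(var_large))
    beta[causal[!is_large]] <- stats::rnorm(sum(!is_large), 0, sqrt(var_small))
  }
  structure(list(beta = beta, causal_idx = which(beta != 0)),
            class = "effect_vector")
}

#' Simulate a standardized phenotype
#'
#' `y = X beta + e` with `e ~ N(0, 1 - h2)` iid; the result is
#' re-standardized to mean 0 and `sum(y^2) = N` (divisor-`N` convention,
#' matching the estimators' precondition).  Optionally rescales the
#' genetic component so the realized genetic variance share is exactly
#' `h2`.
#'
#' @param geno A `std_geno` object (or bare standardized matrix).
#' @param effects An `effect_vector` from [draw_effects()] (or bare
#'   numeric vector of length M).
#' @param h2 Heritability used for the noise variance `1 - h2`.
#' @param seed Integer RNG seed for the noise draw.
#' @param exact_h2 If `TRUE`, rescale `X beta` and `e` so the realized
#'   variance ratio equals `h2` exactly.  Default `FALSE`.
#' @return Numeric phenotype vector of length N (mean 0, `sum(y^2) = N`).
#' @export
simulate_phenotype <- function(geno, effects, h2, seed = 1L, exact_h2 = FALSE) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  x <- as_std_matrix(geno)
  beta <- if (inherits(effects, "effect_vector")) effects$beta else effects
  stopifnot(length(beta) == ncol(x))
  n <- nrow(x)
  g <- drop(x %*% beta)
  set.seed(seed)
  e <- if (h2 < 1) stats::rnorm(n, 0, sqrt(1 - h2)) else numeric(n)
  if (exact_h2) {
    vg <- sum((g - mean(g))^2) / n
    ve <- sum((e - mean(e))^2) / n
    if (vg > 0) g <- g * sqrt(h2 / vg)
    if (ve > 0) e <- e * sqrt((1 - h2) / ve)
  }
  standardize_phenotype(g + e)
}

#' Standardize a phenotype vector
#'
#' Centers to mean 0 and scales so `sum(y^2) = N`.
#'
#' @param y Numeric vector.
#' @return Standardized vector.
#' @export
standardize_phenotype <- function(y) {
  y <- y - mean(y)
  s <- sqrt(sum(y^2) / length(y))
  if (s == 0) stop("phenotype has zero variance")
  y / s
}
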