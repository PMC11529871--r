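# Method-of-moments SNP heritability estimators.
#
# Solving the Haseman-Elston normal equations for standardized X and y
# (tr(K) = N, y'y = N) gives
#   sigma_g^2 = (y'Ky - y'y) / (tr(K^2) - N),  sigma_e^2 = y'y/N - sigma_g^2,
# and h^2 = sigma_g^2.  The exact estimator computes tr(K^2) directly;
# the randomized variant (RHE) substitutes the Hutchinson estimate; the
# summary-statistics variant (SUM-RHE) rewrites y'Ky/y'y = z'z N / M with
# the adjusted z-scores and tr(K^2)/N - 1 = N rho with a reference-panel
# trace summary:  h^2 = (z'z N / M - 1) / (N rho).

new_h2_estimate <- function(h2, se, n_blocks, method, sigma_g2 = NA_real_,
                            sigma_e2 = NA_real_, m = NA_integer_,
                            n = NA_integer_, replicates = NULL) {
  stopifnot(is.finite(h2))
  if (!is.na(se) && se < 0) stop("negative standard error")
  structure(list(h2 = h2, se = se, n_blocks = n_blocks, method = method,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 m = m, n = n, replicates = replicates),
            class = "h2_estimate")
}

.he_point <- function(yKy, yy, trK2, n) {
  denom <- trK2 - n
  if (abs(denom) < 1e-10)
    stop("degenerate normal equations: tr(K^2) = N (no LD information)")
  sg <- (yKy - yy) / denom
  se2 <- yy / n - sg
  list(sigma_g2 = sg, sigma_e2 = se2, h2 = sg / (yy / n))
}

#' Exact Haseman-Elston heritability estimate
#'
#' Solves the HE normal equations with the exact `tr(K^2)`; `y'Ky` is
#' evaluated as `||X'y||^2 / M` without forming `K`.  Small-scale only
#' (the exact trace forms a `min(N, M)^2` Gram matrix; the jackknife an
#' `M x M` one).
#'
#' @param geno A `std_geno` object (or standardized matrix).
#' @param y Standardized phenotype (mean 0, `sum(y^2) = N`).
#' @param n_blocks Jackknife block count for the standard error, or
#'   `NULL` to skip the (relatively costly) exact jackknife.
#' @return An `h2_estimate` with `method = "HE_EXACT"`.
#' @export
estimate_he_exact <- function(geno, y, n_blocks = NULL) {
  x <- as_std_matrix(geno)
  n <- nrow(x); m <- ncol(x)
  stopifnot(length(y) == n)
  w <- drop(crossprod(x, y))
  yy <- sum(y^2)
  yKy <- sum(w^2) / m
  if (is.null(n_blocks)) {
    pt <- .he_point(yKy, yy, exact_trace_K2(x), n)
    return(new_h2_estimate(pt$h2, NA_real_, NA_integer_, "HE_EXACT",
                           pt$sigma_g2, pt$sigma_e2, m, n))
  }
  tk <- trace_jackknife(x, n_blocks = n_blocks, exact = TRUE)
  pt <- .he_point(yKy, yy, tk$trace, n)
  reps <- .he_jackknife_reps(w, yy, tk, n)
  new_h2_estimate(pt$h2, jackknife_se(reps, pt$h2), n_blocks, "HE_EXACT",
                  pt$sigma_g2, pt$sigma_e2, m, n, replicates = reps)
}

# Leave-one-block-out HE replicates: both y'Ky (via the cached X'y) and
# the trace are recomputed with the block's SNPs removed and M_jack = M - m_b.
.he_jackknife_reps <- function(w, yy, tk, n) {
  m <- tk$plan$m
  sw2 <- sum(w^2)
  vapply(seq_len(tk$plan$n_blocks), function(k) {
    ix <- block_index(tk$plan, k)
    mj <- m - tk$plan$sizes[k]
    yKy_j <- (sw2 - sum(w[ix]^2)) / mj
    .he_point(yKy_j, yy, tk$trace_jack[k], n)$h2
  }, numeric(1))
}

#' Randomized Haseman-Elston (RHE) heritability estimate
#'
#' As [estimate_he_exact()] but with `tr(K^2)` replaced by the stochastic
#' Hutchinson estimate with `b` probe vectors.  The SNP-block jackknife
#' couples the trace and the `y'Ky` term: both are recomputed per
#' left-out block with shared probes and `M` renormalized to `M - m_b`.
#'
#' @inheritParams estimate_he_exact
#' @param b Number of probe vectors.
#' @param n_blocks Jackknife block count.
#' @param seed Integer RNG seed for the probes.
#' @param trace Optional precomputed in-sample [make_trace_summary()]
#'   result for this panel (probes are then not redrawn); must have
#'   matching `n_ref` and `m`.  Useful when many phenotypes are analyzed
#'   on one panel, since the trace does not depend on `y`.
#' @return An `h2_estimate` with `method = "RHE"`.
#' @export
estimate_rhe <- function(geno, y, b = 100L, n_blocks = 100L, seed = 1L,
                         trace = NULL) {
  x <- as_std_matrix(geno)
  n <- nrow(x); m <- ncol(x)
  stopifnot(length(y) == n)
  if (is.null(trace)) {
    tk <- trace_jackknife(x, n_blocks = n_blocks, b = b, seed = seed)
    trace_full <- tk$trace
    trace_jack <- tk$trace_jack
    plan <- tk$plan
  } else {
    stopifnot(inherits(trace, "trace_summary"))
    if (trace$n_ref != n || trace$m != m)
      stop("precomputed trace summary does not match this panel (N or M differ)")
    trace_full <- n * (n * trace$rho + 1)
    trace_jack <- n * (n * trace$blocks$rho_jack + 1)
    n_blocks <- nrow(trace$blocks)
    plan <- jackknife_plan(m, n_blocks)
    if (!identical(plan$sizes, as.integer(trace$blocks$m_block)))
      stop("trace summary block sizes are not the contiguous equal-size plan")
  }
  w <- drop(crossprod(x, y))
  yy <- sum(y^2)
  pt <- .he_point(sum(w^2) / m, yy, trace_full, n)
  tk <- list(plan = plan, trace_jack = trace_jack)
  reps <- .he_jackknife_reps(w, yy, tk, n)
  new_h2_estimate(pt$h2, jackknife_se(reps, pt$h2), n_blocks, "RHE",
                  pt$sigma_g2, pt$sigma_e2, m, n, replicates = reps)
}

#' SUM-RHE: heritability from summary statistics plus a trace summary
#'
#' Reconstructs the randomized HE method-of-moments estimate without
#' individual-level data:
#' `h2 = (z'z N / M - 1) / (N rho)`, with adjusted z-scores
#' `z_j = (beta_j/se_j) sqrt(N_j) / N` from the GWAS and the population
#' LD statistic `rho` from a reference-panel trace summary.  Jackknife
#' replicates drop each SNP block from `z'z` (`M_jack = M - m_b`) and use
#' the trace summary's `rho_jack` for that block.
#'
#' @param stats A `gwas_sumstats` object.
#' @param trace A `trace_summary` on the same SNP panel.
#' @param n_target GWAS sample size `N` (precedence: this argument, then
#'   `stats$n_total`, then `max(OBS_CT)`).
#' @param intersect If `TRUE`, SNPs are matched by count only after
#'   intersecting — not supported unless the counts already match; the
#'   default `FALSE` demands an exact SNP-panel match (digest check).
#' @return An `h2_estimate` with `method = "SUM_RHE"` (variance
#'   components are not identifiable from summary data and are reported
#'   relative to unit phenotypic variance).
#' @export
estimate_sumrhe <- function(stats, trace, n_target = NULL, intersect = FALSE) {
  stopifnot(inherits(stats, "gwas_sumstats"), inherits(trace, "trace_summary"))
  n <- as.integer(n_target %||% stats$n_total %||% max(stats$table$obs_ct))
  m <- trace$m
  if (nrow(stats$table) != m)
    stop("SNP count mismatch: sumstats have ", nrow(stats$table),
         " SNPs, trace summary has ", m)
  dg <- snp_digest(stats$snp_ids)
  if (dg != trace$snp_digest) {
    msg <- paste0("SNP list digest mismatch between sumstats (", dg,
                  ") and trace summary (", trace$snp_digest, ")")
    if (intersect) warning(msg, "; proceeding, rho may not match this SNP set")
    else stop(msg)
  }
  if (trace$rho <= 0)
    stop("invalid trace summary: rho <= 0 (increase probe count B)")
  z <- adjusted_z(stats, n_total = n)$z
  zz <- sum(z^2)
  h2 <- (zz * n / m - 1) / (n * trace$rho)
  n_blocks <- nrow(trace$blocks)
  plan <- jackknife_plan(m, n_blocks)
  if (!identical(plan$sizes, as.integer(trace$blocks$m_block)))
    stop("trace summary block sizes are not the contiguous equal-size plan")
  reps <- vapply(seq_len(n_blocks), function(k) {
    ix <- block_index(plan, k)
    mj <- m - plan$sizes[k]
    zzj <- zz - sum(z[ix]^2)
    (zzj * n / mj - 1) / (n * trace$blocks$rho_jack[k])
  }, numeric(1))
  new_h2_estimate(h2, jackknife_se(reps, h2), n_blocks, "SUM_RHE",
                  sigma_g2 = h2, sigma_e2 = 1 - h2, m = m, n = n,
                  replicates = reps)
}

#' Delete-one-block jackknife standard error
#'
#' `SE = sqrt((n-1)/n * sum_i (h2_i - mean(h2))^2)` over the `n`
#' leave-one-block-out replicates.
#'
#' @param replicates Numeric vector of per-block estimates (length >= 2).
#' @param point Point estimate (unused by the formula; accepted for
#'   interface symmetry).
#' @return The jackknife standard error (scalar, >= 0).
#' @export
jackknife_se <- function(replicates, point = NULL) {
  nb <- length(replicates)
  if (nb < 2) stop("need at least 2 jackknife replicates")
  mu <- mean(replicates)
  sqrt((nb - 1) / nb * sum((replicates - mu)^2))
}

#' One-sided test of zero heritability
#'
#' Tests `h2 = 0` against `h2 > 0` with the normal statistic `h2 / se`:
#' `p = 1 - Phi(h2/se)`, rejecting when `p < alpha` (strict).  Calibration
#' relies on estimates being unclamped (about half are negative under the
#' null).
#'
#' @param est An `h2_estimate`.
#' @param alpha Rejection threshold (default 0.05).
#' @param two_sided If `TRUE`, use the two-sided p-value instead.
#' @return A `null_test` list: `statistic`, `p_value`, `reject`, `alpha`.
#' @export
test_null <- function(est, alpha = 0.05, two_sided = FALSE) {
  stopifnot(inherits(est, "h2_estimate"))
  if (is.na(est$se) || est$se <= 0)
    stop("degenerate test: estimate has no positive standard error")
  stat <- est$h2 / est$se
  p <- if (two_sided) 2 * stats::pnorm(-abs(stat))
       else stats::pnorm(stat, lower.tail = FALSE)
  structure(list(statistic = stat, p_value = p, reject = p < alpha,
                 alpha = alpha),
            class = "null_test")
}

#' Clamp an estimate to [0, 1] for presentation
#'
#' Reporting aid only: clamped estimates must not be used for null-test
#' calibration.
#'
#' @param est An `h2_estimate`.
#' @return The estimate with `h2` truncated to `[0, 1]`.
#' @export
clamp_h2 <- function(est) {
  est$h2 <- min(max(est$h2, 0), 1)
  est
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: h2 = %.4f (SE %.4f, %s jackknife blocks), M = %s, N = %s\n",
              x$method, x$h2, x$se,
              ifelse(is.na(x$n_blocks), "no", x$n_blocks), x$m, x$n))
  if (!is.na(x$sigma_g2))
    cat(sprintf("  sigma_g2 = %.4f, sigma_e2 = %.4f\n", x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("H0: h2 = 0 vs h2 > 0: z = %.3f, p = %.4g, %s at alpha = %g\n",
              x$statistic, x$p_value,
              if (x$reject) "REJECT" else "no rejection", x$alpha))
  invisible(x)
}
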