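test_that("exact HE equals a brute-force normal-equation solve", {
  std <- make_std(5, 3, seed = 61)
  y <- simulate_phenotype(std, draw_effects(3, architecture_config(0.5, 1, seed = 62)),
                          0.5, seed = 63)
  # brute force: form K, assemble the 2x2 normal equations, solve
  k <- tcrossprod(std$matrix) / std$m
  lhs <- matrix(c(sum(k * k), sum(diag(k)), sum(diag(k)), std$n), 2)
  rhs <- c(drop(t(y) %*% k %*% y), sum(y^2))
  sol <- solve(lhs, rhs)
  est <- estimate_he_exact(std, y)
  expect_equal(est$sigma_g2, sol[1], tolerance = 1e-10)
  expect_equal(est$sigma_e2, sol[2], tolerance = 1e-10)
  expect_equal(est$h2, sol[1] / (sum(y^2) / std$n), tolerance = 1e-10)
  expect_equal(est$sigma_g2 + est$sigma_e2, 1, tolerance = 1e-6)
})

test_that("exact HE is unbiased under the null and recovers h2 = 1", {
  std <- make_std(200, 150, seed = 64)
  set.seed(65)
  nulls <- vapply(1:60, function(i) {
    y <- simulate_phenotype(std, numeric(std$m), 0, seed = 1000 + i)
    estimate_he_exact(std, y)$h2
  }, numeric(1))
  se <- stats::sd(nulls) / sqrt(length(nulls))
  expect_lt(abs(mean(nulls)), 3 * se)
  # roughly half the null estimates are negative (no clamping)
  expect_gt(mean(nulls < 0), 0.2)
  expect_lt(mean(nulls < 0), 0.8)

  std2 <- make_std(300, 600, seed = 66)
  eff <- draw_effects(std2$m, architecture_config(1.0, 1.0, seed = 67))
  y1 <- simulate_phenotype(std2, eff, 1.0, seed = 68)
  est1 <- estimate_he_exact(std2, y1)
  expect_lt(abs(est1$h2 - 1), 0.15)
})

test_that("RHE converges to exact HE as B grows and is deterministic", {
  std <- make_std(300, 500, seed = 69)
  eff <- draw_effects(std$m, architecture_config(0.4, 0.5, seed = 70))
  y <- simulate_phenotype(std, eff, 0.4, seed = 71)
  he <- estimate_he_exact(std, y)
  rhe <- estimate_rhe(std, y, b = 5000, n_blocks = 20, seed = 2)
  expect_lt(abs(rhe$h2 - he$h2) / abs(he$h2), 0.01)

  r1 <- estimate_rhe(std, y, b = 50, n_blocks = 10, seed = 3)
  r2 <- estimate_rhe(std, y, b = 50, n_blocks = 10, seed = 3)
  expect_identical(r1$h2, r2$h2)
  expect_identical(r1$se, r2$se)

  # a precomputed in-sample trace summary reproduces the same estimate
  ts <- make_trace_summary(std, b = 50, n_blocks = 10, seed = 3)
  r3 <- estimate_rhe(std, y, trace = ts)
  expect_equal(r3$h2, r1$h2, tolerance = 1e-12)
  expect_equal(r3$se, r1$se, tolerance = 1e-12)
})

test_that("SUM-RHE with exact in-sample trace reconstructs exact HE", {
  for (s in 1:3) {
    std <- make_std(150 + 50 * s, 200 + 100 * s, seed = 72 + s)
    eff <- draw_effects(std$m, architecture_config(0.25, 0.1, seed = 80 + s))
    y <- simulate_phenotype(std, eff, 0.25, seed = 90 + s)
    he <- estimate_he_exact(std, y, n_blocks = 10)
    stats <- run_gwas(std, y, se_method = "approx")
    tr <- make_trace_summary(std, b = Inf, n_blocks = 10)
    sr <- estimate_sumrhe(stats, tr, n_target = std$n)
    expect_equal(sr$h2, he$h2, tolerance = 1e-8)
    expect_equal(sr$se, he$se, tolerance = 1e-8)
    expect_equal(sr$replicates, he$replicates, tolerance = 1e-8)
  }
})

test_that("SUM-RHE with real OLS standard errors agrees to O(1/N)", {
  std <- make_std(2000, 1000, seed = 76)
  eff <- draw_effects(std$m, architecture_config(0.3, 1.0, seed = 77))
  y <- simulate_phenotype(std, eff, 0.3, seed = 78)
  he <- estimate_he_exact(std, y)
  stats <- run_gwas(std, y, se_method = "ols")
  tr <- make_trace_summary(std, b = Inf, n_blocks = 10)
  sr <- estimate_sumrhe(stats, tr, n_target = std$n)
  expect_lt(abs(sr$h2 - he$h2), 0.01)
})

test_that("SUM-RHE follows the summary-statistics arithmetic", {
  # z'z N / M = 1 is the null point regardless of rho
  make_stats <- function(z, n) {
    # invert z = (beta/se) sqrt(n)/n with se = 1: beta = z * n / sqrt(n)
    tab <- data.frame(chrom = "1", pos = seq_along(z), id = sprintf("s%d", seq_along(z)),
                      a1 = "A", a2 = "C", obs_ct = n, beta = z * sqrt(n),
                      se = 1)
    sumrhe:::new_gwas_sumstats(tab, n_total = n)
  }
  n <- 100; m <- 50
  z_null <- rep(sqrt(1 / n), m)          # z'z = M/N -> z'z N/M = 1
  blocks <- data.frame(block_index = 1:2, m_block = c(25, 25), rho_jack = c(0.03, 0.03))
  tr <- sumrhe:::new_trace_summary(400, m, 100, rho = 0.03, blocks = blocks,
                                   digest = sumrhe:::snp_digest(sprintf("s%d", 1:m)))
  est0 <- estimate_sumrhe(make_stats(z_null, n), tr)
  expect_equal(est0$h2, 0, tolerance = 1e-12)

  # z'z = 0.65, N = 100, M = 50, rho = 0.03:
  # h2 = (0.65 * 100/50 - 1) / (100 * 0.03) = 0.3/3 = 0.1
  z <- rep(sqrt(0.65 / m), m)
  est <- estimate_sumrhe(make_stats(z, n), tr)
  expect_equal(est$h2, 0.1, tolerance = 1e-12)

  # rho <= 0 is a hard error
  tr_bad <- tr; tr_bad$rho <- -0.01
  expect_error(estimate_sumrhe(make_stats(z, n), tr_bad), "rho <= 0")

  # SNP-panel mismatch is a hard error
  tr_m <- sumrhe:::new_trace_summary(400, 40, 100, 0.03,
                                     data.frame(block_index = 1:2,
                                                m_block = c(20, 20),
                                                rho_jack = c(0.03, 0.03)),
                                     digest = "0")
  expect_error(estimate_sumrhe(make_stats(z, n), tr_m), "SNP count mismatch")
})

test_that("jackknife SE follows the delete-one-block formula", {
  expect_equal(jackknife_se(c(0.2, 0.2, 0.2)), 0)
  expect_equal(jackknife_se(c(0.1, 0.2, 0.3)), sqrt((2 / 3) * 0.02))
  expect_equal(jackknife_se(c(0.1, 0.2, 0.3)), 0.1154701, tolerance = 1e-6)
  # doubling deviations doubles the SE
  r <- c(0.05, 0.12, 0.31, 0.2)
  r2 <- mean(r) + 2 * (r - mean(r))
  expect_equal(jackknife_se(r2), 2 * jackknife_se(r))
  expect_error(jackknife_se(0.1), "at least 2")
})

test_that("jackknife SE tracks the empirical spread of RHE null estimates", {
  std <- make_std(1000, 2500, seed = 79)
  ts <- make_trace_summary(std, b = 100, n_blocks = 50, seed = 80)
  res <- vapply(1:100, function(i) {
    y <- simulate_phenotype(std, numeric(std$m), 0, seed = 2000 + i)
    est <- estimate_rhe(std, y, trace = ts)
    c(est$h2, est$se)
  }, numeric(2))
  emp_sd <- stats::sd(res[1, ])
  mean_se <- mean(res[2, ])
  expect_lt(mean_se / emp_sd, 1.3)
  expect_gt(mean_se / emp_sd, 1 / 1.3)
})

test_that("null test is one-sided with documented boundary behavior", {
  mk <- function(h2, se) sumrhe:::new_h2_estimate(h2, se, 10L, "RHE")
  t0 <- test_null(mk(0, 0.1))
  expect_equal(t0$p_value, 0.5)
  expect_false(t0$reject)

  tb <- test_null(mk(0.16449, 0.1))
  expect_equal(tb$p_value, 0.05, tolerance = 1e-3)

  tn <- test_null(mk(-0.2, 0.1))
  expect_gt(tn$p_value, 0.5)
  expect_false(tn$reject)

  expect_error(test_null(mk(0.1, 0)), "degenerate")

  # two-sided option
  t2 <- test_null(mk(-0.2, 0.1), two_sided = TRUE)
  expect_equal(t2$p_value, 2 * stats::pnorm(-2))
})

test_that("clamping is presentation-only", {
  est <- sumrhe:::new_h2_estimate(-0.07, 0.05, 10L, "SUM_RHE")
  expect_equal(clamp_h2(est)$h2, 0)
  expect_equal(est$h2, -0.07)
})

test_that("reference-transfer SUM-RHE matches in-sample accuracy", {
  pop <- simulate_genotypes(1500, 800, seed = 81)
  tgt <- standardize(sumrhe:::new_genotype_panel(
    pop$calls[1:700, ], pop$samples[1:700, ], pop$snps))
  ref <- standardize(sumrhe:::new_genotype_panel(
    pop$calls[701:1500, ], pop$samples[701:1500, ], pop$snps))
  tr_in <- make_trace_summary(tgt, b = 500, n_blocks = 10, seed = 82)
  tr_ref <- make_trace_summary(ref, b = 500, n_blocks = 10, seed = 83)
  h2 <- 0.4
  errs <- vapply(1:30, function(i) {
    eff <- draw_effects(tgt$m, architecture_config(h2, 1.0, seed = 3000 + i))
    y <- simulate_phenotype(tgt, eff, h2, seed = 4000 + i)
    stats <- run_gwas(tgt, y)
    c(estimate_sumrhe(stats, tr_in)$h2 - h2,
      estimate_sumrhe(stats, tr_ref)$h2 - h2)
  }, numeric(2))
  bias_in <- mean(errs[1, ]); bias_ref <- mean(errs[2, ])
  se_diff <- stats::sd(errs[2, ] - errs[1, ]) / sqrt(ncol(errs))
  expect_lt(abs(bias_ref - bias_in), 3 * se_diff + 0.02)
})
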