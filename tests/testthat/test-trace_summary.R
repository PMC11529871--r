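test_that("exact trace matches rank-one and brute-force oracles", {
  # single SNP: K = xx'/1, tr(K^2) = (x'x)^2 = N^2
  x1 <- standardize(panel_from_matrix(cbind(c(0L, 1L, 2L, 1L, 0L))))
  expect_equal(exact_trace_K2(x1), 25)

  # random 6 x 4 panel vs explicitly formed K
  std <- make_std(6, 4, seed = 41)
  expect_equal(exact_trace_K2(std), brute_trace_K2(std$matrix))

  # Gram-route (M x M) and GRM-route (N x N) agree
  std2 <- make_std(30, 12, seed = 42)
  g_m <- sum(crossprod(std2$matrix)^2) / std2$m^2
  g_n <- sum(tcrossprod(std2$matrix)^2) / std2$m^2
  expect_equal(exact_trace_K2(std2), g_n)
  expect_equal(g_m, g_n, tolerance = 1e-12)
})

test_that("stochastic trace is unbiased and concentrates with B", {
  std <- make_std(100, 200, seed = 43)
  exact <- exact_trace_K2(std)

  ests <- vapply(1:50, function(s) stochastic_trace_K2(std, b = 20, seed = s),
                 numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - exact), 3 * se)

  std2 <- make_std(200, 100, seed = 44)
  exact2 <- exact_trace_K2(std2)
  est2 <- stochastic_trace_K2(std2, b = 2000, seed = 1)
  expect_lt(abs(est2 - exact2) / exact2, 0.02)

  expect_identical(stochastic_trace_K2(std, 50, seed = 7),
                   stochastic_trace_K2(std, 50, seed = 7))
  # Rademacher probes remain unbiased
  rad <- vapply(1:50, function(s)
    stochastic_trace_K2(std, b = 20, seed = s, probes = "rademacher"),
    numeric(1))
  expect_lt(abs(mean(rad) - exact), 3 * stats::sd(rad) / sqrt(50))
})

test_that("exact trace matches the independent-SNP limit N + N^2/M", {
  std <- make_std(2000, 1000, seed = 45)
  tr <- exact_trace_K2(std)
  expect_lt(abs(tr - (2000 + 2000^2 / 1000)) / tr, 0.05)
  # equivalently tr/N ~ N/M + 1, i.e. N*rho ~ N/M
  rho <- (tr / 2000 - 1) / 2000
  expect_lt(abs(2000 * rho - 2000 / 1000) / (2000 / 1000), 0.10)
})

test_that("exact-mode jackknife equals the physically subset panel", {
  std <- make_std(40, 30, seed = 46)
  ts <- make_trace_summary(std, b = Inf, n_blocks = 5)
  plan <- sumrhe:::jackknife_plan(std$m, 5)
  for (k in 1:5) {
    keep <- setdiff(seq_len(std$m), sumrhe:::block_index(plan, k))
    tr_sub <- exact_trace_K2(std$matrix[, keep, drop = FALSE])
    rho_sub <- (tr_sub / std$n - 1) / std$n
    expect_equal(ts$blocks$rho_jack[k], rho_sub, tolerance = 1e-8)
  }
})

test_that("shared-probe leave-one-out equals rerunning the probes on the subset", {
  std <- make_std(50, 24, seed = 47)
  b <- 30; seed <- 5
  ts <- make_trace_summary(std, b = b, n_blocks = 4, seed = seed)
  plan <- sumrhe:::jackknife_plan(std$m, 4)
  for (k in 1:4) {
    keep <- setdiff(seq_len(std$m), sumrhe:::block_index(plan, k))
    # same N, same seed -> identical probe vectors on the subset panel
    tr_sub <- stochastic_trace_K2(std$matrix[, keep, drop = FALSE], b, seed)
    rho_sub <- (tr_sub / std$n - 1) / std$n
    expect_equal(ts$blocks$rho_jack[k], rho_sub, tolerance = 1e-8)
  }
})

test_that("duplicated SNP halves give symmetric jackknife blocks", {
  std <- make_std(30, 6, seed = 48)
  x_dup <- cbind(std$matrix, std$matrix)
  ts <- make_trace_summary(x_dup, b = Inf, n_blocks = 2)
  expect_equal(ts$blocks$rho_jack[1], ts$blocks$rho_jack[2], tolerance = 1e-12)
})

test_that("trace runs pool by b-weighted averaging", {
  std <- make_std(80, 40, seed = 49)
  t1 <- make_trace_summary(std, b = 100, n_blocks = 4, seed = 1)
  t2 <- make_trace_summary(std, b = 100, n_blocks = 4, seed = 2)
  agg <- aggregate_trace_runs(list(t1, t2))
  expect_equal(agg$rho, (t1$rho + t2$rho) / 2)
  expect_equal(agg$b_total, 200)
  expect_equal(agg$blocks$rho_jack, (t1$blocks$rho_jack + t2$blocks$rho_jack) / 2)

  self <- aggregate_trace_runs(list(t1, t1))
  expect_equal(self$rho, t1$rho)
  expect_equal(self$b_total, 200)

  # 25 runs at B = 100 approximate the exact rho closely (B' = 2500)
  runs <- lapply(1:25, function(s)
    make_trace_summary(std, b = 100, n_blocks = 4, seed = 100 + s))
  pooled <- aggregate_trace_runs(runs)
  rho_exact <- (exact_trace_K2(std) / std$n - 1) / std$n
  expect_lt(abs(pooled$rho - rho_exact) / rho_exact, 0.01)

  t_bad <- make_trace_summary(std, b = 100, n_blocks = 5, seed = 1)
  expect_error(aggregate_trace_runs(list(t1, t_bad)), "incompatible")
  t_dig <- make_trace_summary(std$matrix, b = 100, n_blocks = 4, seed = 1,
                              snp_ids = sprintf("other%d", 1:40))
  expect_error(aggregate_trace_runs(list(t1, t_dig)), "digests")
})

test_that("trace files round-trip bit-exactly and are validated", {
  std <- make_std(60, 20, seed = 50)
  ts <- make_trace_summary(std, b = 100, n_blocks = 4, seed = 3)
  path <- file.path(withr::local_tempdir(), "ref.trace")
  write_trace(ts, path)
  back <- read_trace(path)
  expect_identical(back$rho, ts$rho)
  expect_identical(back$blocks$rho_jack, ts$blocks$rho_jack)
  expect_identical(back$n_ref, ts$n_ref)
  expect_identical(back$m, ts$m)
  expect_identical(back$snp_digest, ts$snp_digest)

  # dropping a block line breaks the sum(m_block) == M invariant
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)
  expect_error(read_trace(path), "sum to M")

  # digest validation honors strict
  write_trace(ts, path)
  expect_error(read_trace(path, expect_digest = "deadbeef"), "digest mismatch")
  expect_warning(read_trace(path, expect_digest = "deadbeef", strict = FALSE),
                 "digest mismatch")
})

test_that("rho transfers between disjoint reference samples", {
  # two disjoint samples of one population estimate the same rho
  pop <- simulate_genotypes(1200, 400, seed = 51)
  h1 <- standardize(sumrhe:::new_genotype_panel(
    pop$calls[1:600, ], pop$samples[1:600, ], pop$snps))
  h2 <- standardize(sumrhe:::new_genotype_panel(
    pop$calls[601:1200, ], pop$samples[601:1200, ], pop$snps))
  rho1 <- (exact_trace_K2(h1) / h1$n - 1) / h1$n
  rho2 <- (exact_trace_K2(h2) / h2$n - 1) / h2$n
  # both near the population value 1/M + O(1/N): compare within 15%
  expect_lt(abs(rho1 - rho2) / rho1, 0.15)
})

test_that("jackknife plan covers all SNPs with contiguous blocks", {
  for (m in c(10, 17, 100)) {
    for (nb in c(2, 3, 7)) {
      plan <- sumrhe:::jackknife_plan(m, nb)
      idx <- unlist(lapply(seq_len(nb), function(k) sumrhe:::block_index(plan, k)))
      expect_identical(idx, seq_len(m))
      expect_equal(sum(plan$sizes), m)
    }
  }
  expect_error(sumrhe:::jackknife_plan(5, 6), "exceeds")
  expect_error(make_trace_summary(make_std(10, 5, seed = 1), b = 10,
                                  n_blocks = 6), "exceeds")
})
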