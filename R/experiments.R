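# Simulation harness: bias / SE / false-positive-rate tables over a grid
# of genetic architectures, and relative-MSE comparisons with bootstrap
# confidence intervals.

#' Define a simulation experiment grid
#'
#' @param h2_values Heritabilities to simulate (e.g. `c(0.1, 0.25, 0.4)`).
#' @param causal_ratios Causal-ratio values (e.g. `c(1.0, 0.1, 0.01)`).
#'   Ignored for cells that carry a `mixture`.
#' @param n_replicates Phenotype replicates per cell.
#' @param n Target sample size.
#' @param m SNP count.
#' @param n_ref Reference sample size (split-reference mode only).
#' @param mixture Optional [mixture_config()]; if given, the grid cells
#'   are `h2_values x alpha` of the mixture instead of causal ratios.
#' @param estimators Subset of `c("HE_EXACT", "RHE", "SUM_RHE")`.
#' @param reference_mode `"in_sample"` (trace summary from the target
#'   panel itself) or `"split_reference"` (disjoint reference sample of
#'   the same simulated population).
#' @param b Probe vectors per trace run.
#' @param n_trace_runs Independent trace runs aggregated into the final
#'   trace summary (total probes `b * n_trace_runs`).
#' @param n_blocks Jackknife block count.
#' @param maf_low,maf_high MAF bounds for the simulated panel.
#' @param alpha Null-test rejection threshold.
#' @param fresh_genotypes Redraw the genotype panel every replicate
#'   (default `FALSE`: one fixed panel per grid, fresh phenotypes).
#' @param seed Master seed; every derived seed is a deterministic
#'   function of it.
#' @return An `experiment_grid` list.
#' @export
experiment_grid <- function(h2_values, causal_ratios = 1.0,
                            n_replicates = 100L, n = 2000L, m = 5000L,
                            n_ref = 4000L, mixture = NULL,
                            estimators = c("RHE", "SUM_RHE"),
                            reference_mode = c("in_sample", "split_reference"),
                            b = 100L, n_trace_runs = 25L, n_blocks = 100L,
                            maf_low = 0.05, maf_high = 0.5,
                            alpha = 0.05, fresh_genotypes = FALSE, seed = 1L) {
  reference_mode <- match.arg(reference_mode)
  estimators <- match.arg(estimators, c("HE_EXACT", "RHE", "SUM_RHE"),
                          several.ok = TRUE)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!length(h2_values)) stop("empty h2 grid")
  structure(list(h2_values = h2_values, causal_ratios = causal_ratios,
                 n_replicates = as.integer(n_replicates),
                 n = as.integer(n), m = as.integer(m),
                 n_ref = as.integer(n_ref), mixture = mixture,
                 estimators = estimators, reference_mode = reference_mode,
                 b = b, n_trace_runs = as.integer(n_trace_runs),
                 n_blocks = as.integer(n_blocks),
                 maf_low = maf_low, maf_high = maf_high, alpha = alpha,
                 fresh_genotypes = fresh_genotypes, seed = as.integer(seed)),
            class = "experiment_grid")
}

.grid_cells <- function(grid) {
  if (is.null(grid$mixture)) {
    expand.grid(h2 = grid$h2_values, p = grid$causal_ratios,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    cells <- expand.grid(h2 = grid$h2_values, p = NA_real_,
                         KEEP.OUT.ATTRS = FALSE)
    cells
  }
}

.grid_trace <- function(std, grid, seed0) {
  runs <- lapply(seq_len(grid$n_trace_runs), function(r)
    make_trace_summary(std, b = grid$b, n_blocks = grid$n_blocks,
                       seed = seed0 + r))
  if (length(runs) == 1) runs[[1]] else aggregate_trace_runs(runs)
}

#' Run a simulation grid
#'
#' For each architecture cell: simulate (or reuse) a genotype panel,
#' build trace summaries once per panel (they do not depend on the
#' phenotype), then for each replicate draw effects and a phenotype, run
#' the GWAS and the requested estimators, and apply the one-sided null
#' test.  Fully reproducible from `(grid, seed)`.
#'
#' @param grid An [experiment_grid()].
#' @param verbose Print per-cell progress.
#' @return A `grid_result`: `metrics` (per cell x estimator: bias,
#'   empirical SE (divisor n, so `mse = bias^2 + emp_se^2`), mean
#'   jackknife SE, MSE, FPR, failures) and `replicates` (per-replicate
#'   estimates), plus the grid.
#' @export
run_grid <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- .grid_cells(grid)
  split_mode <- grid$reference_mode == "split_reference"

  panel_env <- new.env()
  get_panels <- function(seed) {
    key <- as.character(seed)
    if (!is.null(panel_env[[key]])) return(panel_env[[key]])
    n_total <- grid$n + if (split_mode) grid$n_ref else 0L
    panel <- simulate_genotypes(n_total, grid$m, grid$maf_low, grid$maf_high,
                                seed = seed)
    if (split_mode) {
      tgt <- new_genotype_panel(panel$calls[seq_len(grid$n), , drop = FALSE],
                                panel$samples[seq_len(grid$n), , drop = FALSE],
                                panel$snps)
      ref <- new_genotype_panel(panel$calls[-seq_len(grid$n), , drop = FALSE],
                                panel$samples[-seq_len(grid$n), , drop = FALSE],
                                panel$snps)
      std_t <- standardize(tgt); std_r <- standardize(ref)
      common <- intersect(std_t$snp_ids, std_r$snp_ids)
      std_t <- subset_snps(std_t, match(common, std_t$snp_ids))
      std_r <- subset_snps(std_r, match(common, std_r$snp_ids))
    } else {
      std_t <- standardize(panel)
      std_r <- std_t
    }
    trace_ref <- if ("SUM_RHE" %in% grid$estimators)
      .grid_trace(std_r, grid, seed0 = seed + 500L) else NULL
    trace_tgt <- if ("RHE" %in% grid$estimators)
      make_trace_summary(std_t, b = grid$b, n_blocks = grid$n_blocks,
                         seed = seed + 900L) else NULL
    out <- list(std_t = std_t, trace_ref = trace_ref, trace_tgt = trace_tgt)
    panel_env[[key]] <- out
    out
  }

  rep_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    h2 <- cells$h2[ci]; p <- cells$p[ci]
    if (verbose)
      message(sprintf("cell %d/%d: h2 = %g, P = %s", ci, nrow(cells), h2,
                      ifelse(is.na(p), "mixture", p)))
    for (r in seq_len(grid$n_replicates)) {
      seed_r <- grid$seed + 10000L + (ci - 1L) * grid$n_replicates + r
      panels <- get_panels(if (grid$fresh_genotypes) seed_r else grid$seed)
      std_t <- panels$std_t
      cfg <- architecture_config(h2,
                                 causal_ratio = if (is.na(p)) 1.0 else p,
                                 mixture = grid$mixture, seed = seed_r)
      eff <- draw_effects(std_t$m, cfg)
      y <- simulate_phenotype(std_t, eff, h2, seed = seed_r + 1L)
      stats <- if ("SUM_RHE" %in% grid$estimators) run_gwas(std_t, y) else NULL
      for (est_name in grid$estimators) {
        est <- tryCatch(
          switch(est_name,
                 HE_EXACT = estimate_he_exact(std_t, y, n_blocks = grid$n_blocks),
                 RHE = estimate_rhe(std_t, y, trace = panels$trace_tgt),
                 SUM_RHE = estimate_sumrhe(stats, panels$trace_ref,
                                           n_target = std_t$n)),
          error = function(e) e)
        if (inherits(est, "error")) {
          rep_rows[[length(rep_rows) + 1L]] <-
            data.frame(cell = ci, h2_true = h2, causal_ratio = p,
                       estimator = est_name, replicate = r,
                       h2 = NA_real_, se = NA_real_, reject = NA,
                       error = conditionMessage(est))
          next
        }
        nt <- test_null(est, alpha = grid$alpha)
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(cell = ci, h2_true = h2, causal_ratio = p,
                     estimator = est_name, replicate = r,
                     h2 = est$h2, se = est$se, reject = nt$reject,
                     error = NA_character_)
      }
    }
  }
  replicates <- do.call(rbind, rep_rows)
  metrics <- .summarize_grid(replicates, grid)
  structure(list(metrics = metrics, replicates = replicates, grid = grid),
            class = "grid_result")
}

.summarize_grid <- function(replicates, grid) {
  keys <- unique(replicates[c("cell", "h2_true", "causal_ratio", "estimator")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- replicates$cell == k$cell & replicates$estimator == k$estimator
    d <- replicates[sel, ]
    failed <- sum(is.na(d$h2))
    d <- d[!is.na(d$h2), ]
    nr <- nrow(d)
    err <- d$h2 - k$h2_true
    bias <- mean(err)
    # divisor-n empirical SE so that mse == bias^2 + emp_se^2 exactly
    emp_se <- if (nr > 1) sqrt(mean((err - bias)^2)) else NA_real_
    data.frame(cell = k$cell, h2_true = k$h2_true,
               causal_ratio = k$causal_ratio, estimator = k$estimator,
               n_replicates = nr, n_failed = failed,
               bias = bias, emp_se = emp_se,
               mean_jack_se = mean(d$se),
               mse = mean(err^2),
               fpr = if (k$h2_true == 0) mean(d$reject) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Relative MSE versus a baseline estimator, with bootstrap CIs
#'
#' Per grid cell, computes `100 * MSE(estimator) / MSE(baseline)` and a
#' percentile bootstrap confidence interval obtained by resampling
#' replicate indices jointly across estimators (preserving their
#' correlation, since all estimators see the same phenotypes).
#'
#' @param result A `grid_result` from [run_grid()].
#' @param baseline Baseline estimator tag (default `"RHE"`).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame: cell, estimator, `rel_mse` (%), `ci_lo`, `ci_hi`.
#' @export
relative_mse <- function(result, baseline = "RHE", n_boot = 10000L,
                         conf = 0.95, seed = 1L) {
  stopifnot(inherits(result, "grid_result"))
  reps <- result$replicates
  if (!baseline %in% reps$estimator)
    stop("baseline estimator '", baseline, "' not present in the results")
  ests <- setdiff(unique(reps$estimator), baseline)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  set.seed(seed)
  out <- list()
  for (ci in unique(reps$cell)) {
    base_d <- reps[reps$cell == ci & reps$estimator == baseline, ]
    base_d <- base_d[order(base_d$replicate), ]
    e_base <- (base_d$h2 - base_d$h2_true)^2
    if (all(is.na(e_base)) || mean(e_base, na.rm = TRUE) == 0)
      stop("baseline MSE is zero or undefined in cell ", ci)
    nr <- nrow(base_d)
    idx <- matrix(sample.int(nr, nr * n_boot, replace = TRUE), nrow = nr)
    for (e in ests) {
      d <- reps[reps$cell == ci & reps$estimator == e, ]
      d <- d[order(d$replicate), ]
      if (!identical(d$replicate, base_d$replicate))
        stop("replicate sets differ between estimators in cell ", ci)
      e_est <- (d$h2 - d$h2_true)^2
      ratio <- 100 * mean(e_est, na.rm = TRUE) / mean(e_base, na.rm = TRUE)
      boot <- 100 * colMeans(matrix(e_est[idx], nrow = nr)) /
        colMeans(matrix(e_base[idx], nrow = nr))
      qs <- stats::quantile(boot, probs, na.rm = TRUE, names = FALSE)
      out[[length(out) + 1L]] <-
        data.frame(cell = ci, h2_true = base_d$h2_true[1],
                   causal_ratio = base_d$causal_ratio[1], estimator = e,
                   rel_mse = ratio, ci_lo = qs[1], ci_hi = qs[2])
    }
  }
  do.call(rbind, out)
}

#' Write a metrics table as tab-separated text
#'
#' Prepends commented header lines recording the grid settings and seed.
#'
#' @param result A `grid_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(result, path) {
  stopifnot(inherits(result, "grid_result"))
  g <- result$grid
  hdr <- c(sprintf("# sumrhe grid: n=%d m=%d n_replicates=%d seed=%d", g$n,
                   g$m, g$n_replicates, g$seed),
           sprintf("# h2={%s} P={%s} mode=%s estimators=%s b=%s runs=%d blocks=%d",
                   paste(g$h2_values, collapse = ","),
                   paste(g$causal_ratios, collapse = ","),
                   g$reference_mode, paste(g$estimators, collapse = ","),
                   g$b, g$n_trace_runs, g$n_blocks))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(result$metrics, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @export
print.grid_result <- function(x, ...) {
  cat("Simulation grid result (", nrow(x$metrics), "cell x estimator rows )\n")
  print(x$metrics, digits = 4)
  invisible(x)
}
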