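# Trace of the squared genetic relatedness matrix K = XX'/M: exact
# (small-scale oracle), stochastic (Hutchinson probes), and the shareable
# "trace summary" rho = (tr(K^2)/N - 1)/N with SNP-block jackknife
# replicates.

#' Exact trace of the squared GRM
#'
#' Computes `tr(K^2)` for `K = X X'/M` without approximation, via the
#' cyclic-trace identity `tr((XX')^2) = tr((X'X)^2) = sum of squared Gram
#' entries`, using whichever Gram matrix (N x N or M x M) is smaller.
#' Intended as a small-scale oracle (forms an `min(N, M)^2` matrix).
#'
#' @param geno A `std_geno` object or bare standardized matrix.
#' @return `tr(K^2)` (scalar).
#' @export
exact_trace_K2 <- function(geno) {
  x <- as_std_matrix(geno)
  m <- ncol(x)
  g <- if (nrow(x) <= m) tcrossprod(x) else crossprod(x)
  sum(g * g) / m^2
}

#' Stochastic (Hutchinson) estimate of the trace of the squared GRM
#'
#' Draws `b` iid standard-normal probe vectors `z` and averages the
#' quadratic forms `z'K'Kz = ||X(X'z)/M||^2`, never forming `K`
#' (cost `O(MNb)`).  Unbiased for `tr(K^2)`; deterministic given `seed`.
#'
#' @param geno A `std_geno` object or bare standardized matrix.
#' @param b Number of probe vectors (>= 1).
#' @param seed Integer RNG seed for the probes.
#' @param probes `"normal"` (default) or `"rademacher"`.
#' @return Estimated `tr(K^2)` (scalar).
#' @export
stochastic_trace_K2 <- function(geno, b = 100L, seed = 1L,
                                probes = c("normal", "rademacher")) {
  if (b < 1) stop("b must be >= 1")
  probes <- match.arg(probes)
  x <- as_std_matrix(geno)
  z <- .draw_probes(nrow(x), b, seed, probes)
  v <- x %*% crossprod(x, z) / ncol(x)   # K z, N x b
  mean(colSums(v^2))
}

.draw_probes <- function(n, b, seed, probes = "normal") {
  set.seed(seed)
  if (probes == "rademacher")
    matrix(sample(c(-1, 1), n * b, replace = TRUE), nrow = n)
  else
    matrix(stats::rnorm(n * b), nrow = n)
}

# Full and leave-one-block-out tr(K^2) with shared probes (stochastic) or
# exactly.  Returns list(trace, trace_jack, plan).  The leave-one-out
# stochastic value is assembled by subtracting the block's contribution
# X_b (X_b' Z) from the accumulated X (X' Z), which is algebraically
# identical to rerunning the same probes on the physically subset panel.
trace_jackknife <- function(geno, n_blocks, b = 100L, seed = 1L,
                            exact = FALSE, probes = "normal") {
  x <- as_std_matrix(geno)
  n <- nrow(x); m <- ncol(x)
  plan <- jackknife_plan(m, n_blocks)
  if (exact) {
    g <- crossprod(x)           # M x M Gram; oracle scale only
    g2 <- g * g
    total <- sum(g2)
    trace <- total / m^2
    tj <- numeric(n_blocks)
    for (k in seq_len(n_blocks)) {
      ix <- block_index(plan, k)
      cross <- sum(g2[ix, , drop = FALSE])
      within <- sum(g2[ix, ix, drop = FALSE])
      mj <- m - plan$sizes[k]
      tj[k] <- (total - 2 * cross + within) / mj^2
    }
    return(list(trace = trace, trace_jack = tj, plan = plan, b = Inf))
  }
  z <- .draw_probes(n, b, seed, probes)
  s <- x %*% crossprod(x, z)    # (XX') Z, N x b
  trace <- mean(colSums((s / m)^2))
  tj <- numeric(n_blocks)
  for (k in seq_len(n_blocks)) {
    ix <- block_index(plan, k)
    xb <- x[, ix, drop = FALSE]
    u <- xb %*% crossprod(xb, z)
    mj <- m - plan$sizes[k]
    tj[k] <- mean(colSums(((s - u) / mj)^2))
  }
  list(trace = trace, trace_jack = tj, plan = plan, b = b)
}

new_trace_summary <- function(n_ref, m, b_total, rho, blocks, digest) {
  stopifnot(is.data.frame(blocks),
            all(c("block_index", "m_block", "rho_jack") %in% names(blocks)))
  if (sum(blocks$m_block) != m)
    stop("block SNP counts do not sum to M (", sum(blocks$m_block), " != ", m, ")")
  structure(list(n_ref = as.integer(n_ref), m = as.integer(m),
                 b_total = b_total, rho = rho, blocks = blocks,
                 snp_digest = digest),
            class = "trace_summary")
}

#' Build a shareable trace summary from reference genotypes
#'
#' Computes the population LD statistic `rho = (tr(K^2)/N - 1)/N` on the
#' reference panel, together with one leave-one-block-out replicate
#' `rho_jack` per contiguous SNP block (block `k` excluded from `X` and
#' `M` replaced by `M - m_k` throughout, reusing the same probe vectors).
#' The result is the artifact a reference-panel holder releases: it
#' contains no individual-level data and, combined with GWAS summary
#' statistics from a target sample of the same population, suffices to
#' reconstruct the randomized HE heritability estimate.
#'
#' @param geno Reference panel (`std_geno` or standardized matrix).
#' @param b Probe vectors for the stochastic trace; `b = Inf` computes the
#'   exact trace instead (oracle mode, small panels only).
#' @param n_blocks Number of jackknife blocks (2..M).
#' @param seed Integer RNG seed.
#' @param snp_ids SNP identifiers used for the integrity digest (defaults
#'   to those stored in `geno`).
#' @return A `trace_summary`: `n_ref`, `m`, `b_total` (0 denotes exact
#'   mode), `rho`, `blocks` (data frame `block_index`, `m_block`,
#'   `rho_jack`), `snp_digest`.
#' @export
make_trace_summary <- function(geno, b = 100L, n_blocks = 100L, seed = 1L,
                               snp_ids = NULL) {
  x <- as_std_matrix(geno)
  ids <- snp_ids %||% (if (inherits(geno, "std_geno")) geno$snp_ids
                       else sprintf("snp%d", seq_len(ncol(x))))
  n <- nrow(x)
  exact <- is.infinite(b)
  tk <- trace_jackknife(x, n_blocks = n_blocks, b = if (exact) 1L else b,
                        seed = seed, exact = exact)
  rho <- (tk$trace / n - 1) / n
  rho_jack <- (tk$trace_jack / n - 1) / n
  blocks <- data.frame(block_index = seq_len(n_blocks),
                       m_block = tk$plan$sizes, rho_jack = rho_jack)
  new_trace_summary(n, ncol(x), b_total = if (exact) 0 else b,
                    rho = rho, blocks = blocks, digest = snp_digest(ids))
}

#' Aggregate trace summaries from independent runs
#'
#' Pools runs made on the same panel with independent probe seeds by
#' `b`-weighted averaging of `rho` and each `rho_jack`; equivalent in
#' expectation to a single run with the summed probe count.
#'
#' @param summaries List of `trace_summary` objects sharing `n_ref`, `m`,
#'   block structure and SNP digest.
#' @return A pooled `trace_summary` with `b_total` summed.
#' @export
aggregate_trace_runs <- function(summaries) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, logical(1), "trace_summary")))
  ref <- summaries[[1]]
  for (s in summaries[-1]) {
    if (s$n_ref != ref$n_ref || s$m != ref$m ||
        !identical(s$blocks$m_block, ref$blocks$m_block))
      stop("incompatible trace summaries: n_ref/m/block structure differ")
    if (s$snp_digest != ref$snp_digest)
      stop("incompatible trace summaries: SNP digests differ")
    if (s$b_total == 0 || ref$b_total == 0)
      stop("cannot aggregate exact-mode trace summaries")
  }
  w <- vapply(summaries, `[[`, numeric(1), "b_total")
  rho <- sum(w * vapply(summaries, `[[`, numeric(1), "rho")) / sum(w)
  rj <- sapply(summaries, function(s) s$blocks$rho_jack)
  rho_jack <- drop(rj %*% w) / sum(w)
  blocks <- data.frame(block_index = ref$blocks$block_index,
                       m_block = ref$blocks$m_block, rho_jack = rho_jack)
  new_trace_summary(ref$n_ref, ref$m, sum(w), rho, blocks, ref$snp_digest)
}

#' Write a trace summary to its text format
#'
#' Header lines `#VERSION 1`, `#NREF`, `#M`, `#B`, `#RHO`, `#SNP_DIGEST`,
#' then one `block_index m_block rho_jack` line per block.  Real values
#' are written with 17 significant digits so the round trip through
#' [read_trace()] is bit-exact.
#'
#' @param ts A `trace_summary`.
#' @param path Output path (conventionally `*.trace`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(ts, path) {
  stopifnot(inherits(ts, "trace_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#VERSION 1",
               sprintf("#NREF %d", ts$n_ref),
               sprintf("#M %d", ts$m),
               sprintf("#B %d", as.integer(ts$b_total)),
               sprintf("#RHO %.17g", ts$rho),
               sprintf("#SNP_DIGEST %s", ts$snp_digest)), con)
  writeLines(sprintf("%d %d %.17g", ts$blocks$block_index,
                     ts$blocks$m_block, ts$blocks$rho_jack), con)
  invisible(path)
}

#' Read a trace summary file
#'
#' @param path File path.
#' @param expect_digest Optional SNP digest (e.g. computed from a `.bim`
#'   id list) to validate against.
#' @param strict If `TRUE` (default) a digest mismatch is an error,
#'   otherwise a warning.
#' @return A `trace_summary`.
#' @export
read_trace <- function(path, expect_digest = NULL, strict = TRUE) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, " "))]
    if (length(ln) != 1) stop("trace file missing header field #", key)
    sub(paste0("^#", key, " "), "", ln)
  }
  if (get("VERSION") != "1") stop("unsupported trace file version: ", get("VERSION"))
  n_ref <- as.integer(get("NREF"))
  m <- as.integer(get("M"))
  b_total <- as.numeric(get("B"))
  rho <- as.numeric(get("RHO"))
  digest <- get("SNP_DIGEST")
  parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  if (is.null(parts) || ncol(parts) != 3)
    stop("malformed block lines in trace file")
  blocks <- data.frame(block_index = as.integer(parts[, 1]),
                       m_block = as.integer(parts[, 2]),
                       rho_jack = as.numeric(parts[, 3]))
  if (sum(blocks$m_block) != m)
    stop("block SNP counts do not sum to M (", sum(blocks$m_block), " != ", m, ")")
  if (!is.null(expect_digest) && expect_digest != digest) {
    msg <- paste0("SNP digest mismatch: file has ", digest,
                  ", expected ", expect_digest)
    if (strict) stop(msg) else warning(msg)
  }
  new_trace_summary(n_ref, m, b_total, rho, blocks, digest)
}

#' @export
print.trace_summary <- function(x, ...) {
  cat("Trace summary: N_ref =", x$n_ref, ", M =", x$m,
      ", B =", if (x$b_total == 0) "exact" else x$b_total,
      ", rho =", format(x$rho, digits = 6),
      ", blocks =", nrow(x$blocks), "\n")
  invisible(x)
}
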