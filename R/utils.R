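#' @keywords internal
"_PACKAGE"

# Polynomial rolling hash of a character vector, mod 2^31 - 1.
# Used as an integrity digest for SNP id lists in trace-summary files;
# not cryptographic.  Deterministic across platforms (pure integer
# arithmetic kept exact in doubles, < 2^53).
snp_digest <- function(ids) {
  stopifnot(is.character(ids))
  p <- 2147483647
  h <- 0
  codes <- utf8ToInt(paste(ids, collapse = "\x1f"))
  for (c in codes) h <- (h * 131 + c) %% p
  sprintf("%08x", h)
}

# Contiguous SNP-block jackknife plan: floor(M/n_blocks) SNPs per block,
# remainder appended to the last block.
jackknife_plan <- function(m, n_blocks) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (n_blocks > m) stop("n_blocks (", n_blocks, ") exceeds SNP count (", m, ")")
  base <- m %/% n_blocks
  sizes <- rep(base, n_blocks)
  sizes[n_blocks] <- sizes[n_blocks] + m - base * n_blocks
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  structure(list(n_blocks = n_blocks, m = m, sizes = sizes,
                 starts = starts, ends = ends),
            class = "jackknife_plan")
}

block_index <- function(plan, b) seq.int(plan$starts[b], plan$ends[b])

# Resolve either a standardized-genotype object or a bare numeric matrix
# (assumed already column-standardized) to the matrix.
as_std_matrix <- function(x) {
  if (inherits(x, "std_geno")) return(x$matrix)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a 'std_geno' object or a numeric matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
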