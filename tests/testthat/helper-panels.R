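# Shared fixtures: all synthetic, generated in code at test time.

make_std <- function(n, m, seed = 1L, maf_low = 0.05, maf_high = 0.5) {
  standardize(simulate_genotypes(n, m, maf_low, maf_high, seed = seed))
}

# A tiny hand-specifiable panel from an explicit call matrix.
panel_from_matrix <- function(calls) {
  n <- nrow(calls); m <- ncol(calls)
  samples <- data.frame(fid = sprintf("F%d", 1:n), iid = sprintf("I%d", 1:n))
  snps <- data.frame(chrom = rep("1", m), id = sprintf("s%d", 1:m), cm = 0,
                     pos = 1:m, a1 = rep("A", m), a2 = rep("C", m))
  colnames(calls) <- snps$id
  sumrhe:::new_genotype_panel(calls, samples, snps)
}

# Brute-force tr(K^2): explicitly form K and sum squared entries.
brute_trace_K2 <- function(x) {
  k <- tcrossprod(x) / ncol(x)
  sum(k * k)
}
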