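# Shared fixtures and independent brute-force oracles.

# tiny 4-tissue fate map: two super-nodes nested in two germ layers
toy_fatemap <- function() {
  tree <- ape::read.tree(text = "(((t1:1,t2:1)SN1:1)GL1:1,((t3:1,t4:1)SN2:1)GL2:1)Root;")
  fatemap(tree, germ_layer_nodes = c("GL1", "GL2"),
          super_nodes = c("SN1", "SN2"))
}

# deterministic small expression matrix
toy_expression <- function(n_genes = 8, tissues = c("t1", "t2", "t3")) {
  set.seed(99)
  mat <- matrix(round(2^stats::rnorm(n_genes * length(tissues), 6, 1), 3),
                n_genes, length(tissues),
                dimnames = list(sprintf("g%02d", seq_len(n_genes)), tissues))
  expression_matrix(mat)
}

small_synthetic <- function(seed = 1, ...) {
  synthetic_spec(n_genes = 400L, n_modules = 20L, module_size = 20L,
                 n_conserved = 2L, n_divergent = 2L, n_correlated = 2L,
                 seed = seed, ...)
}

# Exhaustive hypergeometric oracle: enumerate all C(N_u, n_int) draws from
# a universe whose first m elements are the module, count draws with >= k
# overlap. Independent of stats::phyper.
hypergeom_oracle <- function(k, n_int, m, N_u) {
  if (n_int == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N_u, n_int)
  overlap <- colSums(draws <= m)
  mean(overlap >= k)
}

# Exhaustive two-sample KS oracle: condition on the pooled values, enumerate
# all C(n+m, n) assignments to the first sample, compute the KS statistic for
# each, and return the tail probability P(D >= D_obs). Assumes untied values.
ks_oracle <- function(x, y) {
  pooled <- sort(c(x, y))
  n <- length(x); m <- length(y)
  stat <- function(a, b) {
    grid <- sort(c(a, b))
    max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), 0)))
  }
  d_obs <- stat(x, y)
  picks <- utils::combn(n + m, n)
  d_all <- apply(picks, 2, function(ix) stat(pooled[ix], pooled[-ix]))
  mean(d_all >= d_obs - 1e-12)
}
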