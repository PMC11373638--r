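## Shared fixtures built in code. Everything is seeded so the suite is
## deterministic.

## small complete genotype matrix with arbitrary but valid map
toy_geno <- function(n = 20, m = 50, seed = 1, p = NULL) {
  set.seed(seed)
  p <- p %||% runif(m, 0.05, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  genotype_matrix(d, chrom = rep("1", m), pos_bp = seq_len(m) * 1000L,
                  individual_ids = sprintf("i%03d", seq_len(n)),
                  snp_ids = sprintf("s%03d", seq_len(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## do two compact-letter-display strings share any letter?
shares_letters <- function(a, b)
  length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0

## desk-scale founder pool reused by several simulation tests
small_pool <- function(n = 60, chr = 3, snps = 40, seed = 5, ...) {
  generate_founder_pool(n, n_chromosomes = chr, n_snp_per_chromosome = snps,
                        seed = seed, ...)
}

## the scaled-down founder-number x heritability experiment is expensive
## (~2.5 min), so acceptance tests that look at different aspects of the
## same study conditions share one cached run
.exp_cache <- new.env(parent = emptyenv())
acceptance_experiment <- function() {
  if (is.null(.exp_cache$vt)) {
    pool <- generate_founder_pool(200, n_chromosomes = 21,
                                  n_snp_per_chromosome = 50, seed = 11)
    .exp_cache$pool <- pool
    .exp_cache$vt <- run_syn_experiment(pool, iterations = 25, seed = 101)
  }
  .exp_cache$vt
}
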