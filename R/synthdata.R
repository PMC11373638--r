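#' Generate a synthetic founder pool
#'
#' Creates a phased diploid population that emulates a GBS-genotyped breeding
#' pool: biallelic SNPs on a configurable number of chromosomes, allele
#' frequencies drawn from a Beta-family sampler folded to the minor allele,
#' and haplotypes in Hardy-Weinberg proportions at every locus. By default
#' loci are drawn site-independently (no ancestral LD); the optional
#' `ld_blocks` mode copies haplotype blocks from a small set of ancestral
#' haplotypes, which plants strong local LD for imputation and LD-decay
#' analyses.
#'
#' Minor allele frequencies are sampled as `0.5 * Beta(a, b)` with `a =
#' maf_shape` and `b` solved so that the expected MAF equals `target_maf`,
#' giving an L-shaped frequency spectrum typical of GBS SNP panels. The
#' defaults (21 chromosomes, 649 SNPs each, mean MAF 0.22) mirror a
#' hexaploid wheatgrass panel genotyped and modelled as diploid dosages.
#'
#' @param n_individuals Number of diploid founders.
#' @param n_chromosomes Number of chromosomes (default 21).
#' @param n_snp_per_chromosome SNPs per chromosome (default 649).
#' @param target_maf Expected minor allele frequency of the sampler
#'   (default 0.22).
#' @param maf_shape First Beta shape parameter of the MAF sampler.
#' @param chrom_length_cm Genetic map length per chromosome in centiMorgans
#'   (default 150, a typical grass-genome scale).
#' @param chrom_length_bp Physical length per chromosome in base pairs
#'   (default 1e8).
#' @param ld_blocks `NULL` for site-independent loci, or a list with
#'   elements `block_size` (consecutive SNPs per block) and `n_haplotypes`
#'   (ancestral haplotypes each block is copied from).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A [haplotype_population()] with `generation = 0`.
#' @examples
#' pool <- generate_founder_pool(50, n_chromosomes = 3,
#'                               n_snp_per_chromosome = 40, seed = 1)
#' mean(maf(as_genotype_matrix(pool)))
#' @export
generate_founder_pool <- function(n_individuals,
                                  n_chromosomes = 21,
                                  n_snp_per_chromosome = 649,
                                  target_maf = 0.22,
                                  maf_shape = 1,
                                  chrom_length_cm = 150,
                                  chrom_length_bp = 1e8,
                                  ld_blocks = NULL,
                                  seed = NULL) {
  if (n_individuals < 1 || n_chromosomes < 1 || n_snp_per_chromosome < 1)
    stop("all counts must be positive")
  if (target_maf <= 0 || target_maf > 0.5)
    stop("`target_maf` must lie in (0, 0.5]")
  if (maf_shape <= 0) stop("`maf_shape` must be positive")
  chrom_length_cm <- rep_len(chrom_length_cm, n_chromosomes)
  chrom_length_bp <- rep_len(chrom_length_bp, n_chromosomes)

  with_seed(seed, {
    L <- n_chromosomes * n_snp_per_chromosome
    q <- sample_maf(L, target_maf, maf_shape)
    chrom <- rep(sprintf("chr%02d", seq_len(n_chromosomes)),
                 each = n_snp_per_chromosome)
    pos_bp <- unlist(lapply(seq_len(n_chromosomes), function(c) {
      sort(sample.int(chrom_length_bp[c], n_snp_per_chromosome))
    }), use.names = FALSE)
    ## genetic positions follow physical ones through a linear map, which
    ## keeps the two orderings consistent
    pos_cm <- unlist(lapply(seq_len(n_chromosomes), function(c) {
      j <- ((c - 1) * n_snp_per_chromosome + 1):(c * n_snp_per_chromosome)
      chrom_length_cm[c] * pos_bp[j] / chrom_length_bp[c]
    }), use.names = FALSE)
    map <- data.frame(snp_id = sprintf("c%02d_s%04d",
                                       rep(seq_len(n_chromosomes),
                                           each = n_snp_per_chromosome),
                                       rep(seq_len(n_snp_per_chromosome),
                                           n_chromosomes)),
                      chrom = chrom, pos_bp = pos_bp, pos_cm = pos_cm,
                      stringsAsFactors = FALSE)

    nh <- 2L * n_individuals
    if (is.null(ld_blocks)) {
      H <- matrix(rbinom(nh * L, 1L, rep(q, each = nh)), nh, L)
    } else {
      bs <- ld_blocks$block_size %||% 10L
      na <- ld_blocks$n_haplotypes %||% 4L
      H <- matrix(0L, nh, L)
      for (start in seq(1L, L, by = bs)) {
        j <- start:min(start + bs - 1L, L)
        ## a block never spans two chromosomes
        j <- j[chrom[j] == chrom[start]]
        anc <- matrix(rbinom(na * length(j), 1L, rep(q[j], each = na)),
                      na, length(j))
        H[, j] <- anc[sample.int(na, nh, replace = TRUE), , drop = FALSE]
      }
    }
    odd <- seq(1L, nh, by = 2L)
    haplotype_population(H[odd, , drop = FALSE], H[odd + 1L, , drop = FALSE],
                         map,
                         chrom_length_cm = setNames(chrom_length_cm,
                                                    unique(chrom)),
                         generation = 0L)
  })
}

## MAF ~ 0.5 * Beta(a, b), b solved so that E[MAF] = target
sample_maf <- function(n, target, shape) {
  mean_unit <- 2 * target              # mean of the Beta on (0, 1)
  if (mean_unit >= 1) return(rep(0.5, n))
  b <- shape * (1 - mean_unit) / mean_unit
  0.5 * rbeta(n, shape, b)
}

#' Degrade a complete genotype matrix to GBS-like missingness
#'
#' Masks entries of a complete dosage matrix at the given rates, emulating
#' the sparse calls of genotyping-by-sequencing before filtering and
#' imputation. The positions and true dosages of the masked cells are
#' recorded in the `masked` element of the result so imputation accuracy can
#' be measured.
#'
#' @param geno A complete (no missing cells) [genotype_matrix()].
#' @param per_snp_missing_rate Per-SNP missingness probability in `[0, 1)`;
#'   scalar or one value per SNP.
#' @param per_individual_missing_rate Additional per-individual missingness
#'   probability in `[0, 1)`; scalar or one value per individual. A cell is
#'   masked if either process hits it.
#' @param seed Optional integer seed.
#'
#' @return A `genotype_matrix` with `NA` at masked cells, plus an extra
#'   element `masked`: a data frame with columns `row`, `col`,
#'   `individual_id`, `snp_id`, `dosage_true`.
#' @export
degrade_to_gbs <- function(geno, per_snp_missing_rate,
                           per_individual_missing_rate = 0, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$dosage))
    stop("`geno` must be complete (no missing calls) before degradation")
  n <- nrow(geno$dosage); m <- ncol(geno$dosage)
  rs <- rep_len(per_snp_missing_rate, m)
  ri <- rep_len(per_individual_missing_rate, n)
  if (any(rs < 0 | rs >= 1) || any(ri < 0 | ri >= 1))
    stop("missingness rates must lie in [0, 1)")
  with_seed(seed, {
    p <- 1 - outer(1 - ri, 1 - rs)     # cell-wise union of the two processes
    mask <- matrix(runif(n * m) < p, n, m)
    d <- geno$dosage
    idx <- which(mask, arr.ind = TRUE)
    masked <- data.frame(row = idx[, 1L], col = idx[, 2L],
                         individual_id = rownames(d)[idx[, 1L]],
                         snp_id = colnames(d)[idx[, 2L]],
                         dosage_true = d[mask],
                         stringsAsFactors = FALSE)
    d[mask] <- NA
    out <- genotype_matrix(d, geno$map$chrom, geno$map$pos_bp,
                           geno$map$pos_cm,
                           individual_ids = rownames(d),
                           snp_ids = geno$map$snp_id)
    out$masked <- masked
    out
  })
}

#' Simulate multi-year phenotypes for an additive trait
#'
#' One record per individual and year:
#' `value = genetic value + year effect + Normal(0, var_e)`, with the
#' genetic value (which includes the trait intercept) given by
#' [genetic_values()] and `var_e` taken from the trait architecture,
#' optionally rescaled.
#'
#' @param pop A [haplotype_population()] or complete [genotype_matrix()].
#' @param trait A [trait_architecture()] defined on `pop`'s loci.
#' @param years Number of evaluation years (default 2).
#' @param year_effects Additive fixed year shifts, one per year
#'   (default all zero).
#' @param error_scale Positive multiplier applied to the trait's error
#'   variance (default 1).
#' @param trait_name Label written to the `trait` column.
#' @param seed Optional integer seed.
#'
#' @return Data frame with columns `genotype_id`, `year`, `trait`, `value`.
#' @export
generate_phenotypes <- function(pop, trait, years = 2, year_effects = NULL,
                                error_scale = 1, trait_name = "trait1",
                                seed = NULL) {
  if (years < 1) stop("`years` must be at least 1")
  if (error_scale < 0) stop("`error_scale` must be non-negative")
  year_effects <- year_effects %||% rep(0, years)
  if (length(year_effects) != years)
    stop("`year_effects` must have one entry per year")
  g <- genetic_values(pop, trait)
  ids <- names(g)
  n <- length(g)
  ve <- trait$var_e * error_scale
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(years), function(y) {
      data.frame(genotype_id = ids, year = y, trait = trait_name,
                 value = g + year_effects[y] + rnorm(n, 0, sqrt(ve)),
                 stringsAsFactors = FALSE)
    }))
  })
}
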