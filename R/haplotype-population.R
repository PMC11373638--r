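#' Phased diploid population over mapped loci
#'
#' The simulator's state for one generation: two haplotype matrices
#' (individuals x loci, alleles coded 0/1) plus a locus map with genetic and
#' physical positions. `generation` is 0 for the founder/parent pool and
#' 1, 2, ... for SYN1, SYN2, ...
#'
#' @param H1,H2 Integer 0/1 matrices of identical dimension, one row per
#'   individual, one column per locus.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos_bp`, `pos_cm`,
#'   sorted by chromosome then position.
#' @param chrom_length_cm Named numeric vector of genetic map length (cM) per
#'   chromosome; defaults to the last mapped locus of each chromosome.
#' @param generation Non-negative integer generation index.
#'
#' @return An object of class `haplotype_population`.
#' @seealso [generate_founder_pool()], [advance_generation()],
#'   [as_genotype_matrix()]
#' @export
haplotype_population <- function(H1, H2, map, chrom_length_cm = NULL,
                                 generation = 0L) {
  H1 <- as.matrix(H1); H2 <- as.matrix(H2)
  if (!identical(dim(H1), dim(H2)))
    stop("H1 and H2 must have identical dimensions")
  if (ncol(H1) != nrow(map)) stop("map must have one row per locus")
  if (anyNA(H1) || anyNA(H2))
    stop("both haplotypes must be defined at every locus")
  if (!all(H1 %in% c(0L, 1L)) || !all(H2 %in% c(0L, 1L)))
    stop("haplotype alleles must be 0/1")
  need <- c("snp_id", "chrom", "pos_bp", "pos_cm")
  if (!all(need %in% names(map)))
    stop("map must have columns ", paste(need, collapse = ", "))
  map$chrom <- as.character(map$chrom)
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$pos_cm[map$chrom == ch]) ||
        is.unsorted(map$pos_bp[map$chrom == ch], strictly = TRUE))
      stop("map positions must be sorted within chromosome ", ch)
  }
  if (is.null(chrom_length_cm)) {
    chrom_length_cm <- tapply(map$pos_cm, map$chrom, max)
    chrom_length_cm <- chrom_length_cm[unique(map$chrom)]
  }
  structure(list(H1 = H1, H2 = H2, map = map,
                 chrom_length_cm = chrom_length_cm,
                 generation = as.integer(generation)),
            class = "haplotype_population")
}

#' @export
print.haplotype_population <- function(x, ...) {
  cat(sprintf("haplotype_population: %d diploid individuals, %d loci on %d chromosome(s) [%s]\n",
              nrow(x$H1), ncol(x$H1), length(unique(x$map$chrom)),
              generation_label(x)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A [haplotype_population()].
#' @return Integer count.
#' @export
n_individuals <- function(pop) nrow(pop$H1)

generation_label <- function(pop) {
  if (pop$generation == 0L) "P" else sprintf("SYN%d", pop$generation)
}

#' Subset individuals of a population
#'
#' @param pop A [haplotype_population()].
#' @param idx Individual indices to keep.
#' @return A `haplotype_population` with the selected individuals, same map
#'   and generation.
#' @export
subset_population <- function(pop, idx) {
  haplotype_population(pop$H1[idx, , drop = FALSE],
                       pop$H2[idx, , drop = FALSE],
                       pop$map, pop$chrom_length_cm, pop$generation)
}

#' Collapse phased haplotypes to unphased dosages
#'
#' @param pop A [haplotype_population()].
#' @param individual_ids Optional ids; default combines the generation label
#'   with a running index.
#' @return A [genotype_matrix()] of 0/1/2 dosages.
#' @export
as_genotype_matrix <- function(pop, individual_ids = NULL) {
  stopifnot(inherits(pop, "haplotype_population"))
  d <- pop$H1 + pop$H2
  if (is.null(individual_ids))
    individual_ids <- sprintf("%s_%05d", generation_label(pop),
                              seq_len(nrow(d)))
  genotype_matrix(d, pop$map$chrom, pop$map$pos_bp, pop$map$pos_cm,
                  individual_ids = individual_ids, snp_ids = pop$map$snp_id)
}
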