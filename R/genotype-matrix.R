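#' Genotype matrix of biallelic SNP dosages
#'
#' Container for an individuals-by-SNPs matrix of alternate-allele dosages
#' (0, 1, 2; `NA` = missing call) together with per-SNP chromosome, physical
#' position and optional genetic position.
#'
#' @param dosage Numeric or integer matrix, individuals in rows, SNPs in
#'   columns. Values must be 0, 1, 2 or `NA`.
#' @param chrom Character or integer vector of per-SNP chromosome labels.
#' @param pos_bp Integer vector of per-SNP physical positions (bp, 1-based),
#'   strictly increasing within each chromosome.
#' @param pos_cm Optional numeric vector of genetic positions (cM),
#'   non-decreasing within each chromosome.
#' @param individual_ids,snp_ids Row and column identifiers; defaults are
#'   taken from `dimnames(dosage)` or generated.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (the matrix, with dimnames set) and `map` (a data frame with
#'   columns `snp_id`, `chrom`, `pos_bp` and, when supplied, `pos_cm`).
#' @seealso [filter_genotypes()], [ld_knni_impute()], [read_vcf()]
#' @export
genotype_matrix <- function(dosage, chrom, pos_bp, pos_cm = NULL,
                            individual_ids = rownames(dosage),
                            snp_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  n <- nrow(dosage)
  if (m == 0L || n == 0L) stop("empty genotype matrix")
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA; found ",
                     dosage[which(bad)[1L]])
  if (length(chrom) != m) stop("`chrom` must have one entry per SNP")
  if (length(pos_bp) != m) stop("`pos_bp` must have one entry per SNP")
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (is.null(individual_ids)) individual_ids <- sprintf("ind_%04d", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%05d", seq_len(m))
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  for (ch in unique(chrom)) {
    p <- pos_bp[chrom == ch]
    if (any(diff(p) <= 0))
      stop("physical positions must be strictly increasing within chromosome ", ch)
    if (!is.null(pos_cm)) {
      g <- pos_cm[chrom == ch]
      if (any(diff(g) < 0))
        stop("genetic positions must be non-decreasing within chromosome ", ch)
    }
  }
  dimnames(dosage) <- list(individual_ids, snp_ids)
  map <- data.frame(snp_id = snp_ids, chrom = chrom, pos_bp = pos_bp,
                    stringsAsFactors = FALSE)
  if (!is.null(pos_cm)) map$pos_cm <- as.numeric(pos_cm)
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(d), ncol(d), length(unique(x$map$chrom))))
  miss <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%   mean MAF: %.3f\n",
              100 * miss, mean(maf(x), na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i,j Individual (row) and SNP (column) indices.
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  d <- x$dosage[i, j, drop = FALSE]
  map <- x$map[j, , drop = FALSE]
  genotype_matrix(d, map$chrom, map$pos_bp, map$pos_cm,
                  individual_ids = rownames(d), snp_ids = map$snp_id)
}

#' Allele frequencies and minor allele frequencies
#'
#' `allele_freq()` returns per-SNP alternate-allele frequencies computed on
#' non-missing calls; `maf()` folds them to the minor allele.
#'
#' @param geno A [genotype_matrix()].
#' @return Named numeric vector, one value per SNP (NaN where no calls).
#' @export
allele_freq <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
maf <- function(geno) {
  p <- allele_freq(geno)
  pmin(p, 1 - p)
}

## per-individual fraction of SNPs with a called genotype
call_rate <- function(geno) rowMeans(!is.na(geno$dosage))

## per-SNP fraction of individuals with a missing call
snp_missingness <- function(geno) colMeans(is.na(geno$dosage))
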