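#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF (v4.x) with `vcfR` and converts GT fields to alternate-allele
#' dosages. Only biallelic SNP records are kept; multi-allelic sites are
#' skipped with a message reporting the count. Missing genotypes (`./.`,
#' `.|.` or `.`) become `NA`.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [genotype_matrix()]. SNP ids come from the ID column, falling
#'   back to `chrom_pos` where ID is `.`.
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message("skipping ", sum(multi), " multi-allelic site(s)")
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no biallelic sites in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  d <- matrix(codes[gt], nrow(gt), ncol(gt))
  missing_gt <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  unparsed <- is.na(d) & !missing_gt
  if (any(unparsed)) {
    w <- which(unparsed, arr.ind = TRUE)[1L, ]
    stop("cannot parse genotype '", gt[unparsed][1L], "' at record ",
         keep[w[1L]], " (", fix[w[1L], "CHROM"], ":", fix[w[1L], "POS"], ")")
  }
  ids <- fix[, "ID"]
  fallback <- is.na(ids) | ids == "."
  ids[fallback] <- paste0(fix[fallback, "CHROM"], "_", fix[fallback, "POS"])
  genotype_matrix(t(d), chrom = fix[, "CHROM"],
                  pos_bp = as.integer(fix[, "POS"]),
                  individual_ids = colnames(gt), snp_ids = ids)
}

#' Write a genotype matrix as an uncompressed VCF v4.2 file
#'
#' Dosages become unphased GT calls (`0/0`, `0/1`, `1/1`, `./.` for
#' missing). The alleles themselves are not tracked by [genotype_matrix()],
#' so REF/ALT are written as placeholder `A`/`T`; a round trip preserves
#' dosages, ids, chromosomes and positions.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  d <- geno$dosage
  body <- vapply(seq_len(ncol(d)), function(j) {
    calls <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1L])
    paste(c(geno$map$chrom[j], geno$map$pos_bp[j], geno$map$snp_id[j],
            "A", "T", ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=synpop",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write dosage matrices, genetic maps and phenotypes as TSV
#'
#' The dosage TSV has individuals in rows (first column `individual_id`) and
#' SNPs in columns, missing as `NA`. The genetic map TSV has columns
#' `snp_id`, `chrom`, `pos_bp` and optionally `pos_cm`. The phenotype TSV
#' has columns `genotype_id`, `year`, `trait`, `value`.
#'
#' @param geno A [genotype_matrix()].
#' @param path File path.
#' @param map_path Path of the genetic map TSV accompanying a dosage TSV.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name genio_tsv
NULL

#' @rdname genio_tsv
#' @export
write_dosage_tsv <- function(geno, path, map_path = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(individual_id = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path))
    write.table(geno$map, map_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' @rdname genio_tsv
#' @export
read_dosage_tsv <- function(path, map_path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  map <- read.table(map_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(colnames(d), as.character(map$snp_id)))
    stop("dosage columns do not match the genetic map SNP ids")
  genotype_matrix(d, map$chrom, map$pos_bp, map$pos_cm,
                  individual_ids = df$individual_id, snp_ids = map$snp_id)
}

#' @rdname genio_tsv
#' @export
write_phenotype_tsv <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genio_tsv
#' @export
read_phenotype_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Filter individuals and SNPs of a genotype matrix
#'
#' Applies the standard GBS quality filters in a fixed order: first
#' individuals by call rate, then SNPs by missingness, then SNPs by minor
#' allele frequency computed on the retained individuals. The defaults are
#' the conventional thresholds for GBS SNP panels: MAF >= 3%, per-SNP
#' missingness <= 10%, per-individual call rate >= 80%.
#'
#' @param geno A [genotype_matrix()].
#' @param min_maf Minimum minor allele frequency (kept if `maf >= min_maf`).
#' @param max_snp_missing Maximum per-SNP missing proportion (removed if
#'   missingness `> max_snp_missing`).
#' @param min_call_rate Minimum per-individual call rate (discarded if
#'   `< min_call_rate`).
#' @return List with elements `geno` (the filtered [genotype_matrix()]) and
#'   `report` (class `filter_report`: counts removed at each step and the
#'   thresholds used).
#' @export
filter_genotypes <- function(geno, min_maf = 0.03, max_snp_missing = 0.10,
                             min_call_rate = 0.80) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (any(c(min_maf, max_snp_missing, min_call_rate) < 0) ||
      any(c(min_maf, max_snp_missing, min_call_rate) > 1))
    stop("all thresholds must lie in [0, 1]")
  n0 <- nrow(geno$dosage); m0 <- ncol(geno$dosage)

  keep_ind <- call_rate(geno) >= min_call_rate
  if (!any(keep_ind)) stop("no individuals pass the call-rate filter")
  g1 <- geno[keep_ind, ]

  keep_miss <- snp_missingness(g1) <= max_snp_missing
  if (!any(keep_miss)) stop("no SNPs pass the missingness filter")
  g2 <- g1[, keep_miss]

  mafs <- maf(g2)
  keep_maf <- !is.nan(mafs) & mafs >= min_maf
  if (!any(keep_maf)) stop("no SNPs pass the MAF filter")
  g3 <- g2[, keep_maf]

  report <- structure(list(
    n_individuals_in = n0, n_snps_in = m0,
    individuals_removed_call_rate = sum(!keep_ind),
    snps_removed_missingness = sum(!keep_miss),
    snps_removed_maf = sum(!keep_maf),
    n_individuals_out = nrow(g3$dosage), n_snps_out = ncol(g3$dosage),
    thresholds = list(min_maf = min_maf, max_snp_missing = max_snp_missing,
                      min_call_rate = min_call_rate)),
    class = "filter_report")
  list(geno = g3, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "filter_report: %d x %d -> %d x %d\n",
    "  individuals removed (call rate < %g): %d\n",
    "  SNPs removed (missingness > %g): %d\n",
    "  SNPs removed (MAF < %g): %d\n"),
    x$n_individuals_in, x$n_snps_in, x$n_individuals_out, x$n_snps_out,
    x$thresholds$min_call_rate, x$individuals_removed_call_rate,
    x$thresholds$max_snp_missing, x$snps_removed_missingness,
    x$thresholds$min_maf, x$snps_removed_maf))
  invisible(x)
}

#' LD-kNN imputation of missing genotype dosages
#'
#' For each missing cell (individual i, SNP s): the `l` markers in highest
#' LD (squared dosage correlation on pairwise-complete individuals) with s
#' are selected; the distance from i to every individual with a call at s is
#' the mean per-site absolute dosage difference over those markers (sites
#' missing in either individual are ignored); the dosage is imputed as the
#' 1/distance-weighted mean of the `k` nearest such individuals' dosages at
#' s, rounded to the nearest integer in 0..2. Observed cells are never
#' altered.
#'
#' A zero distance (an identical neighbor) is given weight `1/1e-6`; ties in
#' neighbor ranking are broken by individual index for determinism. A SNP
#' with no observed calls at all is left missing and reported.
#'
#' @param geno A [genotype_matrix()] with missing entries.
#' @param l Number of high-LD markers used for the distance (default 30).
#' @param k Number of nearest neighbors averaged (default 10).
#' @return A [genotype_matrix()]; the ids of SNPs that could not be imputed
#'   (no observed calls) are attached as attribute `"unimputed"`.
#' @export
ld_knni_impute <- function(geno, l = 30, k = 10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (l < 1 || k < 1) stop("`l` and `k` must be at least 1")
  d <- geno$dosage
  if (!anyNA(d)) return(geno)
  r2 <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
  out <- d
  unimputed <- character(0)
  for (s in which(colSums(is.na(d)) > 0L)) {
    obs <- which(!is.na(d[, s]))
    if (length(obs) == 0L) {
      unimputed <- c(unimputed, colnames(d)[s])
      next
    }
    r <- r2[, s]
    r[s] <- NA
    cand <- which(!is.na(r))
    lsel <- cand[order(-r[cand], cand)][seq_len(min(l, length(cand)))]
    X <- d[obs, lsel, drop = FALSE]
    for (i in which(is.na(d[, s]))) {
      diffs <- abs(sweep(X, 2L, d[i, lsel, drop = TRUE]))
      shared <- rowSums(!is.na(diffs))
      dist <- rowSums(diffs, na.rm = TRUE) / shared
      dist[shared == 0L] <- Inf
      finite <- is.finite(dist)
      if (!any(finite)) {
        ## no marker overlap with any called individual: fall back to the
        ## rounded mean of observed dosages at s
        val <- mean(d[obs, s])
      } else {
        nb <- order(dist, obs)[seq_len(min(k, sum(finite)))]
        w <- 1 / pmax(dist[nb], 1e-6)
        val <- sum(w * d[obs[nb], s]) / sum(w)
      }
      out[i, s] <- min(2L, max(0L, as.integer(floor(val + 0.5))))
    }
  }
  res <- genotype_matrix(out, geno$map$chrom, geno$map$pos_bp,
                         geno$map$pos_cm, individual_ids = rownames(d),
                         snp_ids = geno$map$snp_id)
  attr(res, "unimputed") <- unimputed
  res
}

#' Per-SNP mode imputation (baseline)
#'
#' Fills every missing cell with the most frequent observed dosage of its
#' SNP (ties broken toward the smaller dosage). Used as the naive baseline
#' against which LD-kNN imputation is benchmarked.
#'
#' @inheritParams ld_knni_impute
#' @return A [genotype_matrix()].
#' @export
mode_impute <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  for (s in which(colSums(is.na(d)) > 0L)) {
    obs <- d[!is.na(d[, s]), s]
    if (length(obs) == 0L) next
    tab <- tabulate(obs + 1L, nbins = 3L)
    d[is.na(d[, s]), s] <- which.max(tab) - 1L
  }
  genotype_matrix(d, geno$map$chrom, geno$map$pos_bp, geno$map$pos_cm,
                  individual_ids = rownames(geno$dosage),
                  snp_ids = geno$map$snp_id)
}
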