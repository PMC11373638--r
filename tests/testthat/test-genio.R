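## hand-written VCF: 3 individuals, 4 biallelic SNPs (one missing call),
## plus one multi-allelic record that must be skipped
toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", "ind2", "ind3", sep = "\t"),
    paste("chr1", "100", "snpA", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "250", "snpB", "C", "T", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", sep = "\t"),
    paste("chr1", "300", ".", "G", "A,C", ".", "PASS", ".", "GT",
          "1/2", "0/0", "0/1", sep = "\t"),
    paste("chr2", "50", "snpC", "T", "A", ".", "PASS", ".", "GT",
          "1|1", "0|1", "0|0", sep = "\t"),
    paste("chr2", "900", "snpD", "G", "C", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/1", sep = "\t")), path)
  path
}

test_that("VCF parsing matches the hand-checkable fixture", {
  f <- toy_vcf(tempfile(fileext = ".vcf"))
  expect_message(g <- read_vcf(f), "multi-allelic")
  expected <- matrix(c(0L, 1L, 2L,   # snpA
                       1L, NA, 0L,   # snpB (one ./. call)
                       2L, 1L, 0L,   # snpC (phased)
                       0L, 0L, 1L),  # snpD
                     nrow = 3,
                     dimnames = list(c("ind1", "ind2", "ind3"),
                                     c("snpA", "snpB", "snpC", "snpD")))
  expect_identical(g$dosage, expected)
  expect_identical(g$map$chrom, c("chr1", "chr1", "chr2", "chr2"))
  expect_identical(g$map$pos_bp, c(100L, 250L, 50L, 900L))
  expect_identical(sum(is.na(g$dosage)), 1L)
})

test_that("malformed genotypes raise a parse error naming the record", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", sep = "\t"),
    paste("chr1", "100", "bad1", "A", "G", ".", "PASS", ".", "GT",
          "2/2", sep = "\t")), f)
  expect_error(read_vcf(f), "cannot parse genotype '2/2'.*chr1:100")
})

test_that("VCF and TSV round trips preserve dosages, ids and positions", {
  g <- as_genotype_matrix(small_pool(100, chr = 5, snps = 100, seed = 71))
  g$dosage[5, 9] <- NA    # one missing call survives the trip
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(g, vcf)
  g2 <- read_vcf(vcf)
  expect_identical(unname(g2$dosage), unname(g$dosage))
  expect_identical(rownames(g2$dosage), rownames(g$dosage))
  expect_identical(g2$map$snp_id, g$map$snp_id)
  expect_identical(g2$map$chrom, g$map$chrom)
  expect_identical(g2$map$pos_bp, g$map$pos_bp)

  tsv <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_dosage_tsv(g, tsv, map_path = mp)
  g3 <- read_dosage_tsv(tsv, mp)
  expect_identical(g3$dosage, g$dosage)
  expect_identical(g3$map, g$map)
})

test_that("filtering applies call-rate, missingness and MAF rules in order", {
  ## clean matrix passes untouched with an all-zero report
  g <- toy_geno(20, 30, seed = 72, p = runif(30, 0.2, 0.5))
  fl <- filter_genotypes(g)
  expect_identical(fl$geno$dosage, g$dosage)
  expect_identical(fl$report$individuals_removed_call_rate, 0L)
  expect_identical(fl$report$snps_removed_missingness, 0L)
  expect_identical(fl$report$snps_removed_maf, 0L)

  ## one rare SNP among passing SNPs is exactly what gets removed
  g2 <- g
  g2$dosage[, 7] <- c(1L, rep(0L, 19))   # MAF = 1/40 < 0.03
  fl2 <- filter_genotypes(g2)
  expect_identical(setdiff(colnames(g2$dosage), colnames(fl2$geno$dosage)),
                   "s007")

  ## filters are idempotent
  fl3 <- filter_genotypes(fl2$geno)
  expect_identical(fl3$geno$dosage, fl2$geno$dosage)
})

test_that("planted 20x50 fixture filters to the brute-force survivor set", {
  set.seed(73)
  g <- toy_geno(20, 50, seed = 73, p = runif(50, 0.05, 0.5))
  d <- g$dosage
  d[1, sample(50, 15)] <- NA             # individual below 80% call rate
  d[3, sample(50, 12)] <- NA             # second offender
  for (s in c(5, 18, 40)) d[sample(20, 4), s] <- NA  # SNPs > 10% missing
  d[, 22] <- 0L; d[2, 22] <- 1L          # rare SNP
  d[, 33] <- 2L                          # monomorphic SNP
  g$dosage <- d

  ## brute-force oracle: explicit loops over the three rules in order
  keep_i <- which(vapply(seq_len(20),
                         function(i) mean(!is.na(d[i, ])) >= 0.80,
                         logical(1)))
  d2 <- d[keep_i, ]
  keep_s <- which(vapply(seq_len(50),
                         function(s) mean(is.na(d2[, s])) <= 0.10,
                         logical(1)))
  d3 <- d2[, keep_s]
  p <- colMeans(d3, na.rm = TRUE) / 2
  keep_maf <- which(pmin(p, 1 - p) >= 0.03)

  fl <- filter_genotypes(g)
  expect_identical(rownames(fl$geno$dosage), rownames(d)[keep_i])
  expect_identical(colnames(fl$geno$dosage),
                   colnames(d)[keep_s[keep_maf]])
  expect_identical(fl$geno$dosage, d3[, keep_maf])
})

test_that("LD-kNN imputation reproduces an independently coded oracle", {
  ## complete truth with block LD, then mask 10% of cells
  pop <- generate_founder_pool(30, n_chromosomes = 1,
                               n_snp_per_chromosome = 60,
                               ld_blocks = list(block_size = 10,
                                                n_haplotypes = 3),
                               seed = 74)
  truth <- as_genotype_matrix(pop)
  gb <- degrade_to_gbs(truth, 0.1, seed = 75)
  l <- 12; k <- 4
  imp <- ld_knni_impute(gb, l = l, k = k)

  ## observed cells never change and nothing stays missing
  obs <- !is.na(gb$dosage)
  expect_identical(imp$dosage[obs], gb$dosage[obs])
  expect_identical(sum(is.na(imp$dosage)), 0L)

  ## brute-force oracle: scalar re-implementation of the neighbor rule
  d <- gb$dosage
  r2 <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
  for (row in seq_len(nrow(gb$masked))) {
    i <- gb$masked$row[row]; s <- gb$masked$col[row]
    r <- r2[, s]; r[s] <- NA
    cand <- which(!is.na(r))
    lsel <- cand[order(-r[cand], cand)][seq_len(min(l, length(cand)))]
    obs_j <- setdiff(which(!is.na(d[, s])), i)
    dist <- sapply(obs_j, function(j) {
      ok <- !is.na(d[i, lsel]) & !is.na(d[j, lsel])
      if (!any(ok)) return(Inf)
      mean(abs(d[i, lsel][ok] - d[j, lsel][ok]))
    })
    if (any(is.finite(dist))) {
      ord <- order(dist, obs_j)
      nb <- ord[seq_len(min(k, sum(is.finite(dist))))]
      w <- 1 / pmax(dist[nb], 1e-6)
      val <- sum(w * d[obs_j[nb], s]) / sum(w)
    } else {
      val <- mean(d[obs_j, s])   # no usable LD markers (e.g. monomorphic s)
    }
    expected <- min(2L, max(0L, as.integer(floor(val + 0.5))))
    expect_identical(unname(imp$dosage[i, s]), expected)
  }
})

test_that("imputation edge cases: complete input, monomorphic and empty SNPs", {
  g <- toy_geno(10, 12, seed = 76)
  expect_identical(ld_knni_impute(g), g)

  d <- g$dosage
  d[, 4] <- 0L; d[2, 4] <- NA            # monomorphic SNP, one hole
  d[, 9] <- NA                           # SNP with no calls at all
  g2 <- genotype_matrix(d, g$map$chrom, g$map$pos_bp,
                        individual_ids = rownames(d),
                        snp_ids = g$map$snp_id)
  imp <- ld_knni_impute(g2, l = 5, k = 3)
  expect_identical(unname(imp$dosage[2, 4]), 0L)
  expect_true(all(is.na(imp$dosage[, 9])))
  expect_identical(attr(imp, "unimputed"), "s009")
})
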