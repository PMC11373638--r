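## scalar Weir-Cockerham theta for two samples of dosages, written as the
## textbook variance-component arithmetic (independent of the package code)
wc_theta_scalar <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); r <- 2
  p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
  h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a / (a + b + cc)
}

two_group_geno <- function(d1, d2) {
  d <- rbind(d1, d2)
  rownames(d) <- sprintf("i%02d", seq_len(nrow(d)))
  colnames(d) <- sprintf("s%02d", seq_len(ncol(d)))
  g <- genotype_matrix(d, chrom = rep("1", ncol(d)),
                       pos_bp = seq_len(ncol(d)) * 100L)
  labels <- setNames(rep(c("A", "B"), c(nrow(d1), nrow(d2))), rownames(d))
  list(geno = g, labels = labels)
}

test_that("Weir-Cockerham Fst: fixed difference gives 1, identity gives ~0", {
  ## group A fixed 0, group B fixed 2 at one SNP; filler SNPs polymorphic
  set.seed(81)
  filler <- matrix(rbinom(20 * 5, 2, 0.4), 20, 5)
  d <- cbind(c(rep(0L, 10), rep(2L, 10)), filler)
  tg <- two_group_geno(d[1:10, ], d[11:20, ])
  fst <- weir_cockerham_fst(tg$geno, tg$labels, focal = "A")
  expect_equal(unname(fst$per_snp[1]), 1)

  ## identical genotype columns in both groups: mean near 0, small
  ## negatives admissible
  half <- matrix(rbinom(12 * 40, 2, runif(40, 0.1, 0.5)), 12, 40,
                 byrow = FALSE)
  tg2 <- two_group_geno(half, half)
  fst2 <- weir_cockerham_fst(tg2$geno, tg2$labels, focal = "A")
  expect_lt(abs(fst2$summary[["mean"]]), 0.05)
  expect_lte(fst2$summary[["min"]], 0)    # negatives retained, not clipped
})

test_that("per-SNP theta equals the hand variance-component computation", {
  d1 <- matrix(c(0L, 1L, 2L, 1L, 0L,
                 2L, 2L, 1L, 0L, 0L,
                 1L, 1L, 1L, 1L, 0L), 5, 3)
  d2 <- matrix(c(2L, 2L, 1L, 2L, 2L, 1L, 2L,
                 0L, 1L, 0L, 0L, 1L, 0L, 0L,
                 1L, 0L, 1L, 2L, 1L, 0L, 1L), 7, 3)
  tg <- two_group_geno(d1, d2)
  fst <- weir_cockerham_fst(tg$geno, tg$labels, focal = "A")
  for (s in 1:3)
    expect_equal(unname(fst$per_snp[s]), wc_theta_scalar(d1[, s], d2[, s]))
})

test_that("Fst of a random split of one panmictic population centers on 0", {
  pool <- small_pool(100, chr = 2, snps = 80, seed = 82)
  g <- as_genotype_matrix(pool)
  set.seed(83)
  lab <- setNames(sample(rep(c("x", "y"), 50)), rownames(g$dosage))
  fst <- weir_cockerham_fst(g, lab, focal = "x")
  expect_lt(abs(fst$summary[["mean"]]), 0.02)
})

test_that("Nei's D matches the direct formula and its metric properties", {
  ## two loci with engineered group frequencies
  d1 <- matrix(c(1L, 1L, 1L, 1L, 2L, 0L, 0L, 0L, 1L, 1L), 5, 2)
  d2 <- matrix(c(2L, 2L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), 5, 2)
  tg <- two_group_geno(d1, d2)
  p1 <- colMeans(d1) / 2; p2 <- colMeans(d2) / 2
  jxy <- sum(p1 * p2 + (1 - p1) * (1 - p2))
  jx <- sum(p1^2 + (1 - p1)^2); jy <- sum(p2^2 + (1 - p2)^2)
  D <- nei_distance(tg$geno, tg$labels)
  expect_equal(D["A", "B"], -log(jxy / sqrt(jx * jy)))
  expect_equal(D["A", "B"], D["B", "A"])
  expect_identical(unname(diag(D)), c(0, 0))

  ## identical frequency vectors: D = 0
  tg0 <- two_group_geno(d1, d1)
  expect_equal(unname(nei_distance(tg0$geno, tg0$labels)["A", "B"]), 0)

  ## opposite fixation everywhere: capped sentinel with warning
  tgf <- two_group_geno(matrix(0L, 4, 3), matrix(2L, 4, 3))
  expect_warning(Df <- nei_distance(tgf$geno, tgf$labels), "capped")
  expect_gt(Df["A", "B"], 30)
})

test_that("Shannon's H attains ln(m) for uniform dosages and matches hand math", {
  ## the all-heterozygous individual over m SNPs, including the panel size
  ## for which ln(m) rounds to 9.52
  m <- 13633
  d <- rbind(rep(1L, m), c(2L, rep(1L, m - 1)))
  g <- genotype_matrix(d, chrom = rep("1", m), pos_bp = seq_len(m),
                       individual_ids = c("uniform", "other"))
  H <- shannon_index(g)$per_individual
  expect_equal(unname(H[["uniform"]]), log(m))
  expect_equal(round(H[["uniform"]], 2), 9.52)

  ## 3-SNP dosages (2, 1, 1): hand formula
  g3 <- genotype_matrix(rbind(c(2L, 1L, 1L), c(1L, 1L, 1L)),
                        chrom = rep("1", 3), pos_bp = 1:3,
                        individual_ids = c("a", "b"))
  expect_equal(unname(shannon_index(g3)$per_individual[["a"]]),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))

  ## invariant to SNP ordering
  set.seed(90)
  perm <- sample(m)
  gp <- genotype_matrix(d[, perm], chrom = rep("1", m),
                        pos_bp = seq_len(m),
                        individual_ids = c("uniform", "other"),
                        snp_ids = sprintf("p%05d", seq_len(m)))
  expect_equal(shannon_index(gp)$per_individual, H)
})

test_that("PCA matches a dense eigendecomposition and handles degeneracy", {
  g <- toy_geno(10, 20, seed = 84)
  pc <- pca_structure(g)
  ev <- eigen(cov(g$dosage), symmetric = TRUE)$values
  expect_equal(pc$sdev^2, ev[seq_along(pc$sdev)], tolerance = 1e-8)
  expect_equal(sum(pc$var_prop), 1)
  expect_true(all(diff(pc$var_prop) <= 1e-12))
  expect_true(all(pc$var_prop >= 0))

  ## permutation of SNP columns leaves the spectrum unchanged
  set.seed(85)
  perm <- sample(20)
  gp <- genotype_matrix(g$dosage[, perm][, order(perm)], g$map$chrom,
                        g$map$pos_bp, individual_ids = rownames(g$dosage),
                        snp_ids = g$map$snp_id)
  expect_equal(pca_structure(gp)$var_prop, pc$var_prop)

  ## rank-2 planted structure: two axes explain everything
  base <- matrix(rbinom(30, 2, 0.5), 3, 10)
  d2 <- base[c(1, 1, 1, 2, 2, 2, 3, 3), ]
  rownames(d2) <- sprintf("r%d", 1:8)
  g2 <- genotype_matrix(d2, rep("1", 10), 1:10 * 10L)
  pc2 <- pca_structure(g2)
  expect_gt(sum(pc2$var_prop[1:2]), 0.999)

  ## identical rows: explicit degenerate result
  g3 <- genotype_matrix(matrix(1L, 5, 8), rep("1", 8), 1:8 * 5L)
  pc3 <- pca_structure(g3)
  expect_true(pc3$degenerate)
  expect_true(all(is.na(pc3$var_prop)))
  expect_error(pca_structure(g3[1, ]), "at least 2")
})

test_that("composite r2 matches the contingency-table oracle and flags duplicates", {
  set.seed(86)
  x <- rbinom(40, 2, 0.4)
  y <- (x + rbinom(40, 1, 0.3)) %% 3
  d <- cbind(x, y, x)   # third column duplicates the first
  rownames(d) <- sprintf("i%02d", 1:40)
  colnames(d) <- c("sx", "sy", "sdup")
  g <- genotype_matrix(d, rep("1", 3), c(1000L, 5000L, 9000L))
  ld <- ld_decay(g, max_dist_bp = 1e5)
  pairs <- ld$all$pairs

  ## oracle: two-locus genotype table moments
  tab <- table(factor(x, 0:2), factor(y, 0:2))
  n <- sum(tab)
  mx <- sum((0:2) * rowSums(tab)) / n
  my <- sum((0:2) * colSums(tab)) / n
  exy <- sum(outer(0:2, 0:2) * tab) / n
  vx <- sum((0:2)^2 * rowSums(tab)) / n - mx^2
  vy <- sum((0:2)^2 * colSums(tab)) / n - my^2
  r2_oracle <- (exy - mx * my)^2 / (vx * vy)
  got <- pairs$r2[pairs$dist_bp == 4000]   # sx-sy and sy-sdup pairs
  expect_equal(got, rep(r2_oracle, 2), tolerance = 1e-12)
  expect_equal(pairs$r2[pairs$dist_bp == 8000], 1)   # duplicated marker
})

test_that("r2 among independent loci matches the finite-sample expectation", {
  ## site-independent founders: E[r2] ~ 1/n for n individuals
  n <- 50
  pool <- generate_founder_pool(n, n_chromosomes = 1,
                                n_snp_per_chromosome = 150, seed = 87)
  g <- as_genotype_matrix(pool)
  ld <- ld_decay(g, max_dist_bp = 1e9)
  expect_lt(abs(ld$all$mean_r2 - 1 / n), 0.006)
})

test_that("LD decay distance decreases with the threshold and finds block decay", {
  pop <- generate_founder_pool(80, n_chromosomes = 1,
                               n_snp_per_chromosome = 200,
                               chrom_length_bp = 2e7,
                               ld_blocks = list(block_size = 20,
                                                n_haplotypes = 4),
                               seed = 88)
  g <- as_genotype_matrix(pop)
  lds <- lapply(c(0.1, 0.2, 0.3), function(thr)
    ld_decay(g, max_dist_bp = 1e7, r2_threshold = thr)$all)
  dec <- vapply(lds, function(x) x$decay_bp, numeric(1))
  expect_true(all(is.finite(dec)))
  expect_true(all(diff(dec) <= 0))      # monotone non-increasing in threshold
  expect_gt(lds[[2]]$mean_r2, 0.05)     # block LD well above background
})

test_that("the diversity summary has the reported table layout", {
  pool <- small_pool(60, chr = 2, snps = 50, seed = 89)
  par <- subset_population(pool, 1:10)
  s1 <- advance_generation(par, 20, 2, seed = 90)
  s2 <- advance_generation(s1, 20, 2, seed = 91)
  d <- rbind(as_genotype_matrix(s1)$dosage, as_genotype_matrix(s2)$dosage)
  rownames(d) <- sprintf("g%03d", seq_len(nrow(d)))
  g <- genotype_matrix(d, pool$map$chrom, pool$map$pos_bp, pool$map$pos_cm)
  labels <- data.frame(individual_id = rownames(d),
                       group = rep(c("SYN1", "SYN2"), each = 40))
  ds <- diversity_summary(g, labels)
  expect_identical(ds$group, c("SYN1", "SYN2"))
  expect_identical(ds$N, c(40L, 40L))
  expect_true(all(ds$fst_mean >= -1 & ds$fst_mean <= 1))
  expect_true(all(ds$D_min >= 0))
  expect_true(all(ds$H_min > 0 & ds$H_max <= log(50)))
  expect_true(all(ds$fst_min <= ds$fst_mean & ds$fst_mean <= ds$fst_max))
})
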