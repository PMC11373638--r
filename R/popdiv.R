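#' Weir-Cockerham fixation index for one group versus the rest
#'
#' Per-SNP moments estimator theta = a / (a + b + c) of Weir & Cockerham's
#' Fst for the two-group contrast `focal` versus the pooled remaining
#' groups (or versus `others` if given). Negative per-SNP estimates are
#' retained, not truncated: small negative values are the estimator's
#' behaviour when differentiation is absent. SNPs where either side has
#' fewer than 2 called individuals, and SNPs that are monomorphic overall
#' (undefined denominator), are skipped and counted.
#'
#' @param geno A [genotype_matrix()].
#' @param labels Named character vector or factor mapping individual ids to
#'   group labels, or a data frame with columns `individual_id`, `group`.
#' @param focal Group label contrasted against the remainder.
#' @param others Optional vector of group labels forming the contrast's
#'   second side; default all non-focal groups pooled. Passing a single
#'   label gives a pairwise Fst.
#' @return List with `per_snp` (named numeric, `NA` where skipped),
#'   `summary` (min/max/mean over defined SNPs) and `n_skipped`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
weir_cockerham_fst <- function(geno, labels, focal, others = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  lab <- normalize_labels(geno, labels)
  if (!focal %in% lab) stop("focal group '", focal, "' not found in labels")
  side1 <- names(lab)[lab == focal]
  side2 <- if (is.null(others)) names(lab)[lab != focal]
           else names(lab)[lab %in% others]
  if (length(side2) == 0L) stop("contrast group is empty")
  d1 <- geno$dosage[side1, , drop = FALSE]
  d2 <- geno$dosage[side2, , drop = FALSE]

  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1, na.rm = TRUE)
  h2 <- colMeans(d2 == 1, na.rm = TRUE)

  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  theta <- a / (a + b + cc)
  theta[n1 < 2 | n2 < 2] <- NA            # too few calls on one side
  theta[a + b + cc == 0] <- NA            # monomorphic overall
  names(theta) <- geno$map$snp_id
  ok <- !is.na(theta)
  list(per_snp = theta,
       summary = c(min = min(theta[ok]), max = max(theta[ok]),
                   mean = mean(theta[ok])),
       n_skipped = sum(!ok))
}

#' Nei's (1972) standard genetic distance between groups
#'
#' For each pair of groups, `D = -ln(Jxy / sqrt(Jx * Jy))` with the
#' identities `Jxy = sum(p1 p2 + q1 q2)`, `Jx = sum(p1^2 + q1^2)`,
#' `Jy = sum(p2^2 + q2^2)` accumulated over loci where both groups have at
#' least one call (loci with no calls in a group are excluded pairwise).
#' Groups fixed for opposite alleles everywhere give `Jxy = 0`; the
#' infinite distance is reported as the cap `-log(.Machine$double.eps)`
#' (about 36) with a warning.
#'
#' @inheritParams weir_cockerham_fst
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
nei_distance <- function(geno, labels) {
  stopifnot(inherits(geno, "genotype_matrix"))
  lab <- normalize_labels(geno, labels)
  grp <- sort(unique(lab))
  freqs <- lapply(grp, function(g) {
    dd <- geno$dosage[names(lab)[lab == g], , drop = FALSE]
    colMeans(dd, na.rm = TRUE) / 2      # NaN where no calls
  })
  names(freqs) <- grp
  D <- matrix(0, length(grp), length(grp), dimnames = list(grp, grp))
  cap <- -log(.Machine$double.eps)
  for (i in seq_along(grp)) for (j in seq_len(i - 1L)) {
    p1 <- freqs[[i]]; p2 <- freqs[[j]]
    ok <- !is.nan(p1) & !is.nan(p2)
    p1 <- p1[ok]; p2 <- p2[ok]
    jxy <- sum(p1 * p2 + (1 - p1) * (1 - p2))
    jx <- sum(p1^2 + (1 - p1)^2)
    jy <- sum(p2^2 + (1 - p2)^2)
    I <- jxy / sqrt(jx * jy)
    if (I <= .Machine$double.eps) {
      warning("genetic identity of ", grp[i], " and ", grp[j],
              " is ~0; distance capped at ", round(cap, 2))
      dd <- cap
    } else {
      dd <- max(0, -log(min(I, 1)))
    }
    D[i, j] <- D[j, i] <- dd
  }
  D
}

#' Shannon's diversity index per individual
#'
#' Treats each individual's non-missing dosages as abundances:
#' `H = -sum(q_s log q_s)` with `q_s` the dosage at SNP s divided by the
#' individual's total dosage. An individual heterozygous everywhere attains
#' the maximum `log(m)` for m SNPs. Computed with [vegan::diversity()];
#' missing calls contribute nothing.
#'
#' @inheritParams weir_cockerham_fst
#' @param labels Optional group labels; when given, a per-group
#'   min/max/mean summary is returned alongside the per-individual values.
#' @return List with `per_individual` (named numeric) and, when labels are
#'   given, `summary` (data frame with group, N, min, max, mean).
#' @export
shannon_index <- function(geno, labels = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  d[is.na(d)] <- 0
  allzero <- rowSums(d) == 0
  if (any(allzero))
    warning(sum(allzero), " individual(s) with all-zero dosages; H = 0")
  H <- vegan::diversity(d, index = "shannon")
  names(H) <- rownames(geno$dosage)
  out <- list(per_individual = H)
  if (!is.null(labels)) {
    lab <- normalize_labels(geno, labels)
    grp <- sort(unique(lab))
    out$summary <- do.call(rbind, lapply(grp, function(g) {
      h <- H[names(lab)[lab == g]]
      data.frame(group = g, N = length(h), min = min(h), max = max(h),
                 mean = mean(h), stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Principal component structure of a genotype matrix
#'
#' Missing cells are mean-imputed per SNP, then the individuals x SNPs
#' matrix is centered (not variance-scaled) and decomposed with
#' [stats::prcomp()]. Variance proportions sum to 1 over all axes.
#'
#' @inheritParams weir_cockerham_fst
#' @return List with `scores` (individuals x PCs), `var_prop` (proportion
#'   of variance per axis), `sdev`, and `degenerate` (`TRUE` when the
#'   matrix has no variance at all, in which case proportions are `NA`).
#' @export
pca_structure <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  if (nrow(d) < 2) stop("need at least 2 individuals for PCA")
  mu <- colMeans(d, na.rm = TRUE)
  for (s in which(colSums(is.na(d)) > 0L))
    d[is.na(d[, s]), s] <- mu[s]
  d[is.nan(d)] <- 0                     # SNPs with no calls at all
  pc <- prcomp(d, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) {
    return(list(scores = pc$x, var_prop = rep(NA_real_, length(pc$sdev)),
                sdev = pc$sdev, degenerate = TRUE))
  }
  list(scores = pc$x, var_prop = pc$sdev^2 / tot, sdev = pc$sdev,
       degenerate = FALSE)
}

#' Linkage-disequilibrium decay with physical distance
#'
#' Composite r-squared (squared Pearson correlation of unphased dosages on
#' pairwise-complete individuals) for all intra-chromosomal SNP pairs
#' within `max_dist_bp`, per population. A locally weighted smoothing curve
#' ([stats::lowess()], span `span`) is fitted to r-squared against
#' distance; the decay distance is the smallest distance where the fitted
#' curve first crosses `r2_threshold` from above (linearly interpolated),
#' `NA` when the curve never crosses inside the window, and 0 when it
#' starts below the threshold.
#'
#' @inheritParams weir_cockerham_fst
#' @param labels Optional group labels; `NULL` treats all individuals as
#'   one population.
#' @param max_dist_bp Maximum pair distance in bp (default 1e7).
#' @param r2_threshold Conventional decay threshold (default 0.2).
#' @param span Lowess smoother span (default 0.3).
#' @return Named list, one element per population: list with `pairs`
#'   (data frame `dist_bp`, `r2`), `mean_r2`, `decay_bp`, `smooth`
#'   (data frame `dist_bp`, `r2`).
#' @export
ld_decay <- function(geno, labels = NULL, max_dist_bp = 1e7,
                     r2_threshold = 0.2, span = 0.3) {
  stopifnot(inherits(geno, "genotype_matrix"))
  lab <- if (is.null(labels))
    setNames(rep("all", nrow(geno$dosage)), rownames(geno$dosage))
  else normalize_labels(geno, labels)
  pops <- sort(unique(lab))
  out <- lapply(pops, function(g) {
    ids <- names(lab)[lab == g]
    if (length(ids) < 10)
      warning("population '", g, "' has fewer than 10 individuals; ",
              "r2 estimates will be noisy")
    d <- geno$dosage[ids, , drop = FALSE]
    pieces <- lapply(unique(geno$map$chrom), function(ch) {
      j <- which(geno$map$chrom == ch)
      if (length(j) < 2) return(NULL)
      pos <- geno$map$pos_bp[j]
      r2 <- suppressWarnings(
        cor(d[, j, drop = FALSE], use = "pairwise.complete.obs"))^2
      dist <- abs(outer(pos, pos, "-"))
      sel <- upper.tri(dist) & dist <= max_dist_bp & dist > 0
      data.frame(dist_bp = dist[sel], r2 = r2[sel])
    })
    pairs <- do.call(rbind, pieces)
    pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
    if (nrow(pairs) == 0)
      return(list(pairs = pairs, mean_r2 = NA_real_, decay_bp = NA_real_,
                  smooth = NULL))
    sm <- lowess(pairs$dist_bp, pairs$r2, f = span)
    list(pairs = pairs, mean_r2 = mean(pairs$r2),
         decay_bp = decay_crossing(sm$x, sm$y, r2_threshold),
         smooth = data.frame(dist_bp = sm$x, r2 = sm$y))
  })
  names(out) <- pops
  out
}

## first downward crossing of a fitted curve through `thr`
decay_crossing <- function(x, y, thr) {
  if (length(x) == 0) return(NA_real_)
  if (y[1] < thr) return(0)
  below <- which(y < thr)
  if (length(below) == 0) return(NA_real_)
  i <- below[1L]
  x0 <- x[i - 1L]; x1 <- x[i]; y0 <- y[i - 1L]; y1 <- y[i]
  if (y0 == y1) return(x1)
  x0 + (y0 - thr) * (x1 - x0) / (y0 - y1)
}

#' Table-style summary of population diversity
#'
#' Per-group population-genetic summary in the layout typically reported
#' for SYN generations: sample size, per-SNP Weir-Cockerham Fst of the
#' group against the pooled remainder (min/max/mean), Nei's D against the
#' other groups (min/max/mean) and Shannon's H over individuals
#' (min/max/mean).
#'
#' @inheritParams weir_cockerham_fst
#' @return Data frame with one row per group.
#' @export
diversity_summary <- function(geno, labels) {
  lab <- normalize_labels(geno, labels)
  grp <- sort(unique(lab))
  if (length(grp) < 2) stop("need at least 2 groups")
  D <- nei_distance(geno, labels)
  H <- shannon_index(geno, labels)$summary
  do.call(rbind, lapply(grp, function(g) {
    fst <- weir_cockerham_fst(geno, labels, focal = g)
    dvec <- D[g, setdiff(grp, g)]
    h <- H[H$group == g, ]
    data.frame(group = g, N = sum(lab == g),
               fst_min = fst$summary[["min"]],
               fst_max = fst$summary[["max"]],
               fst_mean = fst$summary[["mean"]],
               D_min = min(dvec), D_max = max(dvec), D_mean = mean(dvec),
               H_min = h$min, H_max = h$max, H_mean = h$mean,
               stringsAsFactors = FALSE)
  }))
}

## accept labels as a named vector/factor or a (individual_id, group) data
## frame; return a named character vector covering only known ids
normalize_labels <- function(geno, labels) {
  if (is.data.frame(labels)) {
    if (!all(c("individual_id", "group") %in% names(labels)))
      stop("label data frame needs columns `individual_id` and `group`")
    lab <- setNames(as.character(labels$group),
                    as.character(labels$individual_id))
  } else {
    lab <- setNames(as.character(labels), names(labels))
  }
  if (is.null(names(lab))) stop("labels must be named by individual id")
  unknown <- setdiff(names(lab), rownames(geno$dosage))
  if (length(unknown) > 0)
    stop("labelled id(s) absent from the genotype matrix: ",
         paste(head(unknown, 3), collapse = ", "))
  lab
}
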