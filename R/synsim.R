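#' Additive trait architecture
#'
#' Holds the causative loci (QTL), their additive effects, the intercept,
#' and the variance bookkeeping of a purely additive polygenic trait:
#' base additive variance `v0` (equal to the total genetic variance since
#' dominance, epistasis and G-by-E are absent), target broad-sense
#' heritability `h2`, and the error variance
#' `var_e = v0 * (1 - h2) / h2` implied by the two.
#'
#' @param qtl Integer locus indices of the causative loci.
#' @param effects Additive allele-substitution effects, one per QTL.
#' @param intercept Trait intercept.
#' @param v0 Base additive variance the effects were calibrated to.
#' @param h2 Target heritability in (0, 1]; `h2 = 1` gives a noise-free
#'   trait (`var_e = 0`).
#' @param target_mean Trait mean the intercept was calibrated to.
#' @return An object of class `trait_architecture`.
#' @seealso [sample_qtl_effects()]
#' @export
trait_architecture <- function(qtl, effects, intercept, v0, h2,
                               target_mean = 1) {
  if (length(qtl) != length(effects))
    stop("`qtl` and `effects` must have equal length")
  if (v0 <= 0) stop("`v0` must be positive")
  if (h2 <= 0 || h2 > 1) stop("`h2` must lie in (0, 1]")
  structure(list(qtl = as.integer(qtl), effects = as.numeric(effects),
                 intercept = intercept, v0 = v0, h2 = h2,
                 var_e = v0 * (1 - h2) / h2, target_mean = target_mean),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("trait_architecture: %d QTL, v0 = %.4g, h2 = %.2f, var_e = %.4g\n",
              length(x$qtl), x$v0, x$h2, x$var_e))
  invisible(x)
}

#' Sample a polygenic trait architecture on a founder pool
#'
#' QTL are sampled uniformly from the loci segregating in the pool; raw
#' effects are standard normal and then rescaled so that the variance of
#' genetic values over the full founder pool equals `v0` exactly; the
#' intercept shifts the mean genetic value to `target_mean`.
#'
#' @param pop A [haplotype_population()] (typically the founder pool).
#' @param n_qtl Number of causative loci (default 1000).
#' @param target_mean Desired mean genetic value (default 1).
#' @param v0 Desired base additive variance (default 0.3).
#' @param h2 Target heritability (default 0.6).
#' @param seed Optional integer seed.
#' @return A [trait_architecture()].
#' @export
sample_qtl_effects <- function(pop, n_qtl = 1000, target_mean = 1, v0 = 0.3,
                               h2 = 0.6, seed = NULL) {
  stopifnot(inherits(pop, "haplotype_population"))
  d <- pop$H1 + pop$H2
  p <- colMeans(d) / 2
  seg <- which(p > 0 & p < 1)
  if (length(seg) < n_qtl)
    stop("founder pool segregates at only ", length(seg),
         " loci; cannot place ", n_qtl, " QTL")
  with_seed(seed, {
    qtl <- sort(sample(seg, n_qtl))
    eff <- rnorm(n_qtl)
    g <- drop(d[, qtl, drop = FALSE] %*% eff)
    vg <- var(g)
    if (vg == 0) stop("sampled effects give zero genetic variance")
    eff <- eff * sqrt(v0 / vg)
    g <- g * sqrt(v0 / vg)
    trait_architecture(qtl, eff, intercept = target_mean - mean(g),
                       v0 = v0, h2 = h2, target_mean = target_mean)
  })
}

#' Genetic values of a population under an additive trait
#'
#' @param pop A [haplotype_population()] or complete [genotype_matrix()].
#' @param trait A [trait_architecture()] whose QTL indices refer to `pop`'s
#'   loci (columns).
#' @return Named numeric vector of genetic values (intercept included).
#' @export
genetic_values <- function(pop, trait) {
  stopifnot(inherits(trait, "trait_architecture"))
  if (inherits(pop, "haplotype_population")) {
    d <- pop$H1 + pop$H2
    ids <- sprintf("%s_%05d", generation_label(pop), seq_len(nrow(d)))
  } else if (inherits(pop, "genotype_matrix")) {
    d <- pop$dosage
    ids <- rownames(d)
  } else stop("`pop` must be a haplotype_population or genotype_matrix")
  if (max(trait$qtl) > ncol(d)) stop("trait QTL indices exceed locus count")
  dq <- d[, trait$qtl, drop = FALSE]
  if (anyNA(dq)) stop("missing dosages at QTL; impute first")
  setNames(drop(dq %*% trait$effects) + trait$intercept, ids)
}

#' Additive variance at panmictic equilibrium
#'
#' The additive genetic variance the population would show under
#' Hardy-Weinberg and linkage equilibrium at its current allele
#' frequencies: `sum(2 p (1-p) a^2)` over QTL. For a panmictic SYN
#' population this is the natural population-level variance implied by a set
#' of parents, and it is the quantity the classical drift recursion
#' `E[var(t+1)] = var(t) (1 - 1/(2N))` refers to.
#'
#' @inheritParams genetic_values
#' @return Single numeric value.
#' @export
expected_additive_variance <- function(pop, trait) {
  stopifnot(inherits(pop, "haplotype_population"),
            inherits(trait, "trait_architecture"))
  p <- colMeans(pop$H1 + pop$H2)[trait$qtl] / 2
  sum(2 * p * (1 - p) * trait$effects^2)
}

#' Simulate gametes by meiosis with Poisson crossovers
#'
#' Per chromosome, the crossover count is Poisson with mean `length_cM /
#' 100`, crossover positions are uniform on the genetic map (no
#' interference), and the starting haplotype is chosen by a fair coin; the
#' gamete is the resulting mosaic of the parent's two haplotypes
#' (Haldane's model).
#'
#' @param pop A [haplotype_population()].
#' @param parents Integer vector of parent indices, one per gamete.
#' @param seed Optional integer seed.
#' @return Integer 0/1 matrix, one row per gamete, one column per locus.
#' @export
make_gametes <- function(pop, parents, seed = NULL) {
  stopifnot(inherits(pop, "haplotype_population"))
  G <- length(parents)
  L <- ncol(pop$H1)
  with_seed(seed, {
    gam <- matrix(0L, G, L)
    for (ch in unique(pop$map$chrom)) {
      j <- which(pop$map$chrom == ch)
      pos <- pop$map$pos_cm[j]
      len <- unname(pop$chrom_length_cm[[ch]])
      nx <- rpois(G, len / 100)
      phase <- matrix(sample(0:1, G, replace = TRUE), G, length(j))
      tot <- sum(nx)
      if (tot > 0L) {
        gi <- rep.int(seq_len(G), nx)
        cut <- findInterval(runif(tot, 0, len), pos)
        keep <- cut < length(j)          # crossovers past the last locus are silent
        if (any(keep)) {
          cc <- matrix(tabulate(cut[keep] * G + gi[keep],
                                nbins = G * length(j)), G, length(j))
          for (c2 in seq_len(ncol(cc))[-1L])
            cc[, c2] <- cc[, c2] + cc[, c2 - 1L]
          phase <- (phase + cc) %% 2L
        }
      }
      A <- pop$H1[parents, j, drop = FALSE]
      B <- pop$H2[parents, j, drop = FALSE]
      sel <- phase == 1L
      A[sel] <- B[sel]
      gam[, j] <- A
    }
    gam
  })
}

#' Advance one generation by panmictic random mating
#'
#' Each cross pairs two distinct parents sampled uniformly (with replacement
#' across crosses, i.e. a parent may enter several crosses, but selfing is
#' excluded); each progeny is the union of two independent meioses. No
#' selection is applied at any step, matching how SYN seed-multiplication
#' generations are advanced in the field.
#'
#' @param pop A [haplotype_population()] with at least 2 individuals.
#' @param n_crosses Number of crosses.
#' @param progeny_per_cross Progeny per cross; the next generation has
#'   exactly `n_crosses * progeny_per_cross` individuals.
#' @param seed Optional integer seed.
#' @return A [haplotype_population()] with `generation` incremented.
#' @export
advance_generation <- function(pop, n_crosses, progeny_per_cross,
                               seed = NULL) {
  stopifnot(inherits(pop, "haplotype_population"))
  n <- n_individuals(pop)
  if (n < 2) stop("need at least 2 individuals to mate (selfing excluded)")
  if (n_crosses < 1 || progeny_per_cross < 1)
    stop("`n_crosses` and `progeny_per_cross` must be positive")
  with_seed(seed, {
    p1 <- sample.int(n, n_crosses, replace = TRUE)
    p2 <- sample.int(n, n_crosses, replace = TRUE)
    while (any(bad <- p2 == p1))
      p2[bad] <- sample.int(n, sum(bad), replace = TRUE)
    f <- rep(p1, each = progeny_per_cross)
    m <- rep(p2, each = progeny_per_cross)
    haplotype_population(make_gametes(pop, f), make_gametes(pop, m),
                         pop$map, pop$chrom_length_cm, pop$generation + 1L)
  })
}

#' Estimate additive and phenotypic variance of a population
#'
#' The additive variance is the sample variance of the true genetic values
#' (equal to the total genetic variance for a purely additive trait);
#' phenotypes add independent Normal(0, `var_e`) noise; realized
#' heritability is their ratio.
#'
#' @param pop A [haplotype_population()] with at least 2 individuals.
#' @param trait A [trait_architecture()].
#' @param seed Optional integer seed (for the phenotypic noise).
#' @return List with elements `var_a`, `var_p`, `h2_realized`.
#' @export
estimate_variances <- function(pop, trait, seed = NULL) {
  if (n_individuals(pop) < 2) stop("need at least 2 individuals")
  g <- genetic_values(pop, trait)
  with_seed(seed, {
    ph <- g + rnorm(length(g), 0, sqrt(trait$var_e))
    va <- var(g)
    vp <- var(ph)
    list(var_a = va, var_p = vp, h2_realized = va / vp)
  })
}

#' Run the SYN founder-number x heritability simulation experiment
#'
#' Full factorial over founder counts and heritability levels. Per
#' iteration and founder count: draw parents from the founder pool, sample a
#' fresh QTL architecture (calibrated on the full pool), create SYN1 by
#' random crossing among the parents, advance without selection to SYN4 (or
#' `n_generations`), and record additive variance, phenotypic variance and
#' realized heritability for every generation and heritability level.
#' Effects and parents are resampled every iteration, so the replicate
#' spread reflects architecture and founder sampling, not just drift.
#'
#' @param founder_pool A [haplotype_population()] larger than
#'   `max(parent_counts)`.
#' @param parent_counts Founder numbers to compare (default
#'   `c(7, 10, 15, 20, 25)`).
#' @param h2_levels Heritability levels (default `c(0.4, 0.6, 0.8)`).
#' @param n_qtl Causative loci per architecture (default 1000).
#' @param n_crosses,progeny_per_cross Per-generation crossing design; the
#'   full-scale study uses 1000 x 100, the desk-scale default is 100 x 20.
#' @param n_generations Number of SYN generations (default 4).
#' @param iterations Replicates (default 25 at desk scale).
#' @param v0 Base additive variance (default 0.3; the absolute scale of the
#'   output variances is proportional to it).
#' @param target_mean Trait mean (default 1).
#' @param seed Optional integer master seed.
#'
#' @return A data frame of class `variance_table` with one row per
#'   (`parents`, `generation`, `h2`, `iteration`) and columns `var_a`,
#'   `var_p`, `h2_realized`.
#' @seealso [summarize_variance_table()], [tukey_hsd()]
#' @export
run_syn_experiment <- function(founder_pool,
                               parent_counts = c(7, 10, 15, 20, 25),
                               h2_levels = c(0.4, 0.6, 0.8),
                               n_qtl = 1000,
                               n_crosses = 100,
                               progeny_per_cross = 20,
                               n_generations = 4,
                               iterations = 25,
                               v0 = 0.3,
                               target_mean = 1,
                               seed = NULL) {
  stopifnot(inherits(founder_pool, "haplotype_population"))
  if (n_individuals(founder_pool) <= max(parent_counts))
    stop("founder pool must be larger than the largest parent count")
  n_prog <- n_crosses * progeny_per_cross
  if (n_prog * ncol(founder_pool$H1) > 5e8)
    stop("requested population size is infeasible in memory; ",
         "reduce `n_crosses` or `progeny_per_cross`")
  rows <- vector("list", iterations * length(parent_counts))
  ri <- 0L
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      for (np in parent_counts) {
        trait <- sample_qtl_effects(founder_pool, n_qtl = n_qtl,
                                    target_mean = target_mean, v0 = v0,
                                    h2 = h2_levels[1L])
        parents <- subset_population(founder_pool,
                                     sample.int(n_individuals(founder_pool),
                                                np))
        pop <- parents
        rec <- vector("list", n_generations)
        for (gen in seq_len(n_generations)) {
          pop <- advance_generation(pop, n_crosses, progeny_per_cross)
          g <- genetic_values(pop, trait)
          va <- var(g)
          sub <- lapply(h2_levels, function(h2) {
            ve <- v0 * (1 - h2) / h2
            vp <- var(g + rnorm(length(g), 0, sqrt(ve)))
            data.frame(parents = np, generation = gen, h2 = h2,
                       iteration = it, var_a = va, var_p = vp,
                       h2_realized = va / vp)
          })
          rec[[gen]] <- do.call(rbind, sub)
        }
        ri <- ri + 1L
        rows[[ri]] <- do.call(rbind, rec)
      }
    }
  })
  out <- do.call(rbind, rows)
  ## flag (do not clip) records where noise pushed var_p below var_a
  out$var_p_lt_var_a <- out$var_p < out$var_a
  class(out) <- c("variance_table", "data.frame")
  out
}

#' Aggregate a variance table into per-cell means and SDs
#'
#' @param vt A `variance_table` from [run_syn_experiment()].
#' @return Data frame with one row per (`parents`, `generation`, `h2`) and
#'   mean/SD of `var_a`, `var_p` and `h2_realized` over iterations.
#' @export
summarize_variance_table <- function(vt) {
  stopifnot(is.data.frame(vt))
  agg <- aggregate(cbind(var_a, var_p, h2_realized) ~
                     parents + generation + h2, data = vt,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  out <- data.frame(parents = agg$parents, generation = agg$generation,
                    h2 = agg$h2,
                    var_a_mean = agg$var_a[, "mean"],
                    var_a_sd = agg$var_a[, "sd"],
                    var_p_mean = agg$var_p[, "mean"],
                    var_p_sd = agg$var_p[, "sd"],
                    h2_realized_mean = agg$h2_realized[, "mean"],
                    h2_realized_sd = agg$h2_realized[, "sd"])
  out[order(out$h2, out$parents, out$generation), ]
}

#' Tukey's honestly significant difference with compact letter display
#'
#' One-way ANOVA mean square error, `HSD = q(1 - alpha, k, df) *
#' sqrt(MSE / n_h)` with `n_h` the harmonic mean group size, and letters
#' assigned so that groups sharing a letter have means differing by less
#' than the HSD.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; at least 2 groups
#'   with at least 2 values each.
#' @param alpha Significance level (default 0.001, the level used for
#'   SYN-generation comparisons throughout the package).
#' @return An object of class `tukey_hsd`: list with `means` (sorted
#'   decreasing), `n`, `mse`, `df`, `hsd`, `letters` (named character
#'   vector), `alpha`.
#' @examples
#' set.seed(1)
#' tukey_hsd(c(rnorm(20), rnorm(20, 5)), rep(c("a", "b"), each = 20))
#' @export
tukey_hsd <- function(values, groups, alpha = 0.001) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  ni <- tabulate(g)
  if (any(ni < 2)) stop("every group needs at least 2 values")
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  N <- length(values)
  df <- N - k
  mse <- sum((values - means[g])^2) / df
  degenerate <- mse == 0
  if (degenerate)
    warning("zero within-group variance in all groups; HSD is degenerate")
  nh <- k / sum(1 / ni)
  hsd <- qtukey(1 - alpha, k, df) * sqrt(mse / nh)
  ## compact letter display: means sorted decreasing; maximal runs of
  ## groups whose means differ by less than the HSD share a letter
  o <- order(means, decreasing = TRUE)
  ms <- means[o]
  cmp <- if (degenerate) `<=` else `<`
  ends <- vapply(seq_len(k), function(i) max(which(cmp(ms[i] - ms, hsd))),
                 integer(1))
  keep <- which(!duplicated(ends))
  keep <- keep[ends[keep] == cummax(ends)[keep]]  # only maximal intervals
  lab <- rep("", k)
  for (t in seq_along(keep)) {
    i <- keep[t]
    span <- i:ends[i]
    lab[span] <- paste0(lab[span], letters[(t - 1L) %% 26L + 1L])
  }
  letters_out <- setNames(lab[order(o)], levels(g))
  structure(list(means = ms, n = setNames(ni, levels(g))[o],
                 mse = mse, df = df, hsd = hsd,
                 letters = letters_out, alpha = alpha,
                 degenerate = degenerate),
            class = "tukey_hsd")
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("Tukey HSD at alpha = %g: HSD = %.4g (MSE = %.4g, df = %d)\n",
              x$alpha, x$hsd, x$mse, x$df))
  df <- data.frame(mean = as.numeric(x$means), n = as.integer(x$n),
                   letters = x$letters[names(x$means)])
  rownames(df) <- names(x$means)
  print(df)
  invisible(x)
}
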