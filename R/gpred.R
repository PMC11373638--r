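#' Fit a ridge-regression BLUP model with year fixed effects
#'
#' Mixed model `y = X beta + Z u + e` with `y` the stacked plant-year
#' phenotype records, `X` the year design matrix (intercept plus dummies,
#' first year as reference), `Z` the records-by-markers matrix of dosages
#' centered by the training-set column means, `u ~ N(0, sigma2_u I)` the
#' random marker effects and `e ~ N(0, sigma2_e I)` the residuals.
#'
#' Variance components are estimated by REML: the restricted likelihood is
#' profiled on the variance ratio `lambda = sigma2_e / sigma2_u` through a
#' single eigendecomposition of the projected marker covariance `S Z Z' S`
#' (with `S` the projector orthogonal to `X`) and a one-dimensional
#' optimization in `log(lambda)` (tolerance 1e-8). `beta` and `u` then
#' solve the mixed-model equations at the optimum via generalized least
#' squares on `(Z Z' + lambda I)`.
#'
#' @param pheno Data frame with columns `genotype_id`, `year`, `value`
#'   (records; an individual may appear once per year).
#' @param geno A complete (imputed) [genotype_matrix()] containing at least
#'   the phenotyped individuals.
#' @param lambda Optional fixed variance ratio; skips REML when given.
#' @return An object of class `rrblup_model`: list with `beta` (named fixed
#'   effects), `u` (named marker effects), `lambda`, `sigma2_u`, `sigma2_e`,
#'   `center` (training column means), `snp_ids`, `year_levels`, `loglik`
#'   (restricted, profiled; `NA` when `lambda` was fixed).
#' @seealso [gebv()], [cross_validate()], [predict_populations()]
#' @export
fit_rrblup <- function(pheno, geno, lambda = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"),
            is.data.frame(pheno),
            all(c("genotype_id", "year", "value") %in% names(pheno)))
  ids <- rownames(geno$dosage)
  missing_ids <- setdiff(unique(pheno$genotype_id), ids)
  if (length(missing_ids) > 0)
    stop("phenotyped individual(s) not genotyped: ",
         paste(head(missing_ids, 3), collapse = ", "))
  if (anyNA(geno$dosage))
    stop("genotypes contain missing calls; impute before fitting")

  train_ids <- unique(pheno$genotype_id)
  M <- geno$dosage[train_ids, , drop = FALSE]
  center <- colMeans(M)
  W <- sweep(M, 2L, center)
  Z <- W[match(pheno$genotype_id, train_ids), , drop = FALSE]
  y <- pheno$value
  yr <- factor(pheno$year)
  X <- if (nlevels(yr) > 1) model.matrix(~yr) else cbind(rep(1, length(y)))
  colnames(X) <- c("(Intercept)",
                   if (nlevels(yr) > 1) paste0("year_", levels(yr)[-1L]))
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("singular year design; collinear column(s): ",
         paste(colnames(X), collapse = ", "))
  if (p >= n) stop("more fixed-effect levels than records")

  K <- tcrossprod(Z)
  loglik <- NA_real_
  if (is.null(lambda)) {
    ## decompose S (K + I) S rather than S K S: its null space is exactly
    ## col(X), so the leading n - p eigenvectors span the restricted space
    ## even when K is rank-deficient (e.g. repeated records per individual)
    XtXi <- solve(crossprod(X))
    SX <- X %*% XtXi
    A <- K + diag(n)
    SAS <- A - SX %*% crossprod(X, A)
    SAS <- SAS - (SAS %*% X) %*% t(SX)
    eg <- eigen(SAS, symmetric = TRUE)
    theta <- pmax(eg$values[seq_len(n - p)] - 1, 0)
    U <- eg$vectors[, seq_len(n - p), drop = FALSE]
    eta2 <- drop(crossprod(U, y))^2
    negll <- function(loglam) {
      lam <- exp(loglam)
      (n - p) * log(sum(eta2 / (theta + lam))) + sum(log(theta + lam))
    }
    opt <- optimize(negll, interval = c(-25, 25), tol = 1e-8)
    lambda <- exp(opt$minimum)
    loglik <- -0.5 * (opt$objective +
                        (n - p) * (1 + log(2 * pi / (n - p))))
  }
  H <- K + lambda * diag(n)
  Hi <- chol2inv(chol(H))
  XtHiX <- crossprod(X, Hi %*% X)
  beta <- drop(solve(XtHiX, crossprod(X, Hi %*% y)))
  names(beta) <- colnames(X)
  resid_fix <- y - X %*% beta
  u <- drop(crossprod(Z, Hi %*% resid_fix))
  names(u) <- colnames(M)
  sigma2_u <- drop(crossprod(resid_fix, Hi %*% resid_fix)) / (n - p)
  structure(list(beta = beta, u = u, lambda = lambda,
                 sigma2_u = sigma2_u, sigma2_e = lambda * sigma2_u,
                 center = center, snp_ids = colnames(M),
                 year_levels = levels(yr), n_records = n,
                 loglik = loglik),
            class = "rrblup_model")
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf(paste0("rrblup_model: %d records, %d markers, %d year level(s)\n",
                     "  lambda = %.4g (sigma2_u = %.4g, sigma2_e = %.4g)\n"),
              x$n_records, length(x$u), length(x$year_levels),
              x$lambda, x$sigma2_u, x$sigma2_e))
  invisible(x)
}

#' Genomic estimated breeding values
#'
#' `gebv()` returns `z u` for each individual, with dosages centered by the
#' model's stored training means over the intersection of training and
#' target SNPs; a SNP-set mismatch is reported via message. `predict()`
#' adds the model's average fixed-effect level (intercept plus the mean of
#' the year effects), the appropriate point prediction for individuals
#' without a phenotyping year.
#'
#' @param model An [fit_rrblup()] model.
#' @param geno A complete [genotype_matrix()] of target individuals.
#' @return Named numeric vector.
#' @export
gebv <- function(model, geno) {
  stopifnot(inherits(model, "rrblup_model"),
            inherits(geno, "genotype_matrix"))
  common <- intersect(model$snp_ids, geno$map$snp_id)
  if (length(common) == 0L)
    stop("no SNPs shared between model and target genotypes")
  if (length(common) < length(model$snp_ids))
    message(length(model$snp_ids) - length(common),
            " training SNP(s) absent from the target set; using ",
            length(common), " shared SNPs")
  d <- geno$dosage[, common, drop = FALSE]
  if (anyNA(d)) stop("target genotypes contain missing calls; impute first")
  W <- sweep(d, 2L, model$center[common])
  drop(W %*% model$u[common])
}

#' @rdname gebv
#' @param object An `rrblup_model`.
#' @param ... Unused.
#' @export
predict.rrblup_model <- function(object, geno, ...) {
  fixed <- object$beta[["(Intercept)"]] +
    mean(c(0, object$beta[-1L]))        # average over year levels
  fixed + gebv(object, geno)
}

#' Cross-validated predictive ability of RR-BLUP
#'
#' Per replication, individuals are randomly partitioned into `folds` folds
#' (75/25 train/validation split for the default 4 folds); each fold in
#' turn is held out, the model is refitted on the remaining records, and
#' predictive ability is the Pearson correlation between the validation
#' individuals' GEBV and their year-adjusted observed means (records minus
#' the training fit's fixed year effects, averaged per individual).
#'
#' @inheritParams fit_rrblup
#' @param folds Number of folds (default 4).
#' @param reps Number of replications (default 100).
#' @param seed Optional integer seed.
#' @return List with `per_fold` (data frame `rep`, `fold`, `ability`),
#'   `mean_ability`, `assignments` (data frame `rep`, `genotype_id`,
#'   `fold`) and the settings. Folds with constant observed values are
#'   excluded with a warning.
#' @export
cross_validate <- function(pheno, geno, folds = 4, reps = 100, seed = NULL) {
  ids <- unique(pheno$genotype_id)
  if (length(ids) < 2 * folds)
    stop("need at least ", 2 * folds, " phenotyped individuals")
  with_seed(seed, {
    res <- vector("list", reps * folds)
    assignments <- vector("list", reps)
    ri <- 0L
    for (rep_i in seq_len(reps)) {
      assign_fold <- sample(rep_len(seq_len(folds), length(ids)))
      assignments[[rep_i]] <- data.frame(rep = rep_i, genotype_id = ids,
                                         fold = assign_fold,
                                         stringsAsFactors = FALSE)
      for (f in seq_len(folds)) {
        val_ids <- ids[assign_fold == f]
        train <- pheno[!pheno$genotype_id %in% val_ids, , drop = FALSE]
        fit <- fit_rrblup(train, geno)
        pred <- gebv(fit, geno[val_ids, ])
        obs <- year_adjusted_means(
          pheno[pheno$genotype_id %in% val_ids, , drop = FALSE], fit)
        obs <- obs[names(pred)]
        ri <- ri + 1L
        if (sd(obs) == 0 || sd(pred) == 0) {
          warning("constant values in validation fold ", f, " of rep ",
                  rep_i, "; fold excluded")
          res[[ri]] <- data.frame(rep = rep_i, fold = f, ability = NA_real_)
        } else {
          res[[ri]] <- data.frame(rep = rep_i, fold = f,
                                  ability = cor(pred, obs))
        }
      }
    }
    per_fold <- do.call(rbind, res)
    list(per_fold = per_fold,
         mean_ability = mean(per_fold$ability, na.rm = TRUE),
         assignments = do.call(rbind, assignments),
         folds = folds, reps = reps)
  })
}

## per-individual mean of records after removing the fitted year effects
year_adjusted_means <- function(pheno, model) {
  yr_eff <- setNames(c(0, model$beta[-1L]), model$year_levels)
  adj <- pheno$value - model$beta[["(Intercept)"]] -
    yr_eff[as.character(pheno$year)]
  tapply(adj, pheno$genotype_id, mean)
}

#' Predict trait values of target populations and compare generations
#'
#' Fits RR-BLUP models on random subsamples of the training population
#' (`frac` of the individuals per replication, mirroring repeated
#' cross-validation partitions), predicts every target individual with each
#' fit, averages the predictions over replications, and compares the
#' generation-wise distributions with [tukey_hsd()].
#'
#' @inheritParams fit_rrblup
#' @param targets Named list of complete [genotype_matrix()] objects, one
#'   per target generation; names are the generation labels.
#' @param reps Model replications to average (default 100).
#' @param frac Fraction of training individuals refitted per replication
#'   (default 0.75).
#' @param alpha Tukey HSD significance level (default 0.001).
#' @param seed Optional integer seed.
#' @return List with `predictions` (data frame `individual_id`,
#'   `generation`, `predicted`) and `tukey` (a [tukey_hsd()] object).
#' @export
predict_populations <- function(pheno, geno, targets, reps = 100,
                                frac = 0.75, alpha = 0.001, seed = NULL) {
  stopifnot(is.list(targets), length(targets) >= 1,
            !is.null(names(targets)))
  ids <- unique(pheno$genotype_id)
  n_sub <- max(2L, round(frac * length(ids)))
  with_seed(seed, {
    acc <- lapply(targets, function(tg) {
      numeric(nrow(tg$dosage))
    })
    for (r in seq_len(reps)) {
      sub <- sample(ids, n_sub)
      fit <- fit_rrblup(pheno[pheno$genotype_id %in% sub, , drop = FALSE],
                        geno)
      for (g in names(targets))
        acc[[g]] <- acc[[g]] + predict(fit, targets[[g]])
    }
    predictions <- do.call(rbind, lapply(names(targets), function(g) {
      data.frame(individual_id = rownames(targets[[g]]$dosage),
                 generation = g, predicted = acc[[g]] / reps,
                 stringsAsFactors = FALSE)
    }))
    tk <- if (length(targets) >= 2)
      tukey_hsd(predictions$predicted, predictions$generation, alpha = alpha)
    else NULL
    list(predictions = predictions, tukey = tk)
  })
}
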