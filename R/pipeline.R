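#' Run the full synthetic-population analysis pipeline
#'
#' Orchestrates the package's stages in dependency order:
#' `synthdata` (founder pool, SYN generations, phenotypes, GBS degradation),
#' `filter`, `impute`, `popdiv` (diversity, PCA, LD decay), `simulate`
#' (the founder-number x heritability variance experiment) and `predict`
#' (cross-validation and generation-wise predictions). Each stage writes
#' its tables (TSV) and summaries (JSON) under `out_dir`, and a run
#' manifest records the package version, per-stage seeds, parameters and
#' output checksums so any run can be reproduced bit for bit.
#'
#' Stages not listed in `config$stages` are skipped; a later stage first
#' looks for in-memory results of earlier stages and otherwise reads the
#' file paths given in `config$inputs` (elements `dosage`, `map`,
#' `labels`, `pheno`), so e.g. a popdiv-only run on existing files is
#' possible.
#'
#' @param config A nested list, or the path of a YAML file holding one.
#'   Recognized top-level fields: `out_dir` (required), `seed`, `stages`,
#'   `inputs`, and one list per stage (`synthdata`, `filter`, `impute`,
#'   `popdiv`, `simulate`, `predict`) overriding that stage's defaults.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("synthdata", "filter", "impute", "popdiv", "simulate",
                  "predict")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0) stop("unknown stage(s): ",
                                paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  stage_seed <- setNames(seed + 1000L * seq_along(all_stages), all_stages)
  state <- new.env(parent = emptyenv())
  manifest <- list(package = "synpop",
                   version = as.character(packageVersion("synpop")),
                   seed = seed, stages = stages,
                   stage_seeds = as.list(stage_seed),
                   parameters = config, outputs = list())
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs)
    missing_in <- paths[!file.exists(paths)]
    if (length(missing_in) > 0)
      stop("configured input file(s) do not exist: ",
           paste(missing_in, collapse = ", "))
    manifest$input_checksums <- as.list(tools::md5sum(paths))
  }
  for (st in intersect(all_stages, stages)) {
    files <- tryCatch(
      switch(st,
             synthdata = stage_synthdata(config, state, out_dir,
                                         stage_seed[[st]]),
             filter    = stage_filter(config, state, out_dir),
             impute    = stage_impute(config, state, out_dir),
             popdiv    = stage_popdiv(config, state, out_dir),
             simulate  = stage_simulate(config, state, out_dir,
                                        stage_seed[[st]]),
             predict   = stage_predict(config, state, out_dir,
                                       stage_seed[[st]])),
      error = function(e)
        stop("stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE))
    manifest$outputs[[st]] <- as.list(tools::md5sum(files))
  }
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(state = as.list(state), manifest = manifest))
}

stage_synthdata <- function(config, state, out_dir, seed) {
  p <- utils::modifyList(list(
    n_founders = 80, n_chromosomes = 5, n_snp_per_chromosome = 60,
    target_maf = 0.22, ld_blocks = list(block_size = 10, n_haplotypes = 4),
    n_parents = 20, n_crosses = 40, progeny_per_cross = 5,
    n_generations = 4, n_qtl = 100, v0 = 0.3, h2 = 0.6,
    years = 2, year_effects = c(0, 0.5), per_snp_missing_rate = 0.05),
    config$synthdata %||% list())
  set.seed(seed)
  pool <- generate_founder_pool(p$n_founders, p$n_chromosomes,
                                p$n_snp_per_chromosome, p$target_maf,
                                ld_blocks = p$ld_blocks)
  trait <- sample_qtl_effects(pool, n_qtl = p$n_qtl, v0 = p$v0, h2 = p$h2)
  parents <- subset_population(pool, sample.int(n_individuals(pool),
                                                p$n_parents))
  gens <- list(Parent = as_genotype_matrix(pool))
  pop <- parents
  for (g in seq_len(p$n_generations)) {
    pop <- advance_generation(pop, p$n_crosses, p$progeny_per_cross)
    gens[[sprintf("SYN%d", g)]] <- as_genotype_matrix(pop)
  }
  combined <- do.call(rbind, lapply(gens, function(g) g$dosage))
  geno_all <- genotype_matrix(combined, pool$map$chrom, pool$map$pos_bp,
                              pool$map$pos_cm,
                              individual_ids = rownames(combined),
                              snp_ids = pool$map$snp_id)
  labels <- data.frame(
    individual_id = rownames(combined),
    group = rep(names(gens), vapply(gens, function(g) nrow(g$dosage),
                                    integer(1))),
    stringsAsFactors = FALSE)
  gbs <- degrade_to_gbs(geno_all, p$per_snp_missing_rate)
  pheno <- generate_phenotypes(pool, trait, years = p$years,
                               year_effects = p$year_effects)
  state$pool <- pool; state$trait <- trait; state$gens <- gens
  state$geno_complete <- geno_all; state$gbs <- gbs
  state$labels <- labels; state$pheno <- pheno
  f <- c(dosage = file.path(out_dir, "gbs_dosage.tsv"),
         map = file.path(out_dir, "genetic_map.tsv"),
         labels = file.path(out_dir, "labels.tsv"),
         pheno = file.path(out_dir, "training_phenotypes.tsv"))
  write_dosage_tsv(gbs, f[["dosage"]], map_path = f[["map"]])
  write.table(labels, f[["labels"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_phenotype_tsv(pheno, f[["pheno"]])
  f
}

## read configured input files for stages run without the synthdata stage
load_inputs <- function(config, state) {
  if (is.null(state$gbs)) {
    ins <- config$inputs
    if (is.null(ins$dosage) || is.null(ins$map))
      stop("no in-memory genotypes and no `inputs$dosage`/`inputs$map` configured")
    state$gbs <- read_dosage_tsv(ins$dosage, ins$map)
    if (!is.null(ins$labels))
      state$labels <- read.table(ins$labels, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    if (!is.null(ins$pheno))
      state$pheno <- read_phenotype_tsv(ins$pheno)
  }
  invisible(state)
}

stage_filter <- function(config, state, out_dir) {
  p <- utils::modifyList(list(min_maf = 0.03, max_snp_missing = 0.10,
                              min_call_rate = 0.80),
                         config$filter %||% list())
  load_inputs(config, state)
  fl <- filter_genotypes(state$gbs, p$min_maf, p$max_snp_missing,
                         p$min_call_rate)
  state$filtered <- fl$geno
  f <- c(dosage = file.path(out_dir, "filtered_dosage.tsv"),
         map = file.path(out_dir, "filtered_map.tsv"),
         report = file.path(out_dir, "filter_report.json"))
  write_dosage_tsv(fl$geno, f[["dosage"]], map_path = f[["map"]])
  jsonlite::write_json(unclass(fl$report), f[["report"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  f
}

stage_impute <- function(config, state, out_dir) {
  p <- utils::modifyList(list(l = 30, k = 10), config$impute %||% list())
  load_inputs(config, state)
  geno <- state$filtered %||% state$gbs
  state$imputed <- ld_knni_impute(geno, l = p$l, k = p$k)
  f <- c(dosage = file.path(out_dir, "imputed_dosage.tsv"),
         map = file.path(out_dir, "imputed_map.tsv"))
  write_dosage_tsv(state$imputed, f[["dosage"]], map_path = f[["map"]])
  f
}

stage_popdiv <- function(config, state, out_dir) {
  p <- utils::modifyList(list(max_dist_bp = 1e7, r2_threshold = 0.2,
                              span = 0.3),
                         config$popdiv %||% list())
  load_inputs(config, state)
  geno <- state$imputed %||% state$filtered %||% state$gbs
  if (is.null(state$labels)) stop("popdiv requires group labels")
  labels <- state$labels
  labels <- labels[labels$individual_id %in% rownames(geno$dosage), ,
                   drop = FALSE]
  div <- diversity_summary(geno, labels)
  pca <- pca_structure(geno)
  ld <- ld_decay(geno, labels, max_dist_bp = p$max_dist_bp,
                 r2_threshold = p$r2_threshold, span = p$span)
  f <- c(diversity = file.path(out_dir, "diversity_summary.tsv"),
         pca = file.path(out_dir, "pca_coordinates.tsv"),
         ld = file.path(out_dir, "ld_decay.json"))
  write.table(div, f[["diversity"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  pcs <- data.frame(individual_id = rownames(pca$scores),
                    pca$scores[, seq_len(min(10, ncol(pca$scores))),
                               drop = FALSE])
  write.table(pcs, f[["pca"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(ld, function(x) list(mean_r2 = x$mean_r2,
                                decay_bp = x$decay_bp,
                                n_pairs = nrow(x$pairs))),
    f[["ld"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  state$popdiv <- list(diversity = div, pca = pca, ld = ld)
  f
}

stage_simulate <- function(config, state, out_dir, seed) {
  p <- utils::modifyList(list(
    parent_counts = c(7, 10, 15, 20, 25), h2_levels = c(0.4, 0.6, 0.8),
    n_qtl = 100, n_crosses = 50, progeny_per_cross = 10,
    n_generations = 4, iterations = 10, v0 = 0.3),
    config$simulate %||% list())
  if (is.null(state$pool)) stop("the simulate stage requires the synthdata stage")
  vt <- run_syn_experiment(state$pool, p$parent_counts, p$h2_levels,
                           n_qtl = p$n_qtl, n_crosses = p$n_crosses,
                           progeny_per_cross = p$progeny_per_cross,
                           n_generations = p$n_generations,
                           iterations = p$iterations, v0 = p$v0,
                           seed = seed)
  sm <- summarize_variance_table(vt)
  letters_by_h2 <- lapply(split(vt, vt$h2), function(v)
    tukey_hsd(v$var_a, v$parents)$letters)
  f <- c(table = file.path(out_dir, "variance_table.tsv"),
         summary = file.path(out_dir, "variance_summary.tsv"),
         tukey = file.path(out_dir, "variance_tukey_letters.json"))
  write.table(vt, f[["table"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sm, f[["summary"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(letters_by_h2, f[["tukey"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  state$variance_table <- vt
  f
}

stage_predict <- function(config, state, out_dir, seed) {
  p <- utils::modifyList(list(folds = 4, reps = 10, frac = 0.75,
                              alpha = 0.001),
                         config$predict %||% list())
  if (is.null(state$pheno)) stop("the predict stage requires phenotypes")
  if (is.null(state$gens)) stop("the predict stage requires the synthdata stage")
  train_geno <- state$gens$Parent
  targets <- state$gens[grep("^SYN", names(state$gens))]
  cv <- cross_validate(state$pheno, train_geno, folds = p$folds,
                       reps = p$reps, seed = seed)
  pp <- predict_populations(state$pheno, train_geno, targets,
                            reps = p$reps, frac = p$frac, alpha = p$alpha,
                            seed = seed + 1L)
  f <- c(predictions = file.path(out_dir, "predictions.tsv"),
         cv = file.path(out_dir, "cv_summary.json"),
         tukey = file.path(out_dir, "prediction_tukey_letters.json"))
  write.table(pp$predictions, f[["predictions"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mean_ability = cv$mean_ability,
                            folds = cv$folds, reps = cv$reps),
                       f[["cv"]], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  jsonlite::write_json(as.list(pp$tukey$letters), f[["tukey"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  state$prediction <- pp
  f
}
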