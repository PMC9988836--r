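# End-to-end orchestration: susceptibility screen -> (optional) backcross
# linkage scan -> imputation -> mixed-model association over the locus ->
# functional prioritization -> combined ranking. Each stage writes a TSV
# artifact into the output directory and a manifest records seeds and the
# config hash; with resume = TRUE a stage whose artifact already exists
# is loaded instead of recomputed, so deleting one artifact reruns only
# that stage and everything downstream of it.

#' Build and validate a pipeline configuration
#'
#' @param genotypes Path to a genotype TSV ([read_genotype_tsv()] dialect).
#' @param phenotypes Path to a dose-response TSV.
#' @param network Path to an edge-list TSV.
#' @param gene_sets Path to a GMT file.
#' @param genes_bed Path to a BED file of gene models.
#' @param out_dir Output directory for stage artifacts.
#' @param reference_strain Reference strain for the susceptibility screen.
#' @param locus List with `chrom`, `start`, `end` (1-based, inclusive)
#'   bounding the positional-candidate interval.
#' @param seeds List of per-stage seeds; `prioritize` is required (the
#'   only stochastic stage).
#' @param backcross,marker_map Optional paths to a backcross cohort TSV
#'   (animal_id, phenotype, marker columns) and marker map TSV.
#' @param hmm An [hmm_params()] for the imputation stage.
#' @param svm List of SVM-stage settings: `n_svms`, `folds`,
#'   `max_module_size`, `cost_rounds`.
#' @param emma List of mixed-model settings: `delta_range`, `n_grid`.
#' @param affected_threshold Pooled percent-affected at or above which a
#'   strain is coded susceptible (1) for the association scan.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, phenotypes, network, gene_sets,
                            genes_bed, out_dir, reference_strain, locus,
                            seeds, backcross = NULL, marker_map = NULL,
                            hmm = hmm_params(),
                            svm = list(n_svms = 100, folds = 10,
                                       max_module_size = 400,
                                       cost_rounds = 3),
                            emma = list(delta_range = c(1e-5, 1e5),
                                        n_grid = 100),
                            affected_threshold = 50) {
  if (is.null(seeds$prioritize))
    stop("config must provide an explicit seed for every stochastic ",
         "stage; missing: prioritize")
  stopifnot(is.list(locus),
            all(c("chrom", "start", "end") %in% names(locus)))
  if (locus$start >= locus$end) stop("locus start must be < end")
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 network = network, gene_sets = gene_sets,
                 genes_bed = genes_bed, out_dir = out_dir,
                 reference_strain = reference_strain, locus = locus,
                 seeds = seeds, backcross = backcross,
                 marker_map = marker_map, hmm = hmm, svm = svm,
                 emma = emma, affected_threshold = affected_threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror the
#'   [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$hmm)) raw$hmm <- do.call(hmm_params, raw$hmm)
  do.call(pipeline_config, raw)
}

write_stage_tsv <- function(df, path, seed = NA, hash = NA,
                            extra_header = character(0)) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(provenance_line(seed, hash), extra_header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()] (or path to its YAML file).
#' @param resume If TRUE, stages whose artifact already exists in
#'   `out_dir` are loaded, not recomputed.
#' @return Invisible list with the per-stage results and artifact paths.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  hash <- fnv1a_hash(unclass(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)
  dirty <- FALSE   # once a stage recomputes, downstream stages follow
  stage <- function(name, file, compute, load = read_stage_tsv) {
    path <- art(file)
    if (resume && !dirty && file.exists(path)) {
      message("[", name, "] reusing ", path)
      return(load(path))
    }
    dirty <<- TRUE
    message("[", name, "] computing")
    res <- tryCatch(compute(path), error = function(e)
      stop("stage '", name, "' failed (input hash ", hash, "): ",
           conditionMessage(e), call. = FALSE))
    res
  }

  screen <- stage("pheno-test", "01_susceptibility.tsv", function(path) {
    dr <- read_dose_response_tsv(config$phenotypes)
    s <- susceptibility_screen(dr, config$reference_strain)
    write_stage_tsv(s, path, hash = hash)
    s
  })

  linkage <- NULL
  if (!is.null(config$backcross)) {
    linkage <- stage("linkage-scan", "02_linkage.tsv", function(path) {
      bc_df <- read_stage_tsv(config$backcross)
      map <- read_stage_tsv(config$marker_map)
      geno <- as.matrix(bc_df[, map$marker_id, drop = FALSE])
      geno[geno == "NA" | geno == ""] <- NA_character_
      bc <- backcross_cohort(bc_df[c("animal_id", "phenotype")], map,
                             geno)
      res <- scan_markers(bc)
      write_stage_tsv(res, path, hash = hash)
      res
    })
  }

  imputed <- stage("impute", "03_imputed_genotypes.tsv", function(path) {
    gm <- read_genotype_tsv(config$genotypes)
    res <- impute_panel(gm, config$hmm)
    write_genotype_tsv(res$genotypes, path, config_hash = hash)
    jsonlite::write_json(res$summary$per_strain,
                         art("03_imputation_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    res$genotypes
  }, load = read_genotype_tsv)

  assoc <- stage("assoc", "04_association.tsv", function(path) {
    keep <- imputed$variants$chrom == config$locus$chrom &
      imputed$variants$pos >= config$locus$start &
      imputed$variants$pos <= config$locus$end
    if (!any(keep)) stop("no SNPs inside the locus interval")
    gm <- genotype_matrix(imputed$variants[keep, , drop = FALSE],
                          imputed$strains,
                          imputed$calls[keep, , drop = FALSE])
    pheno_tab <- rbind(
      screen[c("strain", "percent_affected")],
      data.frame(strain = config$reference_strain,
                 percent_affected = 0))
    y <- stats::setNames(
      as.numeric(pheno_tab$percent_affected >=
                   config$affected_threshold), pheno_tab$strain)
    strains <- intersect(gm$strains, names(y))
    if (length(strains) < 3L)
      stop("fewer than 3 strains with both genotype and phenotype")
    gm <- genotype_matrix(gm$variants, strains,
                          gm$calls[, strains, drop = FALSE])
    # kinship from complete-coverage SNPs: IBS over a complete matrix
    # is a scaled sum of Gram matrices, hence positive semidefinite,
    # whereas pairwise-overlap IBS on missing data need not be
    complete <- !apply(is.na(gm$calls), 1L, any)
    if (sum(complete) < 10L)
      stop("fewer than 10 complete-coverage SNPs for kinship ",
           "estimation; check imputation")
    K <- ibs_kinship(genotype_matrix(
      gm$variants[complete, , drop = FALSE], gm$strains,
      gm$calls[complete, , drop = FALSE]))
    res <- lrt_scan(gm, y[strains], K,
                    delta_range = config$emma$delta_range,
                    n_grid = config$emma$n_grid)
    res$neglog10p <- -log10(res$p_value)
    thr <- significance_thresholds(sum(!res$monomorphic))
    write_stage_tsv(res, path, hash = hash, extra_header = c(
      sprintf("# stringent_threshold=%.6g", thr$stringent),
      sprintf("# moderate_threshold=%.6g", thr$moderate)))
    res
  })

  functional <- stage("prioritize", "05_functional.tsv", function(path) {
    net <- read_network_tsv(config$network)
    sets <- read_gmt(config$gene_sets)
    genes <- read_bed(config$genes_bed)
    cand <- genes$gene_id[genes$chrom == config$locus$chrom &
                            genes$end > config$locus$start - 1L &
                            genes$start < config$locus$end]
    ensembles <- list()
    seed <- config$seeds$prioritize
    for (set_name in names(sets)) {
      mods <- cluster_gene_set(sets[[set_name]], net,
                               max_size = config$svm$max_module_size)
      for (mi in seq_along(mods)) {
        seed <- seed + 1L
        costs <- tune_cost(mods[[mi]], net, seed = seed,
                           rounds = config$svm$cost_rounds,
                           folds = config$svm$folds)
        ensembles[[length(ensembles) + 1L]] <- train_ensemble(
          mods[[mi]], net, costs, seed = seed,
          n_svms = config$svm$n_svms, folds = config$svm$folds,
          name = paste0(set_name, ".", mi))
      }
    }
    res <- score_candidates(ensembles, cand)
    write_stage_tsv(res, path, seed = config$seeds$prioritize,
                    hash = hash)
    res
  })

  ranking <- stage("rank", "06_gene_ranking.tsv", function(path) {
    genes <- read_bed(config$genes_bed)
    cand <- functional$gene_id
    locus_genes <- genes[genes$gene_id %in% cand, , drop = FALSE]
    asn <- assign_snps_to_genes(assoc, locus_genes)
    a_score <- gene_assoc_score(assoc, asn, cand)
    f_score <- stats::setNames(functional$neglog10_fpr,
                               functional$gene_id)[cand]
    tab <- combined_score(a_score, f_score)
    write_score_table(tab, path, seed = config$seeds$prioritize,
                      config_hash = hash)
    tab
  })

  manifest <- list(package_version =
                     as.character(utils::packageVersion("strainscan")),
                   config_hash = hash, seeds = config$seeds,
                   artifacts = list.files(config$out_dir))
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(screen = screen, linkage = linkage, imputed = imputed,
                 assoc = assoc, functional = functional,
                 ranking = ranking, manifest = manifest,
                 out_dir = config$out_dir))
}
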