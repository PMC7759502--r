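#' Default pipeline configuration
#'
#' All procedural defaults of the analysis in one overridable list:
#' detection fraction 20%, mean-abundance floor 0.001% (1e-5), clade
#' covariates sex + age + top-3 PCs, gene covariates sex + age, permutation
#' count B = 50000, significance level 0.05, FDR level 0.1, gene-set size
#' range 50-30000, rarefaction depth 3e6, PERMANOVA 1e5 permutations. The
#' simulation block describes the synthetic cohort used when no input paths
#' are given (26 cases / 77 controls).
#'
#' @param ... name = value overrides for any top-level entry.
#' @return nested list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_case = 26, n_control = 77, n_species = 150,
                    n_genes = 300, zero_inflation = 0.2, depth = 5e6,
                    spike_species = NULL, spike_genes = NULL),
    paths = list(counts = NULL, taxonomy = NULL, metadata = NULL,
                 gene_depth = NULL, genesets = NULL, gwas_pvals = NULL),
    filters = list(detect_frac = 0.20, min_mean_rel = 1e-5,
                   exclusion_list = character()),
    covariates = list(clade = c("sex", "age", "PC1", "PC2", "PC3"),
                      gene = c("sex", "age")),
    pca = list(k = 3, outlier_sd = 4.0),
    thresholds = list(B = 50000, alpha = 0.05, fdr_level = 0.1,
                      n_boot = 1000),
    gsea = list(min_size = 50, max_size = 30000, n_perm = 10000),
    diversity = list(rarefy_depth = 3e6, permanova_perm = 1e5,
                     alpha_variant = "welch")
  )
  utils::modifyList(cfg, list(...))
}

stage_seed <- function(root, stage) {
  (as.integer(root) + sum(utf8ToInt(stage)) * 2654L) %% 2147483647L
}

#' Run the full MWAS pipeline on a configuration
#'
#' Executes the stages in order -- cohort simulation (or loading), taxonomic
#' profiling, filtering, Box-Cox / rank-INT normalization, PCA with outlier
#' flagging, clade and gene association scans, permutation thresholds and
#' empirical FDR calls, preranked enrichment, MWAS-GWAS overlap, and
#' diversity comparisons -- and writes every result as TSV plus a JSON
#' provenance record into `out_dir`. A single root seed deterministically
#' derives per-stage seeds, so re-running a configuration reproduces every
#' stochastic output.
#'
#' @param config list from [default_config()] (or a YAML file path readable
#'   by [read_config()]).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list of in-memory results per stage.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("mwas_")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  # --- inputs -------------------------------------------------------------
  log_stage("stage: inputs")
  sim <- config$simulate
  spike_sp <- sim$spike_species
  spec <- cohort_spec(n_case = sim$n_case, n_control = sim$n_control,
                      n_species = sim$n_species,
                      zero_inflation = sim$zero_inflation,
                      depth = sim$depth, spike_list = spike_sp,
                      seed = stage_seed(config$seed, "simulate"))
  if (is.null(config$paths$counts)) {
    cohort <- generate_cohort(spec)
  } else {
    cohort <- list(counts = read_feature_table(config$paths$counts),
                   taxonomy = read_taxonomy(config$paths$taxonomy),
                   metadata = read_metadata(config$paths$metadata))
  }
  gene_spec <- spec
  gene_spec$spike_list <- sim$spike_genes
  genes <- if (is.null(config$paths$gene_depth))
    generate_gene_table(sim$n_genes, gene_spec)
  else list(depth = read_feature_table(config$paths$gene_depth),
            metadata = cohort$metadata)

  # --- profiles + filters -------------------------------------------------
  log_stage("stage: taxonomic profiles")
  tables <- quantify_taxa(cohort$counts, cohort$taxonomy)
  fc <- filter_clades(tables, cohort$metadata,
                      detect_frac = config$filters$detect_frac,
                      min_mean_rel = config$filters$min_mean_rel,
                      exclusion_list = config$filters$exclusion_list)
  fg <- filter_genes(genes$depth, genes$metadata,
                     detect_frac = config$filters$detect_frac)
  utils::write.table(fc$report, file.path(out_dir, "filter_report_clades.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- normalization + PCA ------------------------------------------------
  log_stage("stage: normalization")
  bx <- suppressWarnings(boxcox_table(fc$tables$L7))
  gene_norm <- suppressWarnings(normalize_genes(fg$table))
  pcs <- compute_pcs(bx$table, k = config$pca$k)
  outliers <- flag_outliers(pcs, config$pca$outlier_sd)
  if (length(outliers)) log_stage("PCA outlier sample(s): ",
                                  paste(outliers, collapse = ", "))

  # --- association --------------------------------------------------------
  log_stage("stage: association scans")
  clade_tabs <- lapply(fc$tables, function(t)
    suppressWarnings(boxcox_table(t))$table)
  clade_res <- run_mwas(clade_tabs, cohort$metadata,
                        covariates = config$covariates$clade, pcs = pcs)
  gene_res <- run_mwas(list(gene = gene_norm), genes$metadata,
                       covariates = config$covariates$gene)
  utils::write.table(clade_res, file.path(out_dir, "assoc_clades.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gene_res, file.path(out_dir, "assoc_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- empirical thresholds (species level) --------------------------------
  log_stage("stage: permutation thresholds (B = ", config$thresholds$B, ")")
  null <- permute_null(bx$table, cohort$metadata,
                       covariates = config$covariates$clade, pcs = pcs,
                       B = config$thresholds$B,
                       seed = stage_seed(config$seed, "permute"))
  obs <- scan_neglogp(bx$table, cohort$metadata,
                      covariates = config$covariates$clade, pcs = pcs)
  bonf <- empirical_bonferroni(null, alpha = config$thresholds$alpha,
                               n_boot = config$thresholds$n_boot,
                               seed = stage_seed(config$seed, "boot"))
  fdr <- empirical_fdr(obs, null, level = config$thresholds$fdr_level)
  utils::write.table(
    data.frame(rank = seq_along(fdr$thresholds),
               observed = fdr$observed, threshold = fdr$thresholds,
               feature_id = names(fdr$observed),
               significant = seq_along(fdr$observed) <= fdr$n_sig),
    file.path(out_dir, "fdr_calls.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # --- enrichment + overlap -----------------------------------------------
  log_stage("stage: enrichment")
  metric <- setNames(gene_res$beta, gene_res$feature_id)
  metric <- metric[!is.na(metric)]
  catalog <- if (is.null(config$paths$genesets)) {
    generate_genesets(20, names(metric),
                      size_range = c(min(config$gsea$min_size,
                                         max(1, length(metric) %/% 4)),
                                     min(config$gsea$max_size,
                                         max(2, length(metric) %/% 2))),
                      seed = stage_seed(config$seed, "genesets"))
  } else read_gmt(config$paths$genesets)
  enr <- gsea_preranked(metric, catalog,
                        min_size = min(config$gsea$min_size,
                                       length(metric) %/% 4),
                        max_size = config$gsea$max_size,
                        n_perm = config$gsea$n_perm,
                        seed = stage_seed(config$seed, "gsea"))
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  overlap <- NULL
  if (nrow(enr) >= 2) {
    mwas_path_p <- setNames(enr$p, enr$set_id)
    gwas_p <- if (is.null(config$paths$gwas_pvals))
      generate_gwas_pathway_pvals(names(mwas_path_p), dependence = 0.5,
                                  mwas_pvals = mwas_path_p,
                                  seed = stage_seed(config$seed, "gwas"))
    else read_pathway_pvals(config$paths$gwas_pvals)
    overlap <- pathway_overlap(mwas_path_p, gwas_p)
  }

  # --- diversity ----------------------------------------------------------
  log_stage("stage: diversity")
  depth_r <- min(config$diversity$rarefy_depth, min(colSums(cohort$counts)))
  rare <- rarefy_counts(cohort$counts, depth = depth_r,
                        seed = stage_seed(config$seed, "rarefy"))
  h <- shannon_per_sample(rare)
  is_case <- cohort$metadata$status[match(names(h),
                                          cohort$metadata$sample_id)] == 1
  at <- alpha_test(h[is_case], h[!is_case],
                   variant = config$diversity$alpha_variant)
  bc <- bray_curtis(sweep(rare, 2, colSums(rare), `/`))
  pmv <- permanova(bc, ifelse(is_case, "case", "control"),
                   permutations = config$diversity$permanova_perm,
                   seed = stage_seed(config$seed, "permanova"))
  utils::write.table(data.frame(sample_id = names(h), shannon = h),
                     file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_table(bc, file.path(out_dir, "bray_curtis.tsv"))

  # --- provenance ---------------------------------------------------------
  prov <- list(package = "metamwas",
               version = as.character(utils::packageVersion("metamwas")),
               seed = config$seed,
               config = config[setdiff(names(config), "paths")],
               p_sig = bonf$p_sig, p_sig_ci95 = bonf$ci95,
               n_fdr_calls = fdr$n_sig,
               alpha_diversity_p = at$p, permanova_p = pmv$p,
               pca_outliers = outliers)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(tables = fc$tables, clade_results = clade_res,
                 gene_results = gene_res, p_sig = bonf, fdr = fdr,
                 enrichment = enr, overlap = overlap,
                 alpha = at, permanova = pmv, outliers = outliers,
                 out_dir = out_dir))
}

#' Read a YAML pipeline configuration
#'
#' Values present in the file override [default_config()] entries.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}
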