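#' Specify a synthetic case-control metagenome cohort
#'
#' Collects the generative parameters for [generate_cohort()] and
#' [generate_gene_table()]. The abundance model is a per-feature log-normal
#' latent intensity combined with Bernoulli presence (zero inflation);
#' integer read counts are obtained by a per-sample multinomial draw at a
#' fixed sequencing depth, which reproduces the compositional, sparse
#' structure of real shotgun profiles. Case-control effects ("spikes") act
#' additively on the log-intensity scale before compositional closure, so a
#' spike of `delta` shifts the case-vs-control mean log relative abundance of
#' that feature by `delta` in expectation.
#'
#' @param n_case,n_control group sizes (each at least 2). Defaults follow a
#'   26-case / 77-control gut-metagenome study design.
#' @param n_species number of species-level features.
#' @param zero_inflation per-feature probability in `[0, 1)` that a
#'   feature is absent from a given sample.
#' @param log_mean_sd SD of the per-feature baseline log-intensity means.
#' @param noise_sd within-feature log-intensity SD across samples.
#' @param depth sequencing depth: reads per sample for the multinomial draw.
#' @param spike_list `NULL`, or a data frame with columns `feature_id` and
#'   `delta` giving the log-scale case-vs-control shift per spiked feature
#'   (sign encodes direction).
#' @param covariate_model list with elements `age_mean` (length-2, case then
#'   control), `age_sd`, `sex_p` (length-2 probability of sex == 1 per
#'   group) and `age_beta` (SD of per-feature log-intensity slopes per 10
#'   years of age; nonzero values create deliberate age confounding when the
#'   group age means differ). Ages are truncated to `[20, 90]`.
#' @param seed integer seed; every generator is reproducible given the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case = 26, n_control = 77, n_species = 200,
                        zero_inflation = 0.2, log_mean_sd = 2,
                        noise_sd = 1, depth = 5e6,
                        spike_list = NULL,
                        covariate_model = list(age_mean = c(45, 45),
                                               age_sd = 12,
                                               sex_p = c(0.5, 0.5),
                                               age_beta = 0),
                        seed = 1L) {
  stopifnot(n_case >= 2, n_control >= 2, n_species >= 1,
            zero_inflation >= 0, zero_inflation < 1,
            log_mean_sd > 0, noise_sd >= 0, depth >= 1)
  cm <- covariate_model
  cm$age_mean <- rep_len(cm$age_mean %||% 45, 2)
  cm$age_sd <- cm$age_sd %||% 12
  cm$sex_p <- rep_len(cm$sex_p %||% 0.5, 2)
  cm$age_beta <- cm$age_beta %||% 0
  if (!is.null(spike_list)) {
    spike_list <- as.data.frame(spike_list)
    stopifnot(all(c("feature_id", "delta") %in% names(spike_list)))
  }
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_species = as.integer(n_species),
                 zero_inflation = zero_inflation,
                 log_mean_sd = log_mean_sd, noise_sd = noise_sd,
                 depth = depth, spike_list = spike_list,
                 covariate_model = cm, seed = as.integer(seed)),
            class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

species_ids <- function(n) sprintf("s%04d", seq_len(n))

#' Synthetic taxonomy for a set of species
#'
#' Builds a complete six-level lineage (phylum L2 ... species L7) by nesting
#' species pairwise into genera, genera into families, and so on, plus a
#' genome length per species drawn log-uniformly between 1 and 8 Mb.
#'
#' @param n_species number of species.
#' @param seed integer seed (genome lengths are random).
#' @return data frame with columns `species_id`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `genome_length`.
#' @export
make_taxonomy <- function(n_species, seed = 1L) {
  set.seed(seed)
  i <- seq_len(n_species)
  grp <- function(x, k, tag) sprintf("%s%03d", tag, (x - 1L) %/% k + 1L)
  genus <- (i - 1L) %/% 2L + 1L
  family <- (genus - 1L) %/% 2L + 1L
  order <- (family - 1L) %/% 2L + 1L
  class <- (order - 1L) %/% 2L + 1L
  phylum <- (class - 1L) %/% 2L + 1L
  data.frame(species_id = species_ids(n_species),
             phylum = sprintf("p%03d", phylum),
             class = sprintf("c%03d", class),
             order = sprintf("o%03d", order),
             family = sprintf("f%03d", family),
             genus = sprintf("g%03d", genus),
             genome_length = round(exp(runif(n_species, log(1e6), log(8e6)))),
             stringsAsFactors = FALSE)
}

# Shared covariate draw so the taxon and gene generators describe the same
# individuals for a given spec.
cohort_metadata <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_case + spec$n_control
  status <- rep(c(1L, 0L), c(spec$n_case, spec$n_control))
  cm <- spec$covariate_model
  mu <- ifelse(status == 1L, cm$age_mean[1], cm$age_mean[2])
  # truncated-normal ages via inverse CDF on the truncated interval
  lo <- pnorm(20, mu, cm$age_sd); hi <- pnorm(90, mu, cm$age_sd)
  age <- qnorm(lo + runif(n) * (hi - lo), mu, cm$age_sd)
  sex <- rbinom(n, 1L, ifelse(status == 1L, cm$sex_p[1], cm$sex_p[2]))
  data.frame(sample_id = c(sprintf("case%03d", seq_len(spec$n_case)),
                           sprintf("ctrl%03d", seq_len(spec$n_control))),
             status = status, sex = sex, age = age,
             stringsAsFactors = FALSE)
}

spike_vector <- function(spec, ids) {
  delta <- setNames(numeric(length(ids)), ids)
  if (!is.null(spec$spike_list) && nrow(spec$spike_list) > 0) {
    bad <- setdiff(spec$spike_list$feature_id, ids)
    if (length(bad))
      stop("spiked feature id(s) not present: ", paste(bad, collapse = ", "))
    delta[spec$spike_list$feature_id] <- spec$spike_list$delta
  }
  delta
}

# features x samples matrix of latent (nonnegative) intensities.
# Spiked features are placed in the low-abundance tail of the baseline
# distribution: under compositional closure a planted effect on a dominant
# feature would shift the fractions of every other feature, breaking the
# exchangeability of non-spiked features between groups. Keeping the spiked
# mass share negligible makes that contract hold to high accuracy (and
# mirrors the observation that disease-associated taxa are rarely the
# dominant commensals).
latent_intensity <- function(spec, metadata, ids) {
  m <- length(ids); n <- nrow(metadata)
  delta <- spike_vector(spec, ids)
  mu <- rnorm(m, 0, spec$log_mean_sd)
  sp <- delta != 0
  if (any(sp))
    mu[sp] <- rnorm(sum(sp), -1.5 * spec$log_mean_sd - abs(delta[sp]), 0.25)
  # age slopes vary per feature: a slope common to all features would be a
  # per-sample factor that compositional closure removes exactly
  age_beta <- spec$covariate_model$age_beta
  slope <- if (age_beta != 0) rnorm(m, 0, age_beta) else numeric(m)
  eps <- matrix(rnorm(m * n, 0, spec$noise_sd), m, n)
  logint <- mu + outer(delta, metadata$status) +
    outer(slope, (metadata$age - 50) / 10) + eps
  present <- matrix(rbinom(m * n, 1L, 1 - spec$zero_inflation), m, n)
  out <- exp(logint) * present
  dimnames(out) <- list(ids, metadata$sample_id)
  out
}

#' Generate a synthetic case-control read-count cohort
#'
#' Draws latent per-species intensities under the model described in
#' [cohort_spec()], then allocates `spec$depth` reads per sample by a
#' multinomial draw with probabilities proportional to intensity times
#' genome length (longer genomes attract proportionally more reads, which
#' [quantify_taxa()] later undoes by length normalization).
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `counts` (species x samples integer matrix),
#'   `taxonomy` (see [make_taxonomy()]) and `metadata` (sample_id, status,
#'   sex, age).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  metadata <- cohort_metadata(spec)
  taxonomy <- make_taxonomy(spec$n_species, seed = spec$seed)
  ids <- taxonomy$species_id
  spike_vector(spec, ids)  # validate spike ids against the taxonomy
  set.seed((spec$seed + 104729L) %% 2147483647L)
  lambda <- latent_intensity(spec, metadata, ids)
  w <- lambda * taxonomy$genome_length
  counts <- vapply(seq_len(ncol(w)), function(j) {
    p <- w[, j]
    if (sum(p) <= 0) p <- rep(1, length(p))  # degenerate sample: uniform
    as.integer(rmultinom(1, size = spec$depth, prob = p))
  }, integer(nrow(w)))
  dimnames(counts) <- dimnames(w)
  list(counts = counts, taxonomy = taxonomy, metadata = metadata)
}

#' Generate a synthetic ORF/gene depth table
#'
#' Same latent log-normal x Bernoulli model and spiking contract as
#' [generate_cohort()], but emitted as nonnegative real per-gene depths
#' (mean per-base coverage), multiplied by a per-sample library-size factor
#' so that the per-sample depth normalization of [scale_gene_depth()] has
#' something to remove. Gene ids are `gene0001`, ... and spike ids in
#' `spec$spike_list` are matched against them.
#'
#' @param n_genes number of genes (>= 1).
#' @param spec a [cohort_spec()] (its `n_species` is ignored here).
#' @return list with `depth` (genes x samples numeric matrix), `annotation`
#'   (data frame gene_id -> protein accession) and `metadata` (identical to
#'   the cohort metadata for the same spec).
#' @export
generate_gene_table <- function(n_genes, spec) {
  stopifnot(n_genes >= 1, inherits(spec, "cohort_spec"))
  metadata <- cohort_metadata(spec)
  ids <- sprintf("gene%04d", seq_len(n_genes))
  set.seed((spec$seed + 224737L) %% 2147483647L)
  lambda <- latent_intensity(spec, metadata, ids)
  size_factor <- exp(rnorm(nrow(metadata), 0, 0.3))
  depth <- sweep(lambda, 2, size_factor, `*`)
  annotation <- data.frame(gene_id = ids,
                           accession = paste0("UniRef90_", toupper(ids)),
                           stringsAsFactors = FALSE)
  list(depth = depth, annotation = annotation, metadata = metadata)
}

#' Generate a synthetic gene-set catalog
#'
#' Draws `n_sets` sets of sizes uniform in `size_range`, each sampled
#' without replacement from `gene_ids`. If `enriched_set` is given, an
#' additional first set named `"enriched"` contains all of those genes,
#' padded with random background genes up to the lower size bound, so that
#' downstream enrichment on spiked simulations can recover it.
#'
#' @param n_sets number of background sets (0 allowed).
#' @param gene_ids universe of gene identifiers.
#' @param size_range length-2 integer range of set sizes, within
#'   `[1, length(gene_ids)]`.
#' @param enriched_set optional character vector of (typically spiked) genes.
#' @param seed integer seed.
#' @return named list of character vectors (a gene-set catalog).
#' @export
generate_genesets <- function(n_sets, gene_ids, size_range = c(50, 200),
                              enriched_set = NULL, seed = 1L) {
  stopifnot(n_sets >= 0, length(size_range) == 2,
            size_range[1] >= 1, size_range[2] <= length(gene_ids),
            size_range[1] <= size_range[2])
  set.seed(seed)
  catalog <- list()
  if (!is.null(enriched_set)) {
    stopifnot(all(enriched_set %in% gene_ids))
    fill <- max(0, size_range[1] - length(enriched_set))
    members <- unique(c(enriched_set,
                        sample(setdiff(gene_ids, enriched_set), fill)))
    catalog$enriched <- members
  }
  if (n_sets > 0) {
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
    bg <- lapply(sizes, function(k) sample(gene_ids, k))
    names(bg) <- sprintf("set%04d", seq_len(n_sets))
    catalog <- c(catalog, bg)
  }
  catalog
}

#' Generate GWAS-side pathway P-values with tunable MWAS dependence
#'
#' Emulates a host-GWAS pathway-enrichment P-value list to feed
#' [pathway_overlap()]. With `dependence = 0` the P-values are independent
#' Uniform(0, 1). With `dependence = d > 0`, each pathway copies the MWAS
#' significance classification (P < 0.05 vs >= 0.05) with probability `d`
#' (drawing uniformly within the matching interval) and is otherwise
#' Uniform(0, 1); at `d = 1` the two lists classify identically.
#'
#' @param pathway_ids character vector of pathway identifiers.
#' @param dependence number in `[0, 1]`.
#' @param mwas_pvals named numeric vector of MWAS pathway P-values (required
#'   when `dependence > 0`).
#' @param seed integer seed.
#' @return named numeric vector of P-values.
#' @export
generate_gwas_pathway_pvals <- function(pathway_ids, dependence = 0,
                                        mwas_pvals = NULL, seed = 1L) {
  stopifnot(dependence >= 0, dependence <= 1)
  if (dependence > 0 && is.null(mwas_pvals))
    stop("mwas_pvals required when dependence > 0")
  set.seed(seed)
  n <- length(pathway_ids)
  p <- runif(n)
  if (dependence > 0) {
    m <- mwas_pvals[pathway_ids]
    copy <- runif(n) < dependence
    sig <- !is.na(m) & m < 0.05
    p[copy & sig] <- runif(sum(copy & sig), 0, 0.05)
    p[copy & !sig] <- runif(sum(copy & !sig), 0.05, 1)
  }
  setNames(p, pathway_ids)
}
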