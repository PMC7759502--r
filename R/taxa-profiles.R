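#' Abundance table constructor
#'
#' Lightweight container: a features x samples numeric matrix carrying a
#' taxonomic `level` ("L2".."L7" or "gene") and a `unit` attribute
#' (`relative_fraction`, `normalized_depth` or `transformed`).
#'
#' @param mat numeric matrix, features in rows, samples in columns; both
#'   dimnames required, feature ids unique.
#' @param level character scalar.
#' @param unit character scalar.
#' @return the matrix with class `abundance_table`.
#' @export
abundance_table <- function(mat, level, unit) {
  stopifnot(is.matrix(mat), is.numeric(mat),
            !is.null(rownames(mat)), !is.null(colnames(mat)),
            !anyDuplicated(rownames(mat)))
  if (unit != "transformed") stopifnot(all(mat >= 0))
  structure(mat, level = level, unit = unit,
            class = c("abundance_table", "matrix", "array"))
}

taxa_levels <- c(L2 = "phylum", L3 = "class", L4 = "order",
                 L5 = "family", L6 = "genus", L7 = "species")

#' Multi-level taxonomic relative abundances from per-genome read counts
#'
#' Divides each genome's mapped-read count by its genome length, sums the
#' length-normalized values into every ancestor clade, and renormalizes each
#' level to per-sample fractions summing to one (compositional closure) at
#' six levels: L2 phylum, L3 class, L4 order, L5 family, L6 genus,
#' L7 species.
#'
#' @param read_counts species x samples matrix of nonnegative counts with
#'   species ids as rownames.
#' @param taxonomy data frame as produced by [make_taxonomy()]: `species_id`,
#'   `phylum`..`genus` lineage columns, `genome_length`.
#' @return named list `L2`..`L7` of [abundance_table()]s with unit
#'   `relative_fraction`.
#' @export
quantify_taxa <- function(read_counts, taxonomy) {
  stopifnot(is.matrix(read_counts), all(read_counts >= 0))
  missing <- setdiff(rownames(read_counts), taxonomy$species_id)
  if (length(missing))
    stop("species missing from taxonomy: ", paste(missing, collapse = ", "))
  zero <- colSums(read_counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(read_counts)[zero], collapse = ", "))
  tax <- taxonomy[match(rownames(read_counts), taxonomy$species_id), ]
  norm <- read_counts / tax$genome_length
  lineage <- cbind(tax[, c("phylum", "class", "order", "family", "genus")],
                   species = tax$species_id)
  out <- lapply(seq_along(taxa_levels), function(k) {
    agg <- rowsum(norm, group = lineage[[k]], reorder = TRUE)
    frac <- sweep(agg, 2, colSums(agg), `/`)
    abundance_table(frac, level = names(taxa_levels)[k],
                    unit = "relative_fraction")
  })
  names(out) <- names(taxa_levels)
  out
}

filter_one <- function(mat, status, detect_frac, min_mean_rel,
                       exclusion_list) {
  n <- ncol(mat)
  det <- rowMeans(mat > 0)
  in_case <- rowSums(mat[, status == 1L, drop = FALSE] > 0) > 0
  in_ctrl <- rowSums(mat[, status == 0L, drop = FALSE] > 0) > 0
  mean_rel <- rowMeans(mat)
  reason <- rep(NA_character_, nrow(mat))
  reason[!is.null(min_mean_rel) & mean_rel < (min_mean_rel %||% -Inf)] <-
    "low_abundance"
  reason[!(in_case & in_ctrl)] <- "absent_in_a_group"
  reason[det < detect_frac] <- "low_detection"
  reason[rownames(mat) %in% exclusion_list] <- "exclusion_list"
  reason
}

#' Apply the clade-level feature filters
#'
#' A clade is removed when it is (i) detected (strictly positive) in less
#' than `detect_frac` of all samples, (ii) detected in no case sample or no
#' control sample, (iii) has mean relative abundance below `min_mean_rel`
#' (default 0.001% = 1e-5 as a fraction), or (iv) appears in
#' `exclusion_list` (the contaminant / batch-effect hook for clades never
#' seen in reference cohorts).
#'
#' @param tables named list of [abundance_table()]s (one per level).
#' @param metadata data frame with `sample_id` and binary `status`
#'   covering all samples.
#' @param detect_frac detection-fraction cutoff (strict `<` removal).
#' @param min_mean_rel mean relative-abundance cutoff (strict `<` removal).
#' @param exclusion_list character vector of feature ids to drop.
#' @return list with `tables` (filtered) and `report` (data frame:
#'   level, feature_id, retained, reason).
#' @export
filter_clades <- function(tables, metadata, detect_frac = 0.20,
                          min_mean_rel = 1e-5,
                          exclusion_list = character()) {
  status <- metadata$status[match(colnames(tables[[1]]), metadata$sample_id)]
  if (anyNA(status)) stop("metadata does not cover all samples")
  reports <- list(); out <- list()
  for (lev in names(tables)) {
    mat <- tables[[lev]]
    reason <- filter_one(mat, status, detect_frac, min_mean_rel,
                         exclusion_list)
    keep <- is.na(reason)
    if (!any(keep)) warning("no features retained at level ", lev)
    out[[lev]] <- abundance_table(mat[keep, , drop = FALSE],
                                  level = attr(mat, "level") %||% lev,
                                  unit = attr(mat, "unit") %||% "relative_fraction")
    reports[[lev]] <- data.frame(level = lev, feature_id = rownames(mat),
                                 retained = keep, reason = reason,
                                 stringsAsFactors = FALSE)
  }
  list(tables = out, report = do.call(rbind, c(reports, make.row.names = FALSE)))
}

#' Apply the gene-level feature filters
#'
#' As [filter_clades()] but without the mean-abundance rule: a gene is
#' removed only when detected in less than `detect_frac` of samples or in no
#' sample of either group.
#'
#' @inheritParams filter_clades
#' @param gene_table features x samples matrix (or [abundance_table()]).
#' @return list with `table` (filtered matrix) and `report`.
#' @export
filter_genes <- function(gene_table, metadata, detect_frac = 0.20,
                         exclusion_list = character()) {
  status <- metadata$status[match(colnames(gene_table), metadata$sample_id)]
  if (anyNA(status)) stop("metadata does not cover all samples")
  reason <- filter_one(gene_table, status, detect_frac, NULL, exclusion_list)
  keep <- is.na(reason)
  if (!any(keep)) warning("no genes retained")
  list(table = gene_table[keep, , drop = FALSE],
       report = data.frame(level = "gene", feature_id = rownames(gene_table),
                           retained = keep, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Per-sample principal-component scores
#'
#' PCA of the sample x feature matrix. Features are centered and, by
#' default, scaled to unit variance (correlation PCA): per-feature Box-Cox
#' transforms leave widely different variances, and on a covariance basis
#' the leading components simply reproduce the few highest-variance
#' features — including any strongly case-control-differential one, which
#' conditioning would then erase. On the correlation basis the components
#' capture shared community structure instead. The sign of each component
#' is fixed so that its largest-magnitude feature loading is positive,
#' making scores reproducible across platforms.
#'
#' @param table features x samples matrix (typically the transformed
#'   species-level table).
#' @param k number of components (default 3, the usual covariate set).
#' @param scale scale features to unit variance (default `TRUE`);
#'   constant features are dropped before scaling.
#' @return samples x k matrix of scores (columns `PC1`..).
#' @export
compute_pcs <- function(table, k = 3, scale = TRUE) {
  x <- t(unclass(table))
  if (scale) {
    keep <- apply(x, 2, sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  if (k > min(dim(x)) || k >= nrow(x))
    stop("k exceeds the available rank (", min(nrow(x) - 1, ncol(x)), ")")
  pc <- prcomp(x, center = TRUE, scale. = scale)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(scores, 2, flip, `*`)
  rownames(scores) <- colnames(table)
  scores
}

#' Flag PCA outlier samples
#'
#' A sample is flagged when any of its component scores lies further than
#' `sd_threshold` standard deviations from that component's mean. Components
#' with zero variance flag nothing.
#'
#' @param pc_scores samples x k score matrix from [compute_pcs()].
#' @param sd_threshold positive number of SDs (default 4).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(pc_scores, sd_threshold = 4.0) {
  stopifnot(nrow(pc_scores) >= 3)
  bad <- rep(FALSE, nrow(pc_scores))
  for (j in seq_len(ncol(pc_scores))) {
    s <- sd(pc_scores[, j])
    if (s == 0) next
    z <- abs(pc_scores[, j] - mean(pc_scores[, j])) / s
    bad <- bad | (z > sd_threshold)
  }
  rownames(pc_scores)[bad]
}
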