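#' Effect-size-ranked gene-set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Genes are ranked by signed effect size (descending, ties broken by id).
#' For each catalog set (restricted to ranked genes, then filtered to sizes
#' within `[min_size, max_size]`; sets covering the whole list are excluded
#' because the miss increment is undefined), the enrichment score is the
#' signed maximum deviation of the weighted running sum: hits increment by
#' `|metric| / sum(|metric| over hits)` (weight exponent 1), misses decrement
#' by `1 / (N - Nh)`. Significance comes from gene-label permutation of set
#' membership: `b` counts permuted scores of the same sign at least as
#' extreme in magnitude, and `P = min(1, 2 (b + 1) / (n_perm + 1))`, so P is
#' never exactly zero. Bonferroni adjustment is over the tested sets.
#'
#' @param metric named numeric vector of effect sizes (names are gene ids).
#' @param catalog named list of character vectors (gene sets), e.g. from
#'   [generate_genesets()] or [read_gmt()].
#' @param min_size,max_size retained set-size range after intersection
#'   (defaults 50 and 30000).
#' @param n_perm membership permutations per set.
#' @param seed integer seed.
#' @return data frame `set_id`, `size_used`, `es`, `p`, `p_bonf`, ordered by
#'   `p`; excluded sets are absent.
#' @export
gsea_preranked <- function(metric, catalog, min_size = 50, max_size = 30000,
                           n_perm = 10000, seed = 1L) {
  stopifnot(!is.null(names(metric)), all(is.finite(metric)),
            !anyDuplicated(names(metric)))
  ord <- order(-metric, names(metric))
  metric <- metric[ord]
  genes <- names(metric)
  N <- length(genes)
  sizes <- vapply(catalog, function(s) length(intersect(s, genes)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  catalog <- catalog[keep]
  if (!length(catalog))
    return(data.frame(set_id = character(), size_used = integer(),
                      es = numeric(), p = numeric(), p_bonf = numeric()))
  set.seed(seed)
  rows <- lapply(names(catalog), function(id) {
    hit <- genes %in% catalog[[id]]
    es <- gsea_es(metric, hit)
    nh <- sum(hit)
    perm_es <- vapply(seq_len(n_perm), function(b) {
      h <- logical(N); h[sample.int(N, nh)] <- TRUE
      gsea_es(metric, h)
    }, numeric(1))
    if (es == 0) {
      p <- 1
    } else {
      b <- sum(sign(perm_es) == sign(es) & abs(perm_es) >= abs(es))
      p <- min(1, 2 * (b + 1) / (n_perm + 1))
    }
    data.frame(set_id = id, size_used = nh, es = es, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out[order(out$p, out$set_id), , drop = FALSE]
}

# Signed extremum of the weighted KS running sum over a ranked list.
gsea_es <- function(metric, hit) {
  nh <- sum(hit)
  N <- length(metric)
  w <- abs(metric)
  denom_hit <- sum(w[hit])
  inc <- ifelse(hit,
                if (denom_hit > 0) w / denom_hit else 1 / nh,
                -1 / (N - nh))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' MWAS-GWAS pathway-overlap test
#'
#' Classifies the pathways shared between a metagenome enrichment scan and a
#' host-GWAS pathway scan as significant (P < `alpha`) or not, and tests the
#' 2x2 cross-classification with Fisher's exact test (two-sided).
#'
#' @param mwas_p,gwas_p named numeric vectors of pathway P-values; only the
#'   shared pathway ids are used.
#' @param alpha classification threshold (default 0.05).
#' @return list with `table` (2x2: MWAS significance in rows, GWAS in
#'   columns), `odds_ratio` (conditional MLE), `p` (two-sided Fisher P),
#'   `n_shared`.
#' @export
pathway_overlap <- function(mwas_p, gwas_p, alpha = 0.05) {
  shared <- intersect(names(mwas_p), names(gwas_p))
  if (!length(shared)) stop("no shared pathway ids between the two lists")
  a <- factor(mwas_p[shared] < alpha, levels = c(TRUE, FALSE))
  b <- factor(gwas_p[shared] < alpha, levels = c(TRUE, FALSE))
  tab <- table(mwas = a, gwas = b)
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       n_shared = length(shared))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The P-value is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (the probability-mass two-sided rule of
#' [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @return two-sided P-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(table == round(table)))
  fisher.test(table)$p.value
}
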