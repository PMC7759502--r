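#' Harrell-Davis distribution-free quantile estimator
#'
#' Estimates the `q`-quantile of a sample as a beta-weighted sum of all
#' order statistics: `sum_i w_i x_(i)` with
#' `w_i = I_{i/n}(a, b) - I_{(i-1)/n}(a, b)`, `a = (n+1)q`,
#' `b = (n+1)(1-q)`, and `I` the regularized incomplete beta function.
#' Smooth in the data, equivariant under affine maps, and always inside
#' `[min(x), max(x)]`.
#'
#' @param x numeric sample, `length(x) >= 2`.
#' @param q quantile in (0, 1).
#' @return the estimate (numeric scalar).
#' @export
harrell_davis <- function(x, q) {
  stopifnot(length(x) >= 2, !anyNA(x))
  if (q <= 0 || q >= 1) stop("q must lie strictly in (0, 1)")
  n <- length(x)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  edges <- pbeta(seq(0, 1, length.out = n + 1), a, b)
  w <- diff(edges)
  sum(w * sort(x))
}

#' Phenotype-permutation null of the association scan
#'
#' Randomly permutes the case/control labels across samples (preserving the
#' case:control ratio; covariates travel with their samples so every
#' permuted scan retains covariate adjustment), reruns the full per-feature
#' logistic Wald scan for each of `B` permutations with the compiled IRLS
#' engine, and records each permuted scan's -log10 P-values sorted in
#' descending order. Row 1 of the result is therefore the null distribution
#' of the scan minimum P; column r the null of the rank-r statistic.
#'
#' @param table features x samples matrix of transformed abundances.
#' @param metadata data frame with `sample_id`, `status`, covariate columns.
#' @param covariates covariate names as in [run_mwas()].
#' @param pcs optional PC score matrix.
#' @param B number of permutations (production default 50000; a warning is
#'   issued below 100 where quantiles are unstable).
#' @param seed integer seed.
#' @param perm optional B x n matrix of 1-based sample index permutations,
#'   overriding the random draw (e.g. an exhaustive enumeration).
#' @return object of class `permutation_null`: list with `neglogp`
#'   (B x m matrix, rows sorted non-increasing), `B`, `seed`, `feature_ids`.
#' @export
permute_null <- function(table, metadata, covariates = c("sex", "age"),
                         pcs = NULL, B = 50000, seed = 1L, perm = NULL) {
  mat <- unclass(table)
  y <- as_binary(metadata$status[match(colnames(mat), metadata$sample_id)])
  covs <- build_covariates(metadata[match(colnames(mat),
                                          metadata$sample_id), ],
                           covariates, pcs)
  cmat <- if (is.null(covs)) matrix(0, ncol(mat), 0) else as.matrix(covs)
  n <- ncol(mat)
  if (is.null(perm)) {
    if (B < 100) warning("B < 100 permutations: quantile estimates unstable")
    set.seed(seed)
    perm <- t(replicate(B, sample.int(n)))
  } else {
    perm <- as.matrix(perm)
    B <- nrow(perm)
  }
  storage.mode(perm) <- "integer"
  neglogp <- cpp_perm_scan(t(mat), cmat, y, perm)
  colnames(neglogp) <- NULL
  structure(list(neglogp = neglogp, B = B, seed = seed,
                 feature_ids = rownames(mat)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation_null: B =", x$B, "iterations,",
      ncol(x$neglogp), "features, seed =", x$seed, "\n")
  invisible(x)
}

#' Empirical Bonferroni (metagenome-wide) significance threshold
#'
#' The empirical significance threshold `-log10(P_sig)` is the Harrell-Davis
#' `1 - alpha` quantile (default the 95th percentile) of the permutation
#' null of the minimum-P statistic, with a percentile-bootstrap 95%
#' confidence interval over the `B` null minima.
#'
#' @param null a [permute_null()] result.
#' @param alpha significance level (default 0.05).
#' @param n_boot bootstrap resamples for the CI (0 skips the CI).
#' @param seed seed for the bootstrap.
#' @return list with `p_sig` (on the -log10 scale), `ci95` (length-2 vector
#'   or NULL), `alpha`.
#' @export
empirical_bonferroni <- function(null, alpha = 0.05, n_boot = 1000,
                                 seed = 1L) {
  stopifnot(inherits(null, "permutation_null"), nrow(null$neglogp) > 0)
  mins <- null$neglogp[, 1]
  p_sig <- harrell_davis(mins, 1 - alpha)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b)
      harrell_davis(sample(mins, replace = TRUE), 1 - alpha), numeric(1))
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  list(p_sig = p_sig, ci95 = ci, alpha = alpha)
}

#' Rank-wise empirical FDR calls
#'
#' For each rank r, the threshold is the Harrell-Davis `1 - level` quantile
#' (default the 90th percentile, FDR 0.1) of the null distribution of the
#' rank-r -log10 P statistic. The observed statistics (sorted descending)
#' are compared rank-by-rank; a feature is called significant iff it exceeds
#' its rank's threshold *and* every better rank is also called (step-down
#' contiguity, which prevents isolated deep-rank calls).
#'
#' @param observed named numeric vector of observed -log10 P values (any
#'   order; sorted internally), length equal to the null's feature count.
#' @param null a [permute_null()] result.
#' @param level target FDR level (default 0.1).
#' @return list with `thresholds` (per-rank, non-increasing), `n_sig`,
#'   `significant_ids`, `level`, `observed` (sorted).
#' @export
empirical_fdr <- function(observed, null, level = 0.1) {
  stopifnot(inherits(null, "permutation_null"))
  m <- ncol(null$neglogp)
  if (length(observed) != m)
    stop("observed length (", length(observed),
         ") does not match null feature count (", m, ")")
  obs <- sort(observed, decreasing = TRUE)
  thresholds <- vapply(seq_len(m), function(r)
    harrell_davis(null$neglogp[, r], 1 - level), numeric(1))
  exceed <- obs > thresholds
  k <- if (length(exceed) && exceed[1]) {
    runs <- rle(exceed)
    runs$lengths[1]
  } else 0L
  list(thresholds = thresholds, n_sig = as.integer(k),
       significant_ids = names(obs)[seq_len(k)],
       level = level, observed = obs)
}
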