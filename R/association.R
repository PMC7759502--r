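#' Covariate-adjusted case-control test for one feature
#'
#' Logistic regression of the binary phenotype on the (transformed) feature
#' abundance plus covariates, fitted by iteratively reweighted least squares
#' ([stats::glm()], binomial family, logit link). The effect size is the
#' coefficient on the feature (a log odds ratio); the P-value is the
#' two-sided Wald test. Non-convergence and (quasi-)separation are flagged
#' with a reason code and `NA` results rather than a Firth-type fallback.
#' A Gaussian alternative (`family = "gaussian"`), in which the transformed
#' abundance is the response and case-control status the exposure, is
#' available for sensitivity analyses.
#'
#' @param phenotype binary vector (0/1, logical, or 2-level factor).
#' @param x numeric feature vector (same length; already transformed).
#' @param covariates optional numeric matrix/data frame of covariates.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @return one-row data frame: `beta`, `se`, `p`, `n_used`, `reason`
#'   (`NA` when the fit is clean).
#' @export
test_feature <- function(phenotype, x, covariates = NULL,
                         family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  y <- as_binary(phenotype)
  stopifnot(length(y) == length(x), !anyNA(x))
  bad <- function(reason) data.frame(beta = NA_real_, se = NA_real_,
                                     p = NA_real_, n_used = length(y),
                                     reason = reason,
                                     stringsAsFactors = FALSE)
  if (length(unique(y)) < 2) return(bad("single_class"))
  if (max(x) - min(x) < 1e-12) return(bad("constant"))
  dat <- if (family == "gaussian") data.frame(.y = x, .x = y) else
    data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  reason <- NA_character_
  fit <- withCallingHandlers(
    glm(form, data = dat, family = family),
    warning = function(w) {
      reason <<- if (grepl("fitted probabilities numerically 0 or 1",
                           conditionMessage(w)))
        "separation" else "non_convergence"
      invokeRestart("muffleWarning")
    })
  if (!is.na(reason)) return(bad(reason))
  cf <- summary(fit)$coefficients
  if (!".x" %in% rownames(cf)) return(bad("aliased"))
  data.frame(beta = cf[".x", 1], se = cf[".x", 2],
             p = cf[".x", 4], n_used = length(y),
             reason = NA_character_, stringsAsFactors = FALSE)
}

as_binary <- function(phenotype) {
  if (is.factor(phenotype)) phenotype <- as.integer(phenotype) - 1L
  if (is.logical(phenotype)) phenotype <- as.integer(phenotype)
  stopifnot(all(phenotype %in% c(0, 1)))
  as.numeric(phenotype)
}

build_covariates <- function(metadata, covariate_names, pcs = NULL) {
  if (is.null(covariate_names) || !length(covariate_names)) return(NULL)
  out <- list()
  for (nm in covariate_names) {
    if (nm %in% names(metadata)) {
      out[[nm]] <- metadata[[nm]]
    } else if (!is.null(pcs) && nm %in% colnames(pcs)) {
      v <- pcs[match(metadata$sample_id, rownames(pcs)), nm]
      out[[nm]] <- as.numeric(scale(v))  # PCs standardized to unit variance
    } else {
      stop("covariate not resolvable: ", nm)
    }
  }
  as.data.frame(out)
}

#' Per-feature association scan over one or more abundance tables
#'
#' Runs [test_feature()] for every retained feature of every table, with the
#' requested covariates (metadata columns `sex`, `age`, and/or PC scores
#' `PC1`..`PCk`; PCs are standardized to unit variance). Per-feature
#' failures are recorded via reason codes, never abort the scan. Results are
#' ordered by (level, ascending P).
#'
#' @param tables a single matrix/[abundance_table()] or a named list of them
#'   (transformed units expected).
#' @param metadata data frame with `sample_id`, `status` (1 = case), `sex`,
#'   `age`.
#' @param covariates character vector from `{sex, age, PC1, PC2, PC3, ...}`.
#' @param pcs optional samples x k PC score matrix from [compute_pcs()].
#' @param engine `"glm"` (default, [stats::glm()] with full diagnostics) or
#'   `"fast"` (compiled IRLS, identical Wald statistics, no separation
#'   diagnostics) -- the fast engine backs the permutation framework.
#' @param family passed to [test_feature()] (glm engine only).
#' @return data frame: `feature_id`, `level`, `beta`, `se`, `p`, `n_used`,
#'   `reason`.
#' @export
run_mwas <- function(tables, metadata, covariates = c("sex", "age"),
                     pcs = NULL, engine = c("glm", "fast"),
                     family = "binomial") {
  engine <- match.arg(engine)
  if (is.matrix(tables)) tables <- list(tables)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) attr(t, "level") %||% "gene",
                            character(1))
  res <- lapply(names(tables), function(lev) {
    mat <- unclass(tables[[lev]])
    y <- as_binary(metadata$status[match(colnames(mat), metadata$sample_id)])
    covs <- build_covariates(metadata[match(colnames(mat),
                                            metadata$sample_id), ],
                             covariates, pcs)
    if (engine == "fast" && family == "binomial") {
      cmat <- if (is.null(covs)) matrix(0, ncol(mat), 0) else
        as.matrix(covs)
      sc <- cpp_logit_scan(t(mat), cmat, y)
      data.frame(feature_id = rownames(mat), level = lev,
                 beta = sc$beta, se = sc$se,
                 p = pmin(1, 10^(-sc$neglog10p)),
                 n_used = ncol(mat),
                 reason = ifelse(is.na(sc$beta), "degenerate", NA_character_),
                 stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_len(nrow(mat)), function(i)
        test_feature(y, mat[i, ], covs, family = family))
      cbind(feature_id = rownames(mat), level = lev,
            do.call(rbind, rows))
    }
  })
  out <- do.call(rbind, res)
  out <- out[order(out$level, out$p, out$feature_id), ]
  rownames(out) <- NULL
  out
}

#' Observed scan statistics on the -log10 scale
#'
#' Computes the per-feature -log10 Wald P-values with the same compiled
#' IRLS engine used by [permute_null()], so that observed statistics and
#' their permutation null are numerically exchangeable. Returned sorted in
#' descending order with feature ids as names.
#'
#' @inheritParams run_mwas
#' @param table features x samples matrix of transformed abundances.
#' @return named numeric vector, sorted descending.
#' @export
scan_neglogp <- function(table, metadata, covariates = c("sex", "age"),
                         pcs = NULL) {
  mat <- unclass(table)
  y <- as_binary(metadata$status[match(colnames(mat), metadata$sample_id)])
  covs <- build_covariates(metadata[match(colnames(mat),
                                          metadata$sample_id), ],
                           covariates, pcs)
  cmat <- if (is.null(covs)) matrix(0, ncol(mat), 0) else as.matrix(covs)
  sc <- cpp_logit_scan(t(mat), cmat, y)
  sort(setNames(sc$neglog10p, rownames(mat)), decreasing = TRUE)
}

#' Genomic inflation factor of a P-value vector
#'
#' Median observed chi-square (1 df, from two-sided P) over its null median;
#' a diagnostic used to detect confounding in unadjusted scans.
#'
#' @param p vector of P-values.
#' @return lambda_GC (1 under a calibrated null).
#' @export
lambda_gc <- function(p) {
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi, na.rm = TRUE) / qchisq(0.5, df = 1, lower.tail = FALSE)
}
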