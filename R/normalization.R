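#' Box-Cox power transformation with maximum-likelihood lambda
#'
#' Transforms a single feature's abundance vector with
#' `y = (x^lambda - 1) / lambda` (natural log at `lambda = 0`), choosing
#' `lambda` to maximize the normal profile log-likelihood including the
#' Jacobian term, over a coarse grid on `[-3, 3]` refined by golden-section
#' search ([stats::optimize()]). Zeros (or negative values) are handled by
#' adding a pseudocount of half the smallest positive value before the
#' transform; an explicit `shift` overrides this.
#'
#' @param x numeric vector with at least 3 distinct values (after shift).
#' @param shift optional nonnegative pseudocount; default `NULL` means half
#'   the minimum positive value when `min(x) <= 0`, else 0.
#' @param lambda_range search interval for lambda.
#' @return list with `y` (transformed vector) and `fit` (list `lambda`,
#'   `shift`, `loglik`).
#' @export
boxcox_transform <- function(x, shift = NULL, lambda_range = c(-3, 3)) {
  stopifnot(is.numeric(x), !anyNA(x))
  if (is.null(shift)) {
    shift <- if (min(x) <= 0) {
      pos <- x[x > 0]
      if (!length(pos)) stop("degenerate feature: no positive values")
      min(pos) / 2
    } else 0
  }
  z <- x + shift
  if (any(z <= 0)) stop("values must be positive after shift")
  if (length(unique(z)) < 3) stop("degenerate feature: fewer than 3 distinct values")
  n <- length(z)
  slog <- sum(log(z))
  ll <- function(lambda) {
    y <- bc_apply(z, lambda)
    -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * slog
  }
  grid <- seq(lambda_range[1], lambda_range[2], by = 0.25)
  lg <- vapply(grid, ll, numeric(1))
  i <- which.max(lg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(ll, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda <- opt$maximum
  list(y = bc_apply(z, lambda),
       fit = list(lambda = lambda, shift = shift, loglik = opt$objective))
}

bc_apply <- function(z, lambda) {
  if (abs(lambda) < 1e-8) log(z) else (z^lambda - 1) / lambda
}

#' Box-Cox transform every feature of an abundance table
#'
#' Applies [boxcox_transform()] per feature row; features that are
#' degenerate (fewer than 3 distinct values) are dropped with a warning.
#'
#' @param table features x samples matrix or [abundance_table()].
#' @return list with `table` (transformed matrix, unit `transformed`) and
#'   `lambdas` (named vector of fitted lambda values).
#' @export
boxcox_table <- function(table) {
  mat <- unclass(table)
  rows <- vector("list", nrow(mat)); lambdas <- rep(NA_real_, nrow(mat))
  ok <- rep(TRUE, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    res <- tryCatch(boxcox_transform(mat[i, ]), error = function(e) NULL)
    if (is.null(res)) { ok[i] <- FALSE; next }
    rows[[i]] <- res$y; lambdas[i] <- res$fit$lambda
  }
  if (any(!ok))
    warning(sum(!ok), " degenerate feature(s) dropped before transformation")
  out <- do.call(rbind, rows[ok])
  dimnames(out) <- list(rownames(mat)[ok], colnames(mat))
  list(table = abundance_table(out, level = attr(table, "level") %||% "gene",
                               unit = "transformed"),
       lambdas = setNames(lambdas[ok], rownames(mat)[ok]))
}

#' Per-sample depth scaling of a gene abundance table
#'
#' First step of the two-step gene normalization: each sample's column is
#' divided by its own total ORF depth, removing library-size differences.
#'
#' @param orf_depth_table genes x samples matrix of nonnegative depths.
#' @return matrix with columns summing to 1.
#' @export
scale_gene_depth <- function(orf_depth_table) {
  tot <- colSums(orf_depth_table)
  bad <- tot <= 0
  if (any(bad))
    stop("sample(s) with zero total depth: ",
         paste(colnames(orf_depth_table)[bad], collapse = ", "))
  sweep(orf_depth_table, 2, tot, `/`)
}

#' Rank-based inverse normal transformation (Blom offset)
#'
#' Maps values to normal scores `qnorm((r - c) / (n - 2c + 1))` with the
#' Blom offset `c = 3/8`; ties receive their average rank. Second step of
#' the gene normalization, correcting per-gene distributional heterogeneity
#' before the association scan.
#'
#' @param x numeric vector, `length(x) >= 3`, not all tied.
#' @param offset rank offset `c` (default 3/8).
#' @return numeric vector of normal scores (mean approximately 0).
#' @export
rank_int <- function(x, offset = 3 / 8) {
  stopifnot(is.numeric(x), !anyNA(x), length(x) >= 3)
  if (length(unique(x)) == 1) stop("degenerate feature: all values tied")
  r <- rank(x, ties.method = "average")
  qnorm((r - offset) / (length(x) - 2 * offset + 1))
}

#' Two-step gene normalization
#'
#' Convenience wrapper: [scale_gene_depth()] then [rank_int()] per gene.
#' Degenerate (all-tied) genes are dropped with a warning.
#'
#' @param orf_depth_table genes x samples matrix of nonnegative depths.
#' @return [abundance_table()] of normal scores, unit `transformed`.
#' @export
normalize_genes <- function(orf_depth_table) {
  scaled <- scale_gene_depth(orf_depth_table)
  ok <- apply(scaled, 1, function(v) length(unique(v)) > 1)
  if (any(!ok)) warning(sum(!ok), " all-tied gene(s) dropped")
  out <- t(apply(scaled[ok, , drop = FALSE], 1, rank_int))
  colnames(out) <- colnames(orf_depth_table)
  abundance_table(out, level = "gene", unit = "transformed")
}
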