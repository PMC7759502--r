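#' Rarefy a count table to a common depth
#'
#' Down-samples every sample (column) to exactly `depth` reads without
#' replacement (via [vegan::rrarefy()]), so diversity comparisons are not
#' driven by library size. Samples already at `depth` are returned
#' unchanged; samples below `depth` are an error.
#'
#' @param counts features x samples matrix of nonnegative integers.
#' @param depth target reads per sample (production default 3e6).
#' @param seed integer seed.
#' @return matrix of the same shape with all column sums equal to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 3e6, seed = 1L) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  tot <- colSums(counts)
  low <- tot < depth
  if (any(low))
    stop("sample(s) below rarefaction depth: ",
         paste(colnames(counts)[low], collapse = ", "))
  set.seed(seed)
  # vegan warns when the smallest positive count exceeds 1 (a heuristic for
  # non-count input); simulated tables trip it legitimately
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), sample = depth)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  dimnames(out) <- dimnames(counts)
  out
}

#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` over nonzero fractions, natural logarithm
#' (delegates to [vegan::diversity()]).
#'
#' @param p relative-abundance vector summing to 1 (within 1e-9).
#' @return Shannon index (numeric scalar).
#' @export
shannon <- function(p) {
  if (any(p < 0)) stop("negative abundances")
  if (abs(sum(p) - 1) > 1e-9) stop("abundances must sum to 1")
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Per-sample Shannon indices of a count or abundance table
#'
#' @param table features x samples matrix; columns are closed to fractions
#'   before the index is computed.
#' @return named numeric vector (one index per sample).
#' @export
shannon_per_sample <- function(table) {
  frac <- sweep(table, 2, colSums(table), `/`)
  apply(frac, 2, shannon)
}

#' Case-control comparison of alpha diversity
#'
#' Two-sided t-test of the mean Shannon index difference. Welch's unequal-
#' variance test is the default; Student's equal-variance variant is
#' selectable.
#'
#' @param h_case,h_control Shannon indices per group (each length >= 2).
#' @param variant `"welch"` (default) or `"student"`.
#' @return list with `t`, `p`, `df`, `variant`.
#' @export
alpha_test <- function(h_case, h_control, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(length(h_case) >= 2, length(h_control) >= 2)
  tt <- t.test(h_case, h_control, var.equal = (variant == "student"))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), variant = variant)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all sample pairs
#' (delegates to [vegan::vegdist()]).
#'
#' @param table features x samples matrix of nonnegative abundances.
#' @return samples x samples symmetric matrix, zero diagonal, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(all(table >= 0))
  as.matrix(vegan::vegdist(t(table), method = "bray"))
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities
#' (`SS_total = sum_{i<j} d_ij^2 / n`, within-group analogously per group)
#' into between- and within-group components and forms the pseudo-F
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`. The P-value is the
#' permutation tail probability `(#{F_perm >= F_obs} + 1) / (n_perm + 1)`
#' under random relabeling, or the exact enumeration fraction when
#' `permutations = "exact"` (all distinct label assignments; feasible for
#' small n).
#'
#' @param d symmetric dissimilarity matrix (e.g. [bray_curtis()]).
#' @param groups group labels, >= 2 groups with >= 2 samples each.
#' @param permutations integer count (production default 1e5) or `"exact"`.
#' @param seed integer seed (ignored for exact enumeration).
#' @return list with `pseudo_F`, `p`, `n_perm`, `exact`.
#' @export
permanova <- function(d, groups, permutations = 1e5, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(nrow(d) == ncol(d), length(groups) == nrow(d))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("singleton group(s): ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  if (identical(permutations, "exact")) {
    perms <- enumerate_labelings(groups)
    f_perm <- vapply(perms, function(g) permanova_f(d2, g), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    return(list(pseudo_F = f_obs, p = p, n_perm = length(perms),
                exact = TRUE))
  }
  set.seed(seed)
  n_perm <- as.integer(permutations)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (permanova_f(d2, sample(groups)) >= f_obs - 1e-12) count <- count + 1L
  }
  list(pseudo_F = f_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
       exact = FALSE)
}

# All distinct assignments of the observed multiset of labels (two-group
# case enumerated via combn; the observed labeling is included).
enumerate_labelings <- function(groups) {
  levs <- unique(groups)
  if (length(levs) != 2)
    stop("exact enumeration implemented for two groups")
  n <- length(groups)
  k <- sum(groups == levs[1])
  combos <- utils::combn(n, k, simplify = FALSE)
  lapply(combos, function(idx) {
    g <- rep(levs[2], n)
    g[idx] <- levs[1]
    g
  })
}
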