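test_that("Harrell-Davis estimator: exact cases and incomplete-beta oracle", {
  expect_equal(harrell_davis(rep(3.7, 10), 0.25), 3.7)
  expect_equal(harrell_davis(1:9, 0.5), 5)  # weight symmetry about center
  x <- c(1, 2, 3, 4, 10)
  expect_lt(abs(harrell_davis(x, 0.95) - hd_integrate(x, 0.95)), 1e-10)
  expect_lt(abs(harrell_davis(x, 0.5) - hd_integrate(x, 0.5)), 1e-10)
  expect_error(harrell_davis(x, 1), "q")
})

test_that("Harrell-Davis estimator: monotone in q, bounded, equivariant", {
  set.seed(16)
  x <- rexp(40)
  qs <- seq(0.05, 0.95, 0.05)
  hd <- vapply(qs, function(q) harrell_davis(x, q), numeric(1))
  expect_false(is.unsorted(hd))
  expect_true(all(hd >= min(x) & hd <= max(x)))
  expect_equal(harrell_davis(3 * x + 2, 0.9),
               3 * harrell_davis(x, 0.9) + 2, tolerance = 1e-12)
})

test_that("permutation null rows are sorted and the object is reproducible", {
  spec <- cohort_spec(n_case = 15, n_control = 15, n_species = 25,
                      depth = 1e5, seed = 17)
  cohort <- generate_cohort(spec)
  bx <- suppressWarnings(
    boxcox_table(quantify_taxa(cohort$counts, cohort$taxonomy)$L7))
  null1 <- permute_null(bx$table, cohort$metadata, B = 150, seed = 3)
  null2 <- permute_null(bx$table, cohort$metadata, B = 150, seed = 3)
  expect_identical(null1$neglogp, null2$neglogp)
  expect_true(all(apply(null1$neglogp, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(null1$neglogp >= 0))
  # the unpermuted scan has the same length as a null row
  obs <- scan_neglogp(bx$table, cohort$metadata)
  expect_length(obs, ncol(null1$neglogp))
  expect_warning(permute_null(bx$table, cohort$metadata, B = 50, seed = 1),
                 "unstable")
})

test_that("single-feature exact enumeration reproduces the feature's permutation P", {
  # n = 8 (4 cases / 4 controls): enumerate all C(8,4) = 70 label splits
  set.seed(18)
  x <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, "f1"))
  tab <- t(x); rownames(tab) <- "f1"
  colnames(tab) <- paste0("s", 1:8)
  md <- data.frame(sample_id = paste0("s", 1:8),
                   status = rep(c(1L, 0L), each = 4),
                   sex = 0L, age = 40)
  combos <- utils::combn(8, 4, simplify = FALSE)
  # index permutations realizing every distinct assignment of the labels
  perm <- t(vapply(combos, function(idx) {
    out <- integer(8); out[idx] <- 1:4; out[-idx] <- 5:8; out
  }, integer(8)))
  null <- permute_null(tab, md, covariates = NULL, perm = perm)
  obs <- scan_neglogp(tab, md, covariates = NULL)
  p_min <- mean(null$neglogp[, 1] >= obs[1] - 1e-12)
  # oracle: exact permutation P of the single feature's Wald statistic by glm
  stat <- vapply(combos, function(idx) {
    yy <- integer(8); yy[idx] <- 1L
    g <- suppressWarnings(glm(yy ~ x[, 1], family = binomial))
    abs(coef(summary(g))[2, 3])
  }, numeric(1))
  g0 <- suppressWarnings(glm(md$status ~ x[, 1], family = binomial))
  p_exact <- mean(stat >= abs(coef(summary(g0))[2, 3]) - 1e-9)
  expect_equal(p_min, p_exact)
})

test_that("empirical Bonferroni threshold: degenerate and analytic cases", {
  mk_null <- function(mat) structure(
    list(neglogp = mat, B = nrow(mat), seed = 1,
         feature_ids = paste0("f", seq_len(ncol(mat)))),
    class = "permutation_null")
  # constant minima give the constant back with a zero-width CI
  const <- mk_null(matrix(2.5, 500, 1))
  res <- empirical_bonferroni(const)
  expect_equal(res$p_sig, 2.5)
  expect_equal(res$ci95, c(2.5, 2.5))
  # uniform P, m = 1: threshold is -log10(0.05)
  set.seed(19)
  uni <- mk_null(matrix(-log10(runif(10000)), ncol = 1))
  res_u <- empirical_bonferroni(uni)
  expect_lt(abs(res_u$p_sig - (-log10(0.05))), 0.06)
  expect_gte(-log10(0.05), res_u$ci95[1])
  expect_lte(-log10(0.05), res_u$ci95[2])
  # invariance to iteration order
  shuf <- mk_null(uni$neglogp[sample(10000), , drop = FALSE])
  expect_equal(empirical_bonferroni(shuf, n_boot = 0)$p_sig,
               empirical_bonferroni(uni, n_boot = 0)$p_sig)
})

test_that("rank-wise FDR thresholds and step-down contiguity", {
  # constant null matrix: thresholds equal its row values exactly
  null <- structure(list(neglogp = matrix(rep(c(2, 1, 0.5), each = 200),
                                          200, 3),
                         B = 200, seed = 1, feature_ids = c("a", "b", "c")),
                    class = "permutation_null")
  obs <- c(a = 3.0, b = 0.8, c = 0.6)
  res <- empirical_fdr(obs, null)
  expect_equal(res$thresholds, c(2, 1, 0.5))
  # rank 3 exceeds its threshold but rank 2 does not: contiguity -> 1 call
  expect_equal(res$n_sig, 1L)
  expect_identical(res$significant_ids, "a")
  # everything below thresholds: no calls
  low <- c(a = 1.0, b = 0.5, c = 0.1)
  expect_equal(empirical_fdr(low, null)$n_sig, 0L)
  expect_error(empirical_fdr(obs[1:2], null), "match")
  # thresholds are non-increasing for a stochastic null too
  set.seed(20)
  raw <- t(apply(matrix(-log10(runif(300 * 10)), 300, 10), 1, sort,
                 decreasing = TRUE))
  null2 <- structure(list(neglogp = raw, B = 300, seed = 1,
                          feature_ids = paste0("f", 1:10)),
                     class = "permutation_null")
  thr <- empirical_fdr(setNames(rep(0, 10), paste0("f", 1:10)),
                       null2)$thresholds
  expect_false(is.unsorted(rev(thr)))
})
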