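test_that("rarefaction hits the target depth exactly and is unbiased", {
  set.seed(26)
  counts <- named_matrix(rpois(40, 500), paste0("f", 1:10), paste0("s", 1:4))
  r <- rarefy_counts(counts, depth = 1000, seed = 1)
  expect_true(all(colSums(r) == 1000))
  # a sample already at depth is returned unchanged
  c2 <- counts; c2[, 1] <- c(1000, rep(0, 9))
  expect_equal(rarefy_counts(c2, depth = 1000, seed = 1)[, 1], c2[, 1])
  expect_error(rarefy_counts(counts, depth = 1e7), "s1")
  # hypergeometric mean: E[count_f] = depth * count_f / total
  tot <- sum(counts[, 2])
  draws <- vapply(1:300, function(i)
    rarefy_counts(counts[, 2, drop = FALSE], depth = 800, seed = i)[3, 1],
    numeric(1))
  expected <- 800 * counts[3, 2] / tot
  se <- sqrt(800 * (counts[3, 2] / tot) * (1 - counts[3, 2] / tot) *
             (tot - 800) / (tot - 1) / 300)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("Shannon index: closed-form cases and zero-padding invariance", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon(c(0.5, 0.25, 0.25, 0, 0)),
               shannon(c(0.5, 0.25, 0.25)))
  expect_error(shannon(c(0.7, -0.2, 0.5)), "negative")
  expect_error(shannon(c(0.5, 0.4)), "sum")
})

test_that("alpha-diversity t-test variants behave as documented", {
  expect_equal(alpha_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(alpha_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # hand-computed Welch test on 5 + 5 values
  a <- c(2.1, 2.5, 1.9, 2.3, 2.2); b <- c(1.8, 2.0, 1.7, 1.9, 2.1)
  res <- alpha_test(a, b)
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # equal-variance data: welch and student agree closely
  set.seed(27)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  expect_lt(abs(alpha_test(x, y)$p -
                alpha_test(x, y, variant = "student")$p), 0.01)
})

test_that("Bray-Curtis dissimilarity: closed forms and invariances", {
  m <- named_matrix(c(1, 2, 2, 1, 1, 2, 0, 3), paste0("f", 1:2),
                    paste0("s", 1:4))
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 1 / 3)  # |1-2| + |2-1| over 6
  expect_equal(d["s1", "s3"], 0)      # identical samples
  disj <- named_matrix(c(4, 0, 0, 9), paste0("f", 1:2), c("a", "b"))
  expect_equal(bray_curtis(disj)["a", "b"], 1)  # disjoint supports
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  # joint rescaling of all samples leaves the matrix unchanged
  expect_equal(bray_curtis(m * 7), d)
})

test_that("PERMANOVA matches exhaustive enumeration via an adonis2 oracle", {
  set.seed(28)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  groups <- rep(c("a", "b"), each = 3)
  res <- permanova(d, groups, permutations = "exact")
  expect_equal(res$n_perm, 20)
  # oracle: adonis2 pseudo-F for every one of the 20 label assignments
  combos <- utils::combn(6, 3, simplify = FALSE)
  f_all <- vapply(combos, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    unname(vegan::adonis2(as.dist(d) ~ g, permutations = 1)$F[1])
  }, numeric(1))
  f_obs <- unname(vegan::adonis2(as.dist(d) ~ groups, permutations = 1)$F[1])
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-10)
  expect_equal(res$p, mean(f_all >= f_obs - 1e-12))
})

test_that("PERMANOVA: separated blocks, relabeling invariance, errors", {
  # within-group distance 0, between-group 1: observed F is the maximum
  d <- matrix(1, 8, 8)
  d[1:4, 1:4] <- 0; d[5:8, 5:8] <- 0
  groups <- rep(c("x", "y"), each = 4)
  res <- permanova(d, groups, permutations = "exact")
  combos <- utils::combn(8, 4, simplify = FALSE)
  f_all <- vapply(combos, function(idx) {
    g <- rep("y", 8); g[idx] <- "x"
    metamwas:::permanova_f(d^2, g)
  }, numeric(1))
  expect_equal(res$pseudo_F, max(f_all))
  # relabeling group names leaves P unchanged
  res2 <- permanova(d, c("x" = "ctrl", "y" = "case")[groups],
                    permutations = "exact")
  expect_equal(res2$p, res$p)
  expect_error(permanova(d, c(rep("x", 7), "y")), "singleton")
  expect_error(permanova(d, rep("x", 8)), "two groups")
})

test_that("random permutation P is valid and near-uniform under the null", {
  set.seed(29)
  ps <- replicate(60, {
    pts <- matrix(rnorm(24), 12, 2)
    d <- as.matrix(dist(pts))
    permanova(d, sample(rep(c("a", "b"), each = 6)),
              permutations = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps < 0.3), 0.1)
  expect_lt(mean(ps < 0.05), 0.18)
  expect_true(all(ps > 0 & ps <= 1))
})
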