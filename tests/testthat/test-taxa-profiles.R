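test_that("length normalization and closure match the hand computation", {
  tax <- tiny_taxonomy()[1:2, ]  # spA len 1000, spB len 2000, same genus
  counts <- named_matrix(c(10, 10), c("spA", "spB"), "smp1")
  tabs <- quantify_taxa(counts, tax)
  # count/length = 0.01 and 0.005 -> fractions 2/3, 1/3; genus g1 = 1
  expect_equal(unname(tabs$L7[, "smp1"]), c(2 / 3, 1 / 3))
  expect_equal(unname(tabs$L6["g1", "smp1"]), 1)
})

test_that("single-species cohorts give unit fractions at all six levels", {
  tax <- tiny_taxonomy()[1, ]
  counts <- named_matrix(c(5, 17, 3), "spA", paste0("smp", 1:3))
  tabs <- quantify_taxa(counts, tax)
  for (lev in names(tabs)) expect_true(all(tabs[[lev]] == 1))
})

test_that("row order does not affect level tables, and columns close to 1", {
  set.seed(2)
  spec <- cohort_spec(n_case = 4, n_control = 4, n_species = 24,
                      depth = 1e4, seed = 2)
  cohort <- generate_cohort(spec)
  tabs <- quantify_taxa(cohort$counts, cohort$taxonomy)
  perm <- sample(nrow(cohort$counts))
  tabs2 <- quantify_taxa(cohort$counts[perm, ], cohort$taxonomy)
  for (lev in names(tabs)) {
    expect_equal(unclass(tabs[[lev]]), unclass(tabs2[[lev]]))
    expect_true(all(abs(colSums(tabs[[lev]]) - 1) < 1e-9))
  }
  # aggregation consistency: genus fraction equals the sum of its species
  g <- cohort$taxonomy$genus[1]
  sp <- cohort$taxonomy$species_id[cohort$taxonomy$genus == g]
  expect_equal(unname(tabs$L6[g, ]),
               unname(colSums(tabs$L7[sp, , drop = FALSE])))
})

test_that("quantify_taxa validates inputs", {
  tax <- tiny_taxonomy()
  counts <- named_matrix(rep(0, 6), c("spA", "spB", "spC"),
                         c("smp1", "smp2"))
  counts["spA", "smp1"] <- 4
  expect_error(quantify_taxa(counts, tax), "smp2")
  counts2 <- named_matrix(1:2, c("spA", "spX"), "smp1")
  expect_error(quantify_taxa(counts2, tax), "spX")
})

test_that("clade filters implement the three removal rules plus exclusions", {
  md <- tiny_metadata(50, 53)  # 103 samples, cases first
  n <- 103
  mk <- function(idx, level = 0.01) {
    v <- numeric(n); v[idx] <- level; v
  }
  mat <- rbind(
    lowdet = mk(c(1:10, 51:60)),   # 20/103 = 19.4% < 20% -> removed
    okdet  = mk(c(1:11, 51:60)),   # 21/103 = 20.4%, both groups -> kept
    ctrlonly = mk(51:103),         # absent in cases
    rare   = rep(2e-5, n),         # mean 2e-5 > 1e-5, everywhere -> retained
    toorare = rep(5e-6, n),        # mean below 0.001% -> removed
    excluded = rep(0.01, n)
  )
  colnames(mat) <- md$sample_id
  tabs <- list(L7 = abundance_table(mat, "L7", "relative_fraction"))
  res <- filter_clades(tabs, md, exclusion_list = "excluded")
  rep <- res$report
  reason <- setNames(rep$reason, rep$feature_id)
  expect_equal(unname(reason["lowdet"]), "low_detection")
  expect_equal(unname(reason["ctrlonly"]), "absent_in_a_group")
  expect_equal(unname(reason["toorare"]), "low_abundance")
  expect_equal(unname(reason["excluded"]), "exclusion_list")
  expect_setequal(rownames(res$tables$L7), c("okdet", "rare"))
  expect_equal(sum(rep$retained) + sum(!rep$retained), nrow(mat))
})

test_that("gene filter boundary is strict and matches a brute-force recount", {
  md <- tiny_metadata(10, 10)
  set.seed(33)
  n <- 20; m <- 1000
  det_rate <- runif(m, 0.05, 1)
  mat <- matrix(0, m, n, dimnames = list(sprintf("g%04d", 1:m),
                                         md$sample_id))
  for (i in seq_len(m)) {
    k <- rbinom(1, n, det_rate[i])
    if (k > 0) mat[i, sample(n, k)] <- runif(k, 0.1, 2)
  }
  res <- filter_genes(mat, md)
  # independent recount
  keep <- logical(m)
  for (i in seq_len(m)) {
    v <- mat[i, ]
    keep[i] <- (sum(v > 0) / n >= 0.20) &&
      any(v[md$status == 1] > 0) && any(v[md$status == 0] > 0)
  }
  expect_identical(unname(res$report$retained), keep)
  # exact 20% detection is retained (strict "less than" removal)
  v20 <- numeric(n); v20[1:2] <- 1; v20[11:12] <- 1  # 4/20 = 20%
  mat20 <- rbind(mat, exactly20 = v20)
  res20 <- filter_genes(mat20, md)
  expect_true("exactly20" %in% rownames(res20$table))
  # idempotence
  res2 <- filter_genes(res$table, md)
  expect_identical(dim(res2$table), dim(res$table))
})

test_that("PC scores match an eigendecomposition oracle and are orthogonal", {
  set.seed(4)
  mat <- named_matrix(rnorm(60), paste0("f", 1:6), paste0("s", 1:10))
  sc <- compute_pcs(mat, k = 3, scale = FALSE)
  x <- scale(t(mat), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(x))
  oracle <- x %*% eig$vectors[, 1:3]
  for (j in 1:3)
    expect_equal(abs(unname(sc[, j])), abs(unname(oracle[, j])),
                 tolerance = 1e-8)
  expect_lt(abs(stats::cor(sc[, 1], sc[, 2])), 1e-8)
  expect_lt(abs(stats::cor(sc[, 1], sc[, 3])), 1e-8)
  # correlation-basis scores match the eigen oracle on scaled data too
  scs <- compute_pcs(mat, k = 2)
  xs <- scale(t(mat), center = TRUE, scale = TRUE)
  eigs <- eigen(stats::cor(t(mat)))
  oracle_s <- xs %*% eigs$vectors[, 1:2]
  for (j in 1:2)
    expect_equal(abs(unname(scs[, j])), abs(unname(oracle_s[, j])),
                 tolerance = 1e-8)
  expect_error(compute_pcs(mat, k = 11), "rank")
})

test_that("a rank-1 table loads everything on PC1", {
  u <- rnorm(8); v <- abs(rnorm(12)) + 0.5
  mat <- named_matrix(outer(u, v), paste0("f", 1:8), paste0("s", 1:12))
  sc <- compute_pcs(mat, k = 2)
  vexp <- apply(sc, 2, var)
  expect_gt(vexp[1] / sum(vexp), 0.999)
})

test_that("outlier flagging finds a planted extreme sample only", {
  set.seed(5)
  sc <- matrix(rnorm(200), 100, 2,
               dimnames = list(paste0("s", 1:100), c("PC1", "PC2")))
  sc["s7", 1] <- 10 * sd(sc[-7, 1])
  expect_identical(flag_outliers(sc, 4), "s7")
  expect_length(flag_outliers(sc, Inf), 0)
  same <- matrix(1, 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  expect_length(flag_outliers(same), 0)
})
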