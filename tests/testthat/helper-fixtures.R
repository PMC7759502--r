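# Small in-code fixtures shared across test files.

# A tiny two-genus taxonomy with hand-set genome lengths.
tiny_taxonomy <- function() {
  data.frame(species_id = c("spA", "spB", "spC"),
             phylum = c("p1", "p1", "p2"),
             class = c("c1", "c1", "c2"),
             order = c("o1", "o1", "o2"),
             family = c("f1", "f1", "f2"),
             genus = c("g1", "g1", "g2"),
             genome_length = c(1000, 2000, 1500),
             stringsAsFactors = FALSE)
}

tiny_metadata <- function(n_case = 2, n_control = 2) {
  n <- n_case + n_control
  data.frame(sample_id = paste0("smp", seq_len(n)),
             status = rep(c(1L, 0L), c(n_case, n_control)),
             sex = rep_len(c(0L, 1L), n),
             age = seq(30, 60, length.out = n),
             stringsAsFactors = FALSE)
}

# Convenience: matrix with dimnames.
named_matrix <- function(values, features, samples) {
  matrix(values, nrow = length(features), ncol = length(samples),
         dimnames = list(features, samples))
}

# Exact two-sided Fisher P by full enumeration over all tables with the
# observed margins (probability-mass rule), independent of fisher.test.
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
  }
  p_obs <- prob(tab[1, 1])
  sum(vapply(lo:hi, function(a) {
    pa <- prob(a)
    if (pa <= p_obs * (1 + 1e-7)) pa else 0
  }, numeric(1)))
}

# Harrell-Davis oracle: beta-density weights by numeric integration.
hd_integrate <- function(x, q) {
  n <- length(x)
  a <- (n + 1) * q; b <- (n + 1) * (1 - q)
  xs <- sort(x)
  w <- vapply(seq_len(n), function(i)
    stats::integrate(function(u) stats::dbeta(u, a, b),
                     (i - 1) / n, i / n, rel.tol = 1e-12)$value,
    numeric(1))
  sum(w * xs)
}

# Brute-force weighted KS enrichment score on a ranked metric.
es_brute <- function(metric, members) {
  hit <- names(metric) %in% members
  nh <- sum(hit); N <- length(metric)
  run <- 0; best <- 0
  denom <- sum(abs(metric[hit]))
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(metric[i]) / denom else -1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
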