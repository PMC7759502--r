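#' Calibration studies for the permutation threshold framework
#'
#' These drivers generate many independent synthetic cohorts and measure the
#' operating characteristics of the empirical significance threshold and the
#' rank-wise empirical FDR procedure under the generator's stated model.
#' They are the package's reproducibility harness: the acceptance script and
#' the test suite both call them.
#'
#' @name calibration
NULL

# One cohort -> observed scan + permutation null. Returns the observed
# sorted -log10 P vector, the null object, and the retained feature ids.
calibration_rep <- function(n_case, n_control, n_features, B,
                            spike = NULL, zero_inflation = 0.2,
                            depth = 1e6, seed = 1L) {
  spec <- cohort_spec(n_case = n_case, n_control = n_control,
                      n_species = n_features,
                      zero_inflation = zero_inflation, depth = depth,
                      spike_list = spike, seed = seed)
  cohort <- generate_cohort(spec)
  l7 <- quantify_taxa(cohort$counts, cohort$taxonomy)$L7
  bx <- suppressWarnings(boxcox_table(l7))
  obs <- scan_neglogp(bx$table, cohort$metadata,
                      covariates = c("sex", "age"))
  null <- permute_null(bx$table, cohort$metadata,
                       covariates = c("sex", "age"), B = B,
                       seed = (seed + 7L) %% 2147483647L)
  list(observed = obs, null = null, features = rownames(bx$table))
}

rep_seed <- function(seed, i) (as.integer(seed) + i * 7919L) %% 2147483647L

#' Type-I-error calibration of the empirical significance threshold
#'
#' Simulates `n_rep` independent null cohorts (no spiked effects), computes
#' each cohort's own empirical Bonferroni threshold `-log10(P_sig)` as the
#' Harrell-Davis `1 - alpha` quantile of its B-permutation minimum-P null,
#' and records whether the cohort's observed minimum-P statistic exceeds it.
#' Under the permutation null the rejection fraction converges to `alpha`.
#'
#' @param n_rep number of simulated cohorts.
#' @param n_case,n_control group sizes per cohort.
#' @param n_features species-level features per cohort.
#' @param B permutations per cohort.
#' @param alpha nominal level of the threshold (default 0.05).
#' @param seed integer root seed (per-cohort seeds are derived from it).
#' @return list with `rejection_rate`, `rejections` (logical vector),
#'   `n_rep`, `alpha`.
#' @export
simulate_threshold_calibration <- function(n_rep = 500, n_case = 25,
                                           n_control = 25, n_features = 100,
                                           B = 1000, alpha = 0.05,
                                           seed = 1L) {
  rejections <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    r <- calibration_rep(n_case, n_control, n_features, B,
                         seed = rep_seed(seed, i))
    p_sig <- empirical_bonferroni(r$null, alpha = alpha, n_boot = 0)$p_sig
    rejections[i] <- max(r$observed) > p_sig
  }
  list(rejection_rate = mean(rejections), rejections = rejections,
       n_rep = n_rep, alpha = alpha)
}

#' Realized-FDR calibration of the rank-wise empirical FDR procedure
#'
#' Simulates `n_rep` cohorts in which `n_spiked` of `n_features` features
#' carry a planted log-scale case-control effect `delta`, runs the
#' association scan and [empirical_fdr()] with per-rank Harrell-Davis
#' thresholds from B permutations, and returns the per-cohort realized FDR
#' (false calls / max(1, calls)) together with spike-recovery bookkeeping.
#'
#' @inheritParams simulate_threshold_calibration
#' @param n_spiked number of spiked features per cohort.
#' @param delta log-scale effect of each spike.
#' @param level FDR level of the calls (default 0.1).
#' @return list with `mean_fdr`, `fdr` (per cohort), `mc_se` (Monte-Carlo
#'   standard error of the mean), `power` (mean fraction of spiked features
#'   called), `spike_top_and_called` (per cohort: did a spiked feature
#'   attain the scan minimum P *and* get called), `n_rep`, `level`.
#' @export
simulate_fdr_calibration <- function(n_rep = 200, n_case = 100,
                                     n_control = 100, n_features = 100,
                                     n_spiked = 5, delta = 2, B = 1000,
                                     level = 0.1, seed = 1L) {
  fdr <- numeric(n_rep); power <- numeric(n_rep)
  top_called <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    s <- rep_seed(seed, i)
    set.seed(s)
    spiked_ids <- sample(species_ids(n_features), n_spiked)
    spike <- data.frame(feature_id = spiked_ids, delta = delta)
    r <- calibration_rep(n_case, n_control, n_features, B, spike = spike,
                         seed = s)
    calls <- empirical_fdr(r$observed, r$null, level = level)
    called <- calls$significant_ids
    false_calls <- setdiff(called, spiked_ids)
    fdr[i] <- length(false_calls) / max(1L, length(called))
    power[i] <- length(intersect(called, spiked_ids)) / n_spiked
    top <- names(r$observed)[1]
    top_called[i] <- (top %in% spiked_ids) && (top %in% called)
  }
  list(mean_fdr = mean(fdr), fdr = fdr,
       mc_se = sd(fdr) / sqrt(n_rep),
       power = mean(power), spike_top_and_called = top_called,
       n_rep = n_rep, level = level)
}
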