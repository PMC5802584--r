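#' Type-I-error calibration of the correlation-network procedure
#'
#' Simulates the whole per-pair comparison under the null: both groups are
#' drawn from the *control* configuration (same means, SDs and baseline
#' correlation; coupling overrides stripped), so every between-group
#' correlation difference is pure sampling noise. For each of `K` simulated
#' cohorts the per-group correlation matrices, the per-pair one-tailed tests
#' at `alpha` and the global Welch statistic are computed; the report
#' aggregates the per-pair flag rate (with the exact binomial 99% interval
#' for the flag count at the nominal `alpha`) and the empirical distribution
#' of the global t statistic. Identical `(config, K, alpha, seed)` give
#' identical reports.
#'
#' @param config A `cohort_config` (its control arm defines the null).
#' @param K Number of simulated null cohorts (>= 1).
#' @param alpha Per-pair one-tailed flagging threshold (default 0.001).
#' @param seed Integer seed.
#' @param tail Direction passed to [compare_all_pairs()] (default
#'   `"patients_greater"`).
#' @return A `null_sim_report`: list with `K`, `n_regions`, `n_pairs`,
#'   `n_tests`, `n_flagged`, `flag_rate`, `alpha`, `count_ci99` (exact
#'   binomial 99% interval for the flag count at nominal `alpha`),
#'   `calibrated` (count inside that interval), `global_t` (mean, sd,
#'   quantiles) and `seed`.
#' @export
simulate_null <- function(config, K, alpha = 0.001, seed = NULL,
                          tail = "patients_greater") {
  if (K < 1L) stop_("K must be >= 1")
  if (alpha <= 0 || alpha > 1) stop_("alpha must be in (0, 1]")
  null_cfg <- null_config(config)
  with_seed(seed, {
    n_pairs <- nrow(unique_pairs(null_cfg$regions))
    flags <- integer(K)
    gt <- numeric(K)
    for (k in seq_len(K)) {
      coh <- generate_cohort(null_cfg, seed = NULL, clinical = FALSE)
      m_ctl <- corr_matrix(coh, "control")
      m_pat <- corr_matrix(coh, "patient")
      pc <- compare_all_pairs(m_ctl, m_pat, alpha = alpha, tail = tail)
      flags[k] <- sum(pc$flagged)
      gt[k] <- global_comparison(m_ctl, m_pat)$t
    }
    n_tests <- K * n_pairs
    n_flagged <- sum(flags)
    ci <- stats::qbinom(c(0.005, 0.995), n_tests, alpha)
    structure(list(
      K = K, n_regions = length(null_cfg$regions$names), n_pairs = n_pairs,
      n_tests = n_tests, n_flagged = n_flagged,
      flag_rate = n_flagged / n_tests, alpha = alpha,
      count_ci99 = ci, calibrated = n_flagged >= ci[1] && n_flagged <= ci[2],
      global_t = list(mean = mean(gt), sd = if (K > 1) stats::sd(gt) else NA_real_,
                      quantiles = stats::quantile(gt, c(0.025, 0.5, 0.975),
                                                  names = TRUE)),
      tail = tail, seed = seed
    ), class = "null_sim_report")
  })
}

# both groups <- control arm; couplings stripped
null_config <- function(config) {
  validate_config(config)
  cfg <- config
  cfg$region_params$mean_patient <- cfg$region_params$mean_control
  cfg$region_params$sd_patient <- cfg$region_params$sd_control
  cfg$couplings <- cfg$couplings[0L, , drop = FALSE]
  cfg
}

#' @export
print.null_sim_report <- function(x, ...) {
  cat("<null_sim_report> K = ", x$K, " null cohorts, ", x$n_regions,
      " regions (", x$n_pairs, " pairs)\n", sep = "")
  cat(sprintf("  flag rate at alpha = %g: %.5f (%d / %d tests)\n",
              x$alpha, x$flag_rate, x$n_flagged, x$n_tests))
  cat(sprintf("  exact binomial 99%% count interval: [%d, %d] -> %s\n",
              x$count_ci99[1], x$count_ci99[2],
              if (x$calibrated) "calibrated" else "NOT calibrated"))
  cat(sprintf("  global t: mean %.3f, sd %.3f\n", x$global_t$mean,
              x$global_t$sd))
  invisible(x)
}

#' Permutation test for the global correlation comparison
#'
#' Nonparametric alternative to the parametric global Welch test: group
#' labels are re-assigned uniformly at random `B` times (preserving group
#' sizes), the global statistic is recomputed for each relabelling, and the
#' two-sided permutation p-value is `(1 + #{|t_b| >= |t_obs|}) / (B + 1)`
#' (add-one estimator, so p is never 0).
#'
#' @param cohort A `cohort_table` with both groups present (each n >= 4).
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param transform Passed to [global_comparison()].
#' @return List with `t_obs`, `p`, `B`, and the permuted statistics `t_perm`.
#' @export
permutation_global <- function(cohort, B = 1000L, seed = NULL,
                               transform = "fisher_z") {
  if (B < 100L) stop_("B must be >= 100")
  n_pat <- sum(cohort$group == "patient")
  n_ctl <- sum(cohort$group == "control")
  if (n_pat < 4L || n_ctl < 4L) stop_("both groups need >= 4 subjects")
  stat_for <- function(coh) {
    global_comparison(corr_matrix(coh, "control"), corr_matrix(coh, "patient"),
                      transform = transform)$t
  }
  t_obs <- stat_for(cohort)
  with_seed(seed, {
    n <- nrow(cohort)
    t_perm <- numeric(B)
    for (b in seq_len(B)) {
      coh_b <- cohort
      pat_idx <- sample.int(n, n_pat)
      coh_b$group <- factor(ifelse(seq_len(n) %in% pat_idx, "patient", "control"),
                            levels = c("control", "patient"))
      t_perm[b] <- stat_for(coh_b)
    }
    list(t_obs = t_obs, p = (1 + sum(abs(t_perm) >= abs(t_obs))) / (B + 1),
         B = B, t_perm = t_perm)
  })
}
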