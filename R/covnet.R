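#' Per-group inter-regional Pearson correlation matrix
#'
#' The receptor covariance network of one group: Pearson correlations of
#' regional DVR values across the group's subjects, for every pair of
#' analysis regions.
#'
#' @param cohort A `cohort_table`.
#' @param group Group label (`"patient"` or `"control"`).
#' @return A `corr_matrix`: list with `group`, `regions` (ordered labels),
#'   `r` (symmetric matrix, unit diagonal) and `n` (subjects contributing).
#' @export
corr_matrix <- function(cohort, group) {
  rs <- attr(cohort, "regions")
  if (is.null(rs)) stop_("cohort has no region-set attribute")
  x <- cohort_dvr(cohort, group)
  if (nrow(x) < 4L)
    stop_("need >= 4 subjects in group '", group, "' (n - 3 must be positive)")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop_("zero-variance region(s) in group '", group, "': ",
          paste(colnames(x)[sds == 0], collapse = ", "))
  structure(list(group = group, regions = rs$names,
                 r = stats::cor(x), n = nrow(x)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("<corr_matrix> group '", x$group, "', ", length(x$regions),
      " regions, n = ", x$n, "\n", sep = "")
  cat("  mean off-diagonal r = ",
      signif(mean(x$r[upper.tri(x$r)]), 4), "\n", sep = "")
  invisible(x)
}

#' Fisher's r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform under which a sample correlation from n subjects has approximate
#' variance 1/(n - 3). Correlations of exactly +/-1 (degenerate inputs such
#' as duplicated regions) are clamped to +/-(1 - 1e-12) with a warning.
#'
#' @param r Numeric vector of correlations, |r| <= 1.
#' @return `atanh(r)` with clamping at the boundary.
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3)
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop_("|r| must be <= 1")
  if (any(abs(r) == 1, na.rm = TRUE)) {
    warning("correlation(s) of exactly +/-1 clamped to +/-(1 - 1e-12)",
            call. = FALSE)
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  atanh(r)
}

#' Fisher z test for two independent correlations
#'
#' Compares a correlation observed in two independent groups:
#' `stat = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))` with `zi = atanh(ri)`,
#' referred to the standard normal. `tail = "greater"`/`"less"` test the
#' alternatives that the first correlation is the larger/smaller one.
#'
#' @param r1,r2 Correlations in group 1 and group 2.
#' @param n1,n2 Group sizes (each > 3).
#' @param tail `"two_sided"` (default), `"greater"` or `"less"` (with respect
#'   to the first group's correlation).
#' @return List with `stat` (normal deviate) and `p`.
#' @export
#' @examples
#' pair_z_test(0.3, 14, 0.9, 14)$stat  # about -2.73
pair_z_test <- function(r1, n1, r2, n2,
                        tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (n1 <= 3 || n2 <= 3) stop_("both group sizes must exceed 3")
  stat <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(tail,
    two_sided = 2 * stats::pnorm(-abs(stat)),
    greater = stats::pnorm(stat, lower.tail = FALSE),
    less = stats::pnorm(stat)
  )
  list(stat = stat, p = p)
}

#' Per-pair comparison of two correlation matrices
#'
#' Applies [pair_z_test()] to every unique region pair of the two group
#' matrices (630 pairs for 36 regions) and flags pairs at `p < alpha`. The
#' default one-tailed direction is the alternative that patients have the
#' larger correlation; no multiplicity correction is applied by default
#' (set `adjust = TRUE` for a Benjamini–Hochberg column). The test statistic
#' is reported as `(z_ctl - z_pat) / SE`, so strong patient-specific
#' couplings appear as large negative deviates.
#'
#' @param m_ctl,m_pat `corr_matrix` objects for controls and patients, with
#'   identical region order.
#' @param alpha Flagging threshold (default 0.001).
#' @param tail `"patients_greater"` (default), `"controls_greater"` or
#'   `"two_sided"`.
#' @param adjust Add a `p_bh` column (default `FALSE`).
#' @return Data frame (`pair_comparison_table`) with one row per unique pair:
#'   `region_a`, `region_b`, `r_ctl`, `r_pat`, `z_ctl`, `z_pat`, `stat`,
#'   `p_one_tailed` (named `p` for `tail = "two_sided"`), `flagged`. The
#'   direction is recorded in attribute `"tail"`.
#' @export
compare_all_pairs <- function(m_ctl, m_pat, alpha = 0.001,
                              tail = c("patients_greater", "controls_greater",
                                       "two_sided"),
                              adjust = FALSE) {
  tail <- match.arg(tail)
  check_matching_matrices(m_ctl, m_pat)
  pairs <- unique_pairs(m_ctl$regions)
  ia <- match(pairs$region_a, m_ctl$regions)
  ib <- match(pairs$region_b, m_ctl$regions)
  idx <- cbind(ia, ib)
  r_ctl <- m_ctl$r[idx]
  r_pat <- m_pat$r[idx]
  zt <- pair_z_test(r_ctl, m_ctl$n, r_pat, m_pat$n,
                    tail = switch(tail, patients_greater = "less",
                                  controls_greater = "greater",
                                  two_sided = "two_sided"))
  out <- data.frame(pairs,
                    r_ctl = r_ctl, r_pat = r_pat,
                    z_ctl = fisher_z(r_ctl), z_pat = fisher_z(r_pat),
                    stat = zt$stat, p_one_tailed = zt$p,
                    flagged = zt$p < alpha,
                    stringsAsFactors = FALSE)
  p_col <- "p_one_tailed"
  if (tail == "two_sided") {
    names(out)[names(out) == "p_one_tailed"] <- "p"
    p_col <- "p"
  }
  if (adjust) out$p_bh <- stats::p.adjust(out[[p_col]], "BH")
  attr(out, "tail") <- tail
  attr(out, "alpha") <- alpha
  class(out) <- c("pair_comparison_table", "data.frame")
  out
}

check_matching_matrices <- function(m_ctl, m_pat) {
  if (!inherits(m_ctl, "corr_matrix") || !inherits(m_pat, "corr_matrix"))
    stop_("inputs must be corr_matrix objects")
  if (!identical(m_ctl$regions, m_pat$regions))
    stop_("region order mismatch between the two correlation matrices")
  invisible(TRUE)
}

#' Global comparison of the two correlation sets
#'
#' The global arm of the three-step procedure: the unique off-diagonal
#' correlations of each group (630 values for 36 regions) are pooled per
#' group — Fisher z-transformed by default, raw as a sensitivity arm — and
#' compared with Welch's t test, controls minus patients, two-sided. A
#' negative t therefore means globally higher inter-regional correlations in
#' patients. The Welch df is bounded above by 2 * R(R-1)/2 - 2 (1258 for 36
#' regions). Note the 630 values per group are mutually dependent (they share
#' subjects), which the test ignores; [simulate_null()] quantifies the actual
#' operating characteristics.
#'
#' @inheritParams compare_all_pairs
#' @param transform `"fisher_z"` (default) or `"raw_r"`.
#' @return A `global_comparison`: list with `t`, `df`, `p` (two-sided),
#'   `transform`, and per-group `mean`/`sd`/`n_pairs`.
#' @export
global_comparison <- function(m_ctl, m_pat,
                              transform = c("fisher_z", "raw_r")) {
  transform <- match.arg(transform)
  check_matching_matrices(m_ctl, m_pat)
  v_ctl <- m_ctl$r[upper.tri(m_ctl$r)]
  v_pat <- m_pat$r[upper.tri(m_pat$r)]
  if (length(v_ctl) < 2L) stop_("need at least 2 region pairs")
  if (transform == "fisher_z") {
    v_ctl <- fisher_z(v_ctl)
    v_pat <- fisher_z(v_pat)
  }
  w <- welch_test(v_ctl, v_pat)
  structure(list(t = w$t, df = w$df, p = w$p, transform = transform,
                 controls = list(mean = mean(v_ctl), sd = stats::sd(v_ctl)),
                 patients = list(mean = mean(v_pat), sd = stats::sd(v_pat)),
                 n_pairs = length(v_ctl)),
            class = "global_comparison")
}

#' @export
print.global_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Global correlation comparison (%s, controls - patients):\n  t = %.*g, df = %.*g, p = %.*g over %d pairs/group\n",
    x$transform, digits, x$t, digits, x$df, digits, x$p, x$n_pairs))
  invisible(x)
}

#' Correlation difference map
#'
#' Entrywise `r_controls - r_patients`: positive entries mean the pair is
#' more strongly coupled in controls, negative entries more strongly coupled
#' in patients (the convention used for the diverging heatmap, red for
#' controls > patients).
#'
#' @inheritParams compare_all_pairs
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
difference_map <- function(m_ctl, m_pat) {
  check_matching_matrices(m_ctl, m_pat)
  d <- m_ctl$r - m_pat$r
  dimnames(d) <- list(m_ctl$regions, m_ctl$regions)
  d
}

#' Write a region-by-region matrix as TSV
#'
#' @param m Square matrix with region dimnames.
#' @param path Output TSV path.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(region = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(format_num_df(d), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
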