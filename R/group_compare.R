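#' Per-region group comparison by general linear model
#'
#' Fits `DVR ~ group + covariates` by least squares and tests the group
#' factor by partial F (full model vs the model with group dropped):
#' `F = (SS_group / 1) / (SS_resid / df_den)`, with SPSS-style partial
#' eta-squared `SS_group / (SS_group + SS_resid)`. With no covariates this is
#' the one-way ANOVA, whose F equals the square of the pooled-variance t
#' statistic.
#'
#' @param cohort A `cohort_table`.
#' @param region Region label (a DVR column of `cohort`).
#' @param covariates Character vector of clinical column names (default none).
#' @return A `region_comparison`: list with `region`, `f`, `df_num`, `df_den`,
#'   `p`, `partial_eta_sq`, `adjusted`, and per-group `mean`/`sd`/`n`.
#' @export
#' @examples
#' coh <- generate_cohort(make_default_config(), seed = 1)
#' ancova_region(coh, "amygdala", covariates = c("BDI", "BAI"))
ancova_region <- function(cohort, region, covariates = character()) {
  if (!region %in% names(cohort)) stop_("unknown region: ", region)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop_("missing covariate column(s): ",
                          paste(miss, collapse = ", "))
  d <- data.frame(.y = cohort[[region]], .group = cohort$group,
                  cohort[, covariates, drop = FALSE], check.names = FALSE)
  if (anyNA(d)) stop_("covariates/DVR must be complete for all subjects")
  if (nrow(d) < length(covariates) + 3L)
    stop_("too few subjects for the requested model")
  rhs_cov <- if (length(covariates))
    paste(sprintf("`%s`", covariates), collapse = " + ") else NULL
  f_full <- stats::as.formula(paste(c(".y ~ .group", rhs_cov), collapse = " + "))
  f_red <- stats::as.formula(paste(c(".y ~ 1", rhs_cov), collapse = " + "))
  fit <- stats::lm(f_full, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_("rank-deficient design; collinear term(s): ",
          paste(bad, collapse = ", "))
  }
  red <- stats::lm(f_red, data = d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_grp <- sum(stats::residuals(red)^2) - ss_res
  df_den <- stats::df.residual(fit)
  f <- (ss_grp / 1) / (ss_res / df_den)
  p <- stats::pf(f, 1, df_den, lower.tail = FALSE)
  grp_stats <- function(g) {
    v <- d$.y[d$.group == g]
    list(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  structure(list(region = region, f = f, df_num = 1L, df_den = df_den, p = p,
                 partial_eta_sq = ss_grp / (ss_grp + ss_res),
                 adjusted = length(covariates) > 0L,
                 patient = grp_stats("patient"), control = grp_stats("control")),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("%s: F(%d, %d) = %.*g, p = %.*g, partial eta^2 = %.*g%s\n",
              x$region, x$df_num, x$df_den, digits, x$f, digits, x$p,
              digits, x$partial_eta_sq,
              if (x$adjusted) " (covariate-adjusted)" else ""))
  invisible(x)
}

#' Compare all regions between groups
#'
#' Runs [ancova_region()] for every region of the cohort's region set, in
#' region-set order, and reports both arms side by side: the
#' covariate-adjusted model and the unadjusted one-way ANOVA (identical when
#' `covariates` is empty). P-values are uncorrected by default; set
#' `adjust = TRUE` for additional Benjamini–Hochberg and Bonferroni columns
#' over the unadjusted p-values.
#'
#' @inheritParams ancova_region
#' @param adjust Add `p_bh` and `p_bonf` columns (default `FALSE`).
#' @return Data frame with one row per region: group summary statistics,
#'   `F_adj`, `df_adj`, `p_adj`, `partial_eta_sq_adj`, `F_unadj`, `df_unadj`,
#'   `p_unadj`, `partial_eta_sq` (unadjusted arm), and optionally `p_bh`,
#'   `p_bonf`.
#' @export
compare_all_regions <- function(cohort, covariates = character(),
                                adjust = FALSE) {
  rs <- attr(cohort, "regions")
  if (is.null(rs)) stop_("cohort has no region-set attribute")
  rows <- lapply(rs$names, function(r) {
    adj <- ancova_region(cohort, r, covariates)
    una <- if (length(covariates)) ancova_region(cohort, r, character()) else adj
    data.frame(region = r,
               n_pat = adj$patient$n, n_ctl = adj$control$n,
               mean_pat = adj$patient$mean, sd_pat = adj$patient$sd,
               mean_ctl = adj$control$mean, sd_ctl = adj$control$sd,
               F_adj = adj$f, df_adj = adj$df_den, p_adj = adj$p,
               partial_eta_sq_adj = adj$partial_eta_sq,
               F_unadj = una$f, df_unadj = una$df_den, p_unadj = una$p,
               partial_eta_sq = una$partial_eta_sq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$p_bh <- stats::p.adjust(out$p_unadj, "BH")
    out$p_bonf <- stats::p.adjust(out$p_unadj, "bonferroni")
  }
  out
}

#' Multivariate analysis of covariance over all regions
#'
#' Front-end to the multivariate general linear model with every regional DVR
#' as a dependent variable, group as the factor of interest (entered after
#' the covariates) and optional clinical covariates. Returns Wilks' Lambda
#' and Pillai's trace with their F approximations for the group term. The
#' design is singular whenever the residual degrees of freedom do not exceed
#' the number of regions — with 36 regions and 28 subjects this is the
#' expected outcome, and an explicit error recommends dimension reduction.
#' With a single region the statistics collapse to the univariate F.
#'
#' @inheritParams ancova_region
#' @return List with one element per test (`wilks`, `pillai`), each holding
#'   `statistic`, `f`, `df_num`, `df_den`, `p`.
#' @export
mancova <- function(cohort, covariates = character()) {
  rs <- attr(cohort, "regions")
  if (is.null(rs)) stop_("cohort has no region-set attribute")
  nm <- rs$names
  n <- nrow(cohort)
  df_resid <- n - length(covariates) - 2L  # intercept + group + covariates
  if (df_resid <= length(nm))
    stop_("singular multivariate design: ", length(nm),
          " dependent variables but only ", df_resid,
          " residual degrees of freedom; reduce the number of regions or ",
          "use per-region comparisons")
  if (length(nm) == 1L) {
    u <- ancova_region(cohort, nm, covariates)
    one <- list(statistic = NA_real_, f = u$f, df_num = u$df_num,
                df_den = u$df_den, p = u$p)
    return(list(wilks = one, pillai = one))
  }
  d <- data.frame(.group = cohort$group,
                  cohort[, covariates, drop = FALSE], check.names = FALSE)
  y <- as.matrix(cohort[, nm, drop = FALSE])
  rhs <- paste(c(sprintf("`%s`", covariates), ".group"), collapse = " + ")
  fit <- stats::manova(stats::as.formula(paste("y ~", rhs)), data = d)
  pick <- function(test) {
    s <- summary(fit, test = test)$stats
    row <- s[".group", ]
    list(statistic = unname(row[test]), f = unname(row["approx F"]),
         df_num = unname(row["num Df"]), df_den = unname(row["den Df"]),
         p = unname(row["Pr(>F)"]))
  }
  list(wilks = pick("Wilks"), pillai = pick("Pillai"))
}

#' Shapiro–Wilk normality screen per (group, region)
#'
#' Explorative per-cell normality check of the DVR values, flagging cells at
#' p < `alpha` (uncorrected). Cells with fewer than 3 subjects or zero
#' variance are marked indeterminate.
#'
#' @param cohort A `cohort_table`.
#' @param alpha Flagging threshold (default 0.05).
#' @return Data frame with `group`, `region`, `W`, `p`, `flagged`,
#'   `indeterminate`.
#' @export
normality_screen <- function(cohort, alpha = 0.05) {
  rs <- attr(cohort, "regions")
  if (is.null(rs)) stop_("cohort has no region-set attribute")
  grid <- expand.grid(group = c("patient", "control"), region = rs$names,
                      stringsAsFactors = FALSE)
  res <- mapply(function(g, r) {
    v <- cohort[[r]][cohort$group == g]
    if (length(v) < 3L || stats::sd(v) == 0)
      return(c(W = NA_real_, p = NA_real_, ind = 1))
    s <- stats::shapiro.test(v)
    c(W = unname(s$statistic), p = s$p.value, ind = 0)
  }, grid$group, grid$region)
  out <- data.frame(grid, W = res["W", ], p = res["p", ],
                    indeterminate = res["ind", ] == 1,
                    stringsAsFactors = FALSE)
  out$flagged <- !out$indeterminate & out$p < alpha
  rownames(out) <- NULL
  out[, c("group", "region", "W", "p", "flagged", "indeterminate")]
}
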