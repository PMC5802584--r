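#' Generate a synthetic two-group cohort
#'
#' Draws each group's regional DVR vectors from a multivariate normal with the
#' configured means, SDs and correlation structure (baseline correlation plus
#' coupling overrides, completed to a positive-semidefinite correlation matrix
#' that honours the coupling targets exactly). Subject vectors containing a
#' non-positive DVR are rejected and redrawn with a warning, so the DVR > 0
#' invariant holds while the configured moments are preserved at realistic
#' SDs. Clinical variables are generated as floor-truncated normals with the
#' configured group moments; the AASE craving subscores are tied to the
#' configured region's DVR at the configured (negative) target correlation in
#' patients; antidepressant use is assigned with probability decreasing in
#' that region's DVR, imipramine-equivalent doses are drawn for medicated
#' patients, and relapse probability increases with the imipramine dose.
#'
#' Identical `(config, seed)` pairs give identical cohorts.
#'
#' @param config A `cohort_config`, e.g. [make_default_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param clinical Generate clinical variables as well as DVRs (default
#'   `TRUE`); `FALSE` is useful for pure correlation-structure simulations.
#' @return A `cohort_table`: a data frame with `subject_id`, `group` (factor,
#'   levels control/patient), one numeric DVR column per region, and (when
#'   `clinical = TRUE`) `BDI`, `BAI`, `AUDIT`, `AASE_item_1..20`,
#'   `drinks_per_week`, `antidepressant`, `imipramine_eq`, `relapse`. The
#'   region set is attached as attribute `"regions"`.
#' @export
#' @examples
#' coh <- generate_cohort(make_default_config(), seed = 1)
#' table(coh$group)
#' mean(coh$amygdala[coh$group == "patient"])
generate_cohort <- function(config, seed = config$seed, clinical = TRUE) {
  validate_config(config)
  with_seed(seed, {
    nm <- config$regions$names
    rp <- config$region_params[match(nm, config$region_params$region), ]
    groups <- list(
      patient = list(n = config$n_patients, mean = rp$mean_patient,
                     sd = rp$sd_patient),
      control = list(n = config$n_controls, mean = rp$mean_control,
                     sd = rp$sd_control)
    )
    draws <- lapply(names(groups), function(g) {
      gp <- groups[[g]]
      corr <- group_corr_matrix(config, g)
      sigma <- corr * tcrossprod(gp$sd)
      x <- draw_positive_mvn(gp$n, gp$mean, sigma, group = g)
      colnames(x) <- nm
      x
    })
    names(draws) <- names(groups)

    id <- c(sprintf("P%02d", seq_len(config$n_patients)),
            sprintf("C%02d", seq_len(config$n_controls)))
    group <- factor(rep(c("patient", "control"),
                        c(config$n_patients, config$n_controls)),
                    levels = c("control", "patient"))
    dvr <- rbind(draws$patient, draws$control)
    out <- data.frame(subject_id = id, group = group, dvr,
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (clinical) out <- cbind(out, generate_clinical(config, out))
    rownames(out) <- NULL
    structure(out, regions = config$regions, class = c("cohort_table", "data.frame"))
  })
}

# mvrnorm with reject-and-redraw of rows containing non-positive values
draw_positive_mvn <- function(n, mu, sigma, group, max_rounds = 100L) {
  x <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  if (n == 1L) x <- matrix(x, nrow = 1L)
  bad <- which(apply(x, 1L, function(r) any(r <= 0)))
  rounds <- 0L
  while (length(bad)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop_("could not draw positive DVR vectors for group '", group,
            "'; configured means/SDs place too much mass below zero")
    warning(sprintf("redrawing %d %s subject vector(s) with non-positive DVR",
                    length(bad), group), call. = FALSE)
    y <- MASS::mvrnorm(length(bad), mu = mu, Sigma = sigma)
    if (length(bad) == 1L) y <- matrix(y, nrow = 1L)
    x[bad, ] <- y
    bad <- which(apply(x, 1L, function(r) any(r <= 0)))
  }
  x
}

# clinical layer; assumes `out` has DVR columns and group factor
generate_clinical <- function(config, out) {
  cp <- config$clinical_params
  ap <- config$assoc_params
  n <- nrow(out)
  pat <- out$group == "patient"

  draw_score <- function(spec) {
    v <- numeric(n)
    for (g in c("patient", "control")) {
      i <- if (g == "patient") pat else !pat
      if (!any(i)) next
      v[i] <- rtruncnorm_lower(sum(i), spec[[g]][["mean"]], spec[[g]][["sd"]],
                               spec$floor %||% -Inf)
    }
    v
  }
  cl <- data.frame(
    BDI = draw_score(cp$BDI), BAI = draw_score(cp$BAI),
    AUDIT = draw_score(cp$AUDIT),
    drinks_per_week = draw_score(cp$drinks_per_week)
  )

  aase <- generate_aase(config, out, pat)
  cl <- cbind(cl[, c("BDI", "BAI", "AUDIT")], aase,
              drinks_per_week = cl$drinks_per_week)

  # medication / imipramine / relapse (patients only)
  region <- ap$craving_region
  zr <- rep(0, n)
  if (region %in% names(out)) {
    rp <- config$region_params
    k <- match(region, rp$region)
    zr[pat] <- (out[[region]][pat] - rp$mean_patient[k]) / rp$sd_patient[k]
  }
  p_med <- plogis(qlogis(ap$antidepressant_rate) +
                    ap$antidepressant_dvr_logodds * zr)
  med <- pat & (runif(n) < p_med)
  imi <- numeric(n)
  if (any(med))
    imi[med] <- rtruncnorm_lower(sum(med), ap$imipramine_mean,
                                 ap$imipramine_sd, ap$imipramine_floor %||% 0)
  z_imi <- rep(0, n)
  if (any(med)) z_imi[med] <- (imi[med] - ap$imipramine_mean) / ap$imipramine_sd
  p_rel <- plogis(qlogis(ap$relapse_rate) + ap$relapse_imipramine_logodds * z_imi)
  relapse <- rep(NA, n)
  relapse[pat] <- runif(sum(pat)) < p_rel[pat]

  cl$antidepressant <- med
  cl$imipramine_eq <- imi
  cl$relapse <- relapse
  cl
}

# 20 AASE temptation items on the configured scale; in patients the reward
# {4,8,15,17,20} and relief {3,6,12,16,18} subscores are generated from
# latent Gaussians correlated with the craving region's standardised DVR at
# the configured target r.
generate_aase <- function(config, out, pat) {
  cp <- config$clinical_params$aase
  ap <- config$assoc_params
  n <- nrow(out)
  lo <- cp$scale[1]; hi <- cp$scale[2]
  items <- matrix(NA_real_, n, 20L,
                  dimnames = list(NULL, paste0("AASE_item_", 1:20)))
  reward_idx <- c(4L, 8L, 15L, 17L, 20L)
  relief_idx <- c(3L, 6L, 12L, 16L, 18L)

  for (g in c("patient", "control")) {
    i <- if (g == "patient") pat else !pat
    if (!any(i)) next
    m <- cp$item_mean[[g]]; s <- cp$item_sd[[g]]
    items[i, ] <- pmin(hi, pmax(lo, matrix(rnorm(sum(i) * 20L, m, s), sum(i))))
  }

  region <- ap$craving_region
  if (any(pat) && region %in% names(out)) {
    rp <- config$region_params
    k <- match(region, rp$region)
    z <- (out[[region]][pat] - rp$mean_patient[k]) / rp$sd_patient[k]
    mu_sub <- 5 * cp$item_mean[["patient"]]
    for (sub in list(list(idx = reward_idx, r = ap$reward_craving_r),
                     list(idx = relief_idx, r = ap$relief_craving_r))) {
      if (is.null(sub$r) || is.na(sub$r)) next
      lat <- sub$r * z + sqrt(1 - sub$r^2) * rnorm(sum(pat))
      score <- mu_sub + cp$subscore_sd * lat
      base <- score / 5
      d <- matrix(rnorm(sum(pat) * 5L, 0, cp$item_noise_sd), sum(pat))
      d <- d - rowMeans(d)                      # items sum exactly to score
      items[pat, sub$idx] <- pmin(hi, pmax(lo, base + d))
    }
  }
  as.data.frame(items)
}

#' @export
print.cohort_table <- function(x, ...) {
  rs <- attr(x, "regions")
  cat("<cohort_table> ", nrow(x), " subjects (",
      sum(x$group == "patient"), " patients, ",
      sum(x$group == "control"), " controls), ",
      length(rs$names), " regions\n", sep = "")
  invisible(x)
}

#' Extract a cohort's DVR matrix
#'
#' @param cohort A `cohort_table`.
#' @param group Optional group label to restrict to (`"patient"` or
#'   `"control"`).
#' @return Numeric matrix, subjects x regions, in region-set order.
#' @export
cohort_dvr <- function(cohort, group = NULL) {
  rs <- attr(cohort, "regions")
  if (is.null(rs)) stop_("cohort has no region-set attribute")
  if (!is.null(group)) cohort <- cohort[cohort$group == group, , drop = FALSE]
  m <- as.matrix(cohort[, rs$names, drop = FALSE])
  rownames(m) <- cohort$subject_id
  m
}

#' Read and write cohort CSV files
#'
#' The cohort CSV dialect has the header
#' `subject_id,group,<region_1>,...,<region_R>,BDI,BAI,AUDIT,
#' AASE_item_1..AASE_item_20,drinks_per_week,imipramine_eq,relapse`;
#' clinical columns are optional and written empty when absent. Identical
#' cohorts serialise to byte-identical files.
#'
#' @param cohort A `cohort_table`.
#' @param path CSV file path.
#' @param regions Region set; for `read_cohort()`, `NULL` infers the region
#'   columns as everything between `group` and the first clinical column.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  rs <- attr(cohort, "regions")
  clin <- c("BDI", "BAI", "AUDIT", paste0("AASE_item_", 1:20),
            "drinks_per_week", "imipramine_eq", "relapse")
  out <- cohort[, c("subject_id", "group", rs$names), drop = FALSE]
  for (cc in clin) out[[cc]] <- if (cc %in% names(cohort)) cohort[[cc]] else NA
  out$relapse <- ifelse(is.na(out$relapse), "", ifelse(out$relapse, "TRUE", "FALSE"))
  utils::write.csv(format_num_df(out), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

format_num_df <- function(d) {
  d[] <- lapply(d, function(v)
    if (is.numeric(v)) formatC(v, digits = 15, format = "g") else v)
  d
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, regions = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  clin_first <- match("BDI", names(d))
  if (is.null(regions)) {
    last <- if (is.na(clin_first)) ncol(d) else clin_first - 1L
    regions <- region_set(names(d)[3:last])
  }
  d$group <- factor(d$group, levels = c("control", "patient"))
  if ("relapse" %in% names(d))
    d$relapse <- ifelse(d$relapse %in% c("TRUE", "FALSE"),
                        d$relapse == "TRUE", NA)
  structure(d, regions = regions, class = c("cohort_table", "data.frame"))
}
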