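#' Default synthetic-cohort configuration
#'
#' Builds the fully parameterised configuration of the synthetic two-group
#' cohort generator, calibrated to the printed summary statistics of the study
#' the pipeline is designed around:
#'
#' * two groups of 14 subjects (patients with alcohol use disorder vs healthy
#'   controls);
#' * 36 regional DVR means/SDs — the ten temporal-lobe regions carry their
#'   published group means and SDs (e.g. amygdala 1.91 +/- 0.20 in patients vs
#'   1.69 +/- 0.14 in controls); the remaining 26 regions default to mean 1.80,
#'   SD 0.15 in both groups;
#' * a baseline inter-regional correlation of 0.5 within each group (the
#'   global positive covariance pattern);
#' * a patient-specific coupling of the anterior cingulate gyrus with the
#'   middle orbitofrontal cortex, posterior orbitofrontal cortex and straight
#'   gyrus (target r = 0.85 in patients vs 0.10 in controls);
#' * clinical scores (BDI, BAI, AUDIT, drinks/week, 20 AASE temptation items)
#'   with the published group moments, floored at their legal minima;
#' * a negative association between patient amygdala DVR and the AASE reward-
#'   and relief-craving subscores (target r = -0.8), plus antidepressant-use,
#'   imipramine-equivalent and relapse structure.
#'
#' @param n_patients,n_controls Group sizes (defaults 14 and 14).
#' @param base_corr Baseline inter-regional correlation within each group,
#'   in (-1, 1); default 0.5.
#' @param regions A `region_set`; default [default_regions()].
#' @param seed Optional integer seed stored in the config (used by
#'   [generate_cohort()] when no explicit seed is given).
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- make_default_config()
#' cfg$region_params[cfg$region_params$region == "amygdala", ]
make_default_config <- function(n_patients = 14L, n_controls = 14L,
                                base_corr = 0.5, regions = default_regions(),
                                seed = NULL) {
  temporal <- data.frame(
    region = c("hippocampus", "amygdala",
               "anterior_temporal_lobe_medial", "anterior_temporal_lobe_lateral",
               "parahippocampal_ambient_gyri", "superior_temporal_gyrus_posterior",
               "middle_inferior_temporal_gyrus", "fusiform_gyrus",
               "posterior_temporal_lobe", "superior_temporal_gyrus_anterior"),
    mean_patient = c(1.76, 1.91, 1.94, 2.00, 1.85, 1.79, 1.92, 2.01, 1.79, 1.83),
    sd_patient   = c(0.18, 0.20, 0.16, 0.16, 0.20, 0.13, 0.16, 0.19, 0.14, 0.15),
    mean_control = c(1.65, 1.69, 1.80, 1.84, 1.65, 1.70, 1.78, 1.87, 1.68, 1.70),
    sd_control   = c(0.12, 0.14, 0.13, 0.13, 0.13, 0.12, 0.13, 0.12, 0.09, 0.13),
    stringsAsFactors = FALSE
  )
  nm <- regions$names
  rp <- data.frame(region = nm, mean_patient = 1.80, sd_patient = 0.15,
                   mean_control = 1.80, sd_control = 0.15,
                   stringsAsFactors = FALSE)
  m <- match(temporal$region, rp$region)
  hit <- !is.na(m)
  rp[m[hit], -1L] <- temporal[hit, -1L]

  coupled <- c("middle_orbitofrontal_cortex", "posterior_orbitofrontal_cortex",
               "straight_gyrus")
  coupled <- coupled[coupled %in% nm]
  acc <- "anterior_cingulate_gyrus"
  couplings <- if (acc %in% nm && length(coupled)) {
    data.frame(
      group = rep(c("patient", "control"), each = length(coupled)),
      region_a = acc,
      region_b = rep(coupled, 2L),
      target_r = rep(c(0.85, 0.10), each = length(coupled)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(group = character(), region_a = character(),
               region_b = character(), target_r = numeric(),
               stringsAsFactors = FALSE)
  }

  clinical_params <- list(
    BDI = list(patient = c(mean = 3.5, sd = 3.2),
               control = c(mean = 1.1, sd = 1.7), floor = 0),
    BAI = list(patient = c(mean = 2.1, sd = 1.9),
               control = c(mean = 0.9, sd = 1.9), floor = 0),
    AUDIT = list(patient = c(mean = 25, sd = 7.5),
                 control = c(mean = 2, sd = 1.5), floor = 0),
    drinks_per_week = list(patient = c(mean = 77, sd = 49),
                           control = c(mean = 4.2, sd = 2.5), floor = 0),
    aase = list(scale = c(1, 5),
                item_mean = c(patient = 2.4, control = 1.6),
                item_sd = c(patient = 0.8, control = 0.5),
                subscore_sd = 2.5, item_noise_sd = 0.25)
  )

  assoc_params <- list(
    craving_region = "amygdala",
    reward_craving_r = -0.8,
    relief_craving_r = -0.8,
    antidepressant_rate = 0.5,
    antidepressant_dvr_logodds = -1.5,
    imipramine_mean = 139.4,
    imipramine_sd = 97.8,
    imipramine_floor = 10,
    relapse_rate = 8 / 14,
    relapse_imipramine_logodds = 0.8
  )

  cfg <- structure(list(
    regions = regions,
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    region_params = rp,
    base_corr = base_corr,
    couplings = couplings,
    clinical_params = clinical_params,
    assoc_params = assoc_params,
    seed = seed
  ), class = "cohort_config")
  validate_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks group sizes, positivity of SDs, correlation bounds, that coupling
#' overrides reference known regions, and that each implied per-group
#' correlation matrix admits a positive-semidefinite completion that honours
#' the coupling targets exactly (see [generate_cohort()] for the projection).
#'
#' @param config A `cohort_config`.
#' @return `config`, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "cohort_config")) stop_("not a cohort_config")
  if (config$n_patients < 1L || config$n_controls < 1L)
    stop_("group sizes must be positive")
  rp <- config$region_params
  nm <- config$regions$names
  if (!setequal(rp$region, nm))
    stop_("region_params must cover exactly the regions of the region set")
  if (any(rp$sd_patient <= 0) || any(rp$sd_control <= 0))
    stop_("all region SDs must be > 0")
  if (abs(config$base_corr) >= 1) stop_("|base_corr| must be < 1")
  cp <- config$couplings
  if (nrow(cp)) {
    if (!all(cp$group %in% c("patient", "control")))
      stop_("coupling group labels must be 'patient' or 'control'")
    bad <- !(cp$region_a %in% nm) | !(cp$region_b %in% nm)
    if (any(bad))
      stop_("coupling regions not in region set: ",
            paste(unique(c(cp$region_a[bad], cp$region_b[bad])), collapse = ", "))
    if (any(abs(cp$target_r) >= 1)) stop_("coupling target_r must be in (-1, 1)")
    if (any(cp$region_a == cp$region_b)) stop_("coupling pairs must be distinct regions")
  }
  for (g in c("patient", "control")) group_corr_matrix(config, g)  # errors if infeasible
  invisible(config)
}

# Build the per-group population correlation matrix: base_corr everywhere,
# coupling targets at the configured pairs, projected to the PSD cone while
# holding the unit diagonal and the coupled entries fixed.
group_corr_matrix <- function(config, group) {
  nm <- config$regions$names
  r <- length(nm)
  m <- matrix(config$base_corr, r, r, dimnames = list(nm, nm))
  diag(m) <- 1
  cp <- config$couplings
  cp <- cp[cp$group == group, , drop = FALSE]
  fix_idx <- NULL
  fix_val <- NULL
  if (nrow(cp)) {
    ia <- match(cp$region_a, nm); ib <- match(cp$region_b, nm)
    fix_idx <- rbind(cbind(ia, ib), cbind(ib, ia))
    fix_val <- rep(cp$target_r, 2L)
    m[fix_idx] <- fix_val
  }
  ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= 1e-8) return(m)
  out <- project_corr_fixed(m, fix_idx, fix_val)
  if (is.null(out)) {
    pairs <- if (nrow(cp)) paste(cp$region_a, cp$region_b, sep = "-", collapse = ", ")
             else "(none)"
    stop_("correlation structure for group '", group,
          "' is not positive definite and cannot be completed; ",
          "offending pairs: ", pairs)
  }
  out
}

# Alternating projections between the PSD cone (eigenvalues clipped at 1e-8)
# and the affine set {unit diagonal; fixed entries at their targets}. The
# coupled entries and the diagonal are preserved exactly; only the remaining
# baseline entries move. Returns NULL when the two sets do not intersect
# within the iteration budget.
project_corr_fixed <- function(m, fix_idx, fix_val, eps = 1e-8,
                               maxit = 1000L, tol = 1e-10) {
  x <- m
  for (i in seq_len(maxit)) {
    e <- eigen(x, symmetric = TRUE)
    y <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
    y <- (y + t(y)) / 2
    diag(y) <- 1
    if (!is.null(fix_idx)) y[fix_idx] <- fix_val
    delta <- max(abs(y - x))
    x <- y
    if (delta < tol) break
  }
  ev_min <- min(eigen(x, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 || any(abs(x) > 1 + 1e-8)) return(NULL)
  dimnames(x) <- dimnames(m)
  x
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", length(x$regions$names), " regions, n = ",
      x$n_patients, " patients / ", x$n_controls, " controls\n", sep = "")
  cat("  base_corr = ", x$base_corr, "; ", nrow(x$couplings),
      " coupling override(s)\n", sep = "")
  invisible(x)
}

#' Read / write a cohort configuration (YAML or JSON)
#'
#' Serialises a `cohort_config` with its field names unchanged. The format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config A `cohort_config`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$regions <- list(names = config$regions$names,
                    reference = config$regions$reference)
  # named numeric vectors serialise as mappings, not sequences
  x$clinical_params <- lapply(x$clinical_params, function(v)
    lapply(v, function(e) if (!is.null(names(e))) as.list(e) else e))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, column.major = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else stop_("unsupported config format: .", ext)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else stop_("unsupported config format: .", ext)
  to_df <- function(d, cols) {
    d <- as.data.frame(do.call(rbind, lapply(d, as.data.frame)),
                       stringsAsFactors = FALSE)
    if (!nrow(d)) d <- as.data.frame(stats::setNames(
      lapply(cols, function(.) character(0)), cols))
    d
  }
  if (!is.data.frame(x$region_params)) x$region_params <- to_df(x$region_params)
  if (is.null(x$couplings) || length(x$couplings) == 0L) {
    x$couplings <- data.frame(group = character(), region_a = character(),
                              region_b = character(), target_r = numeric(),
                              stringsAsFactors = FALSE)
  } else if (!is.data.frame(x$couplings)) x$couplings <- to_df(x$couplings)
  num_cols <- c("mean_patient", "sd_patient", "mean_control", "sd_control")
  x$region_params[num_cols] <- lapply(x$region_params[num_cols], as.numeric)
  # yaml flattens named numeric vectors to lists; restore
  x$clinical_params <- lapply(x$clinical_params, function(v)
    lapply(v, function(e) if (is.list(e)) unlist(e) else e))
  cfg <- structure(list(
    regions = region_set(x$regions$names, x$regions$reference),
    n_patients = as.integer(x$n_patients),
    n_controls = as.integer(x$n_controls),
    region_params = x$region_params,
    base_corr = as.numeric(x$base_corr),
    couplings = x$couplings,
    clinical_params = x$clinical_params,
    assoc_params = x$assoc_params,
    seed = x$seed
  ), class = "cohort_config")
  validate_config(cfg)
  cfg
}
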