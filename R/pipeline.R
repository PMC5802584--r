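#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: input paths (a TAC CSV to be
#' quantified, a cohort CSV, or neither — in which case a synthetic cohort is
#' simulated from `cohort_config`), the output directory, the analysis
#' parameters and the report toggles.
#'
#' @param out_dir Output directory (created if absent).
#' @param tacs Optional TAC CSV path (quantified with [equilibrium_dvr()]).
#' @param cohort Optional cohort CSV path (used directly).
#' @param cohort_config A `cohort_config` for simulation when no input file
#'   is given; default [make_default_config()].
#' @param window Equilibrium window, numeric `c(start, end)`; default 45-60.
#' @param covariates Clinical covariates for the adjusted per-region arm;
#'   default `c("BDI", "BAI")`.
#' @param alpha Per-pair flagging threshold (default 0.001).
#' @param tail Per-pair one-tailed direction (default `"patients_greater"`).
#' @param nullsim_K Number of null simulations (0 disables; default 0).
#' @param heatmaps Render PNG heatmaps (default `TRUE`).
#' @param seed Integer seed governing all randomness in the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, tacs = NULL, cohort = NULL,
                            cohort_config = make_default_config(),
                            window = c(45, 60),
                            covariates = c("BDI", "BAI"),
                            alpha = 0.001, tail = "patients_greater",
                            nullsim_K = 0L, heatmaps = TRUE, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop_("alpha must be in (0, 1]")
  structure(list(out_dir = out_dir, tacs = tacs, cohort = cohort,
                 cohort_config = cohort_config, window = window,
                 covariates = covariates, alpha = alpha, tail = tail,
                 nullsim_K = as.integer(nullsim_K), heatmaps = heatmaps,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: obtain a cohort (quantify TACs,
#' read a cohort CSV, or simulate), per-region group comparison, normality
#' screen, the three-step correlation-network comparison (per-group matrices,
#' global Welch test on z-transformed and raw correlations, per-pair tests,
#' difference map), clinical associations, and optionally the null-simulation
#' calibration. All tables are written as TSV/CSV, scalar results as JSON,
#' heatmaps as PNG, plus a run manifest (config, seed, package version, input
#' checksums). A second run with the same config and seed reproduces
#' byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_("not a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  path <- function(f) file.path(config$out_dir, f)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  # --- stage: cohort ---------------------------------------------------
  checksums <- list()
  if (!is.null(config$tacs)) {
    if (!file.exists(config$tacs))
      stop_("stage quantify: TAC file not found: ", config$tacs)
    checksums$tacs <- unname(tools::md5sum(config$tacs))
    tacs <- read_tacs(config$tacs)
    cohort <- equilibrium_dvr(tacs, window = config$window)
    log_stage("quantify", "%d subjects x %d regions from %s",
              nrow(cohort), length(attr(cohort, "regions")$names), config$tacs)
  } else if (!is.null(config$cohort)) {
    if (!file.exists(config$cohort))
      stop_("stage cohort: cohort file not found: ", config$cohort)
    checksums$cohort <- unname(tools::md5sum(config$cohort))
    cohort <- read_cohort(config$cohort)
    log_stage("cohort", "read %d subjects from %s", nrow(cohort), config$cohort)
  } else {
    cohort <- generate_cohort(config$cohort_config, seed = config$seed)
    log_stage("simulate", "generated %d subjects (seed %d)", nrow(cohort),
              config$seed)
  }
  out$cohort <- write_cohort(cohort, path("cohort.csv"))

  # --- stage: group comparison ----------------------------------------
  covs <- intersect(config$covariates, names(cohort))
  regions_tbl <- compare_all_regions(cohort, covariates = covs, adjust = TRUE)
  utils::write.table(format_num_df(regions_tbl), path("regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  out$regions <- path("regions.tsv")
  norm_tbl <- normality_screen(cohort)
  utils::write.table(format_num_df(norm_tbl), path("normality.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  out$normality <- path("normality.tsv")
  log_stage("compare", "%d regions, %d covariate(s), %d normality flags",
            nrow(regions_tbl), length(covs), sum(norm_tbl$flagged))

  # --- stage: covnet ---------------------------------------------------
  m_ctl <- corr_matrix(cohort, "control")
  m_pat <- corr_matrix(cohort, "patient")
  out$corr_control <- write_matrix_tsv(m_ctl$r, path("corr_control.tsv"))
  out$corr_patient <- write_matrix_tsv(m_pat$r, path("corr_patient.tsv"))
  pairs_tbl <- compare_all_pairs(m_ctl, m_pat, alpha = config$alpha,
                                 tail = config$tail)
  utils::write.table(format_num_df(as.data.frame(pairs_tbl)),
                     path("pairs.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  out$pairs <- path("pairs.tsv")
  dmap <- difference_map(m_ctl, m_pat)
  out$difference_map <- write_matrix_tsv(dmap, path("difference_map.tsv"))
  glob <- list(fisher_z = unclass(global_comparison(m_ctl, m_pat, "fisher_z")),
               raw_r = unclass(global_comparison(m_ctl, m_pat, "raw_r")))
  jsonlite::write_json(glob, path("global_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  out$global <- path("global_comparison.json")
  log_stage("covnet", "%d pairs, %d flagged at alpha = %g (%s)",
            nrow(pairs_tbl), sum(pairs_tbl$flagged), config$alpha, config$tail)

  # --- stage: clinical -------------------------------------------------
  if (all(paste0("AASE_item_", 1:20) %in% names(cohort))) {
    rs <- attr(cohort, "regions")
    region <- if ("amygdala" %in% rs$names) "amygdala" else rs$names[1L]
    cl <- list(
      reward = correlate_region_clinical(cohort, region, "reward_craving",
                                         method = "spearman", group = "patient"),
      relief = correlate_region_clinical(cohort, region, "relief_craving",
                                         method = "spearman", group = "patient"),
      region = region
    )
    if ("antidepressant" %in% names(cohort))
      cl$medication <- unclass(subgroup_welch(cohort, "antidepressant", region,
                                              group = "patient"))
    if ("relapse" %in% names(cohort) && "imipramine_eq" %in% names(cohort))
      cl$relapse_imipramine <- unclass(subgroup_welch(cohort, "relapse",
                                                      "imipramine_eq",
                                                      group = "patient"))
    jsonlite::write_json(cl, path("clinical.json"), auto_unbox = TRUE,
                         digits = NA)
    out$clinical <- path("clinical.json")
    log_stage("clinical", "%s vs craving: rho = %.3f / %.3f", region,
              cl$reward$estimate, cl$relief$estimate)
  }

  # --- stage: nullsim (optional) ---------------------------------------
  if (config$nullsim_K > 0L) {
    rep <- simulate_null(config$cohort_config, K = config$nullsim_K,
                         alpha = config$alpha, seed = config$seed)
    rep$count_ci99 <- as.numeric(rep$count_ci99)
    rep$global_t$quantiles <- as.list(rep$global_t$quantiles)
    jsonlite::write_json(unclass(rep), path("null_report.json"),
                         auto_unbox = TRUE, digits = NA)
    out$null_report <- path("null_report.json")
    log_stage("nullsim", "K = %d, flag rate %.5f", rep$K, rep$flag_rate)
  }

  # --- stage: heatmaps -------------------------------------------------
  if (isTRUE(config$heatmaps)) {
    out$heatmap_control <- render_heatmap(m_ctl$r, "correlation",
                                          path("corr_control.png"))
    out$heatmap_patient <- render_heatmap(m_pat$r, "correlation",
                                          path("corr_patient.png"))
    out$heatmap_difference <- render_heatmap(dmap, "difference",
                                             path("difference_map.png"))
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "petcovnet",
    version = as.character(utils::packageVersion("petcovnet")),
    seed = config$seed,
    alpha = config$alpha, tail = config$tail,
    covariates = covs, window = config$window,
    input_checksums = checksums,
    outputs = lapply(out, basename)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out$manifest <- path("manifest.json")
  invisible(out)
}
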