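#' Standard framing for a 60-minute bolus/infusion acquisition
#'
#' @param frame_min Frame duration in minutes (must divide 60); default 5.
#' @return Data frame with `start_min`, `end_min` covering 0-60 min.
#' @export
standard_frames <- function(frame_min = 5) {
  if (60 %% frame_min != 0) stop_("frame_min must divide 60")
  s <- seq(0, 60 - frame_min, by = frame_min)
  data.frame(start_min = s, end_min = s + frame_min)
}

validate_frames <- function(frames) {
  if (!all(c("start_min", "end_min") %in% names(frames)))
    stop_("frames need columns start_min, end_min")
  if (any(frames$start_min >= frames$end_min))
    stop_("every frame must have start < end")
  o <- order(frames$start_min)
  frames <- frames[o, , drop = FALSE]
  if (any(frames$start_min[-1L] < frames$end_min[-nrow(frames)]))
    stop_("frames must be non-overlapping")
  if (min(frames$start_min) > 0 || max(frames$end_min) < 60)
    stop_("frames must cover at least 0-60 min")
  frames
}

#' Generate synthetic time-activity curves for a cohort
#'
#' Emulates a bolus/infusion acquisition: each subject's reference-region TAC
#' rises quickly and sits exactly on a flat plateau at `ref_level` from
#' `t_plateau` minutes onward; each analysis region follows the same kinetic
#' shape scaled so its plateau equals `ref_level` x the subject's assigned
#' DVR. Within the 45-60 min equilibrium window the noiseless curves are
#' therefore constant, and quantification with [equilibrium_dvr()] recovers
#' the assigned DVRs to machine precision at `noise_sd = 0`. Frame activities
#' are the curve evaluated at the frame midpoint, perturbed multiplicatively
#' by Gaussian noise with SD `noise_sd` x the frame's noiseless value
#' (clamped at zero).
#'
#' @param cohort A `cohort_table` with assigned DVRs.
#' @param frames Frame table (`start_min`, `end_min`), ordered,
#'   non-overlapping, covering at least 0-60 min; default [standard_frames()].
#' @param ref_level Reference-region plateau activity concentration
#'   (arbitrary units); default 10.
#' @param noise_sd Fractional frame noise SD; default 0 (noiseless).
#' @param seed Integer seed for the noise draws.
#' @param t_plateau Time (min) from which the curves are exactly flat;
#'   default 40 (must be <= 45 so the equilibrium window is flat).
#' @param tau Rise time constant (min) of the pre-plateau approach; default 6.
#' @return A `tac_set`: data frame with columns `subject_id`, `group`,
#'   `region`, `frame_start_min`, `frame_end_min`, `activity`, including the
#'   reference region, with the region set attached as attribute `"regions"`.
#' @export
#' @examples
#' coh <- generate_cohort(make_default_config(n_patients = 2, n_controls = 2), seed = 1)
#' tacs <- generate_tacs(coh, noise_sd = 0)
#' head(tacs)
generate_tacs <- function(cohort, frames = standard_frames(), ref_level = 10,
                          noise_sd = 0, seed = NULL, t_plateau = 40, tau = 6) {
  frames <- validate_frames(frames)
  if (t_plateau > 45)
    stop_("t_plateau must be <= 45 so the 45-60 min window is at equilibrium")
  rs <- attr(cohort, "regions")
  if (is.null(rs)) stop_("cohort has no region-set attribute")
  mid <- (frames$start_min + frames$end_min) / 2
  # normalised bolus/infusion shape: exponential approach, exact plateau at 1
  shape <- pmin(1, (1 - exp(-mid / tau)) / (1 - exp(-t_plateau / tau)))
  regions <- c(rs$names, rs$reference)
  dvr <- cbind(cohort_dvr(cohort), 1)   # reference region has DVR 1
  colnames(dvr)[ncol(dvr)] <- rs$reference

  nf <- nrow(frames)
  ns <- nrow(cohort)
  nr <- length(regions)
  out <- data.frame(
    subject_id = rep(cohort$subject_id, each = nr * nf),
    group = rep(as.character(cohort$group), each = nr * nf),
    region = rep(rep(regions, each = nf), times = ns),
    frame_start_min = rep(frames$start_min, times = ns * nr),
    frame_end_min = rep(frames$end_min, times = ns * nr),
    stringsAsFactors = FALSE
  )
  plateau <- ref_level * as.vector(t(dvr))        # subject-major, region order
  act <- as.vector(vapply(plateau, function(p) p * shape, numeric(nf)))
  if (noise_sd > 0) {
    act <- with_seed(seed, act * (1 + rnorm(length(act), 0, noise_sd)))
    act <- pmax(act, 0)
  }
  out$activity <- act
  structure(out, regions = rs, class = c("tac_set", "data.frame"))
}

#' Read and write TAC CSV files
#'
#' Dialect: header `subject_id,group,region,frame_start_min,frame_end_min,
#' activity`, activity in arbitrary concentration units.
#'
#' @param tacs A `tac_set`.
#' @param path CSV file path.
#' @param reference Reference-region label used when reading (default
#'   `"cerebellum"`).
#' @return `write_tacs()` returns `path` invisibly; `read_tacs()` a `tac_set`.
#' @export
write_tacs <- function(tacs, path) {
  cols <- c("subject_id", "group", "region", "frame_start_min",
            "frame_end_min", "activity")
  utils::write.csv(format_num_df(tacs[, cols]), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tacs
#' @export
read_tacs <- function(path, reference = "cerebellum") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "region", "frame_start_min",
            "frame_end_min", "activity")
  if (!all(need %in% names(d)))
    stop_("TAC CSV must have columns: ", paste(need, collapse = ", "))
  nm <- setdiff(unique(d$region), reference)
  structure(d, regions = region_set(nm, reference),
            class = c("tac_set", "data.frame"))
}
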