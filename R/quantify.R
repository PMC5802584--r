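#' Equilibrium window for DVR quantification
#'
#' @param start_min,end_min Window bounds in minutes (defaults 45 and 60,
#'   the late frames at bolus/infusion equilibrium).
#' @return An `equilibrium_window` object.
#' @export
equilibrium_window <- function(start_min = 45, end_min = 60) {
  if (!(is_scalar_num(start_min) && is_scalar_num(end_min)))
    stop_("window bounds must be single numbers")
  if (start_min < 0 || start_min >= end_min)
    stop_("need 0 <= start < end")
  structure(list(start_min = start_min, end_min = end_min),
            class = "equilibrium_window")
}

as_window <- function(window) {
  if (inherits(window, "equilibrium_window")) return(window)
  if (is.numeric(window) && length(window) == 2L)
    return(equilibrium_window(window[1L], window[2L]))
  stop_("window must be an equilibrium_window or numeric length-2 vector")
}

# frame inclusion rule: midpoint in [start, end)
in_window <- function(start, end, window) {
  mid <- (start + end) / 2
  mid >= window$start_min & mid < window$end_min
}

# duration-weighted mean activity of in-window frames; NA if none
window_mean <- function(start, end, activity, window) {
  keep <- in_window(start, end, window)
  if (!any(keep)) return(NA_real_)
  w <- (end - start)[keep]
  sum(w * activity[keep]) / sum(w)
}

#' Compute regional DVR at equilibrium
#'
#' The distribution volume ratio of each region is the duration-weighted mean
#' activity of its frames inside the equilibrium window divided by the same
#' quantity for the reference region. A frame is in-window iff its midpoint
#' lies in `[start, end)`. At bolus/infusion equilibrium this activity ratio
#' equals the DVR; the reference region itself yields exactly 1. Equilibrium
#' is assumed, not enforced — use [check_equilibrium()] as the diagnostic.
#'
#' @param tacs A `tac_set` (see [generate_tacs()] / [read_tacs()]).
#' @param window An `equilibrium_window` or numeric `c(start, end)`;
#'   default 45-60 min.
#' @param regions Region set; defaults to the one attached to `tacs`.
#' @return A `cohort_table` data frame (`subject_id`, `group`, one DVR column
#'   per analysis region).
#' @export
#' @examples
#' coh <- generate_cohort(make_default_config(n_patients = 2, n_controls = 2), seed = 1)
#' tacs <- generate_tacs(coh, noise_sd = 0)
#' dvr <- equilibrium_dvr(tacs)
#' all.equal(dvr$amygdala, coh$amygdala)
equilibrium_dvr <- function(tacs, window = equilibrium_window(),
                            regions = attr(tacs, "regions")) {
  window <- as_window(window)
  if (is.null(regions)) stop_("no region set available")
  subjects <- unique(tacs$subject_id)
  nm <- regions$names
  dvr <- matrix(NA_real_, length(subjects), length(nm),
                dimnames = list(subjects, nm))
  grp <- character(length(subjects))
  for (i in seq_along(subjects)) {
    ts <- tacs[tacs$subject_id == subjects[i], , drop = FALSE]
    grp[i] <- ts$group[1L]
    ref <- ts[ts$region == regions$reference, , drop = FALSE]
    if (!nrow(ref))
      stop_("subject ", subjects[i], ": reference region '",
            regions$reference, "' missing")
    ref_mean <- window_mean(ref$frame_start_min, ref$frame_end_min,
                            ref$activity, window)
    if (is.na(ref_mean))
      stop_("subject ", subjects[i], ": reference region has no in-window frames")
    if (ref_mean == 0)
      stop_("subject ", subjects[i], ": zero reference activity in window")
    for (r in nm) {
      tr <- ts[ts$region == r, , drop = FALSE]
      if (!nrow(tr))
        stop_("subject ", subjects[i], ": region '", r, "' missing")
      m <- window_mean(tr$frame_start_min, tr$frame_end_min, tr$activity, window)
      if (is.na(m))
        stop_("subject ", subjects[i], ", region '", r,
              "': no frames in the equilibrium window")
      dvr[i, r] <- m / ref_mean
    }
  }
  out <- data.frame(subject_id = subjects,
                    group = factor(grp, levels = c("control", "patient")),
                    dvr, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, regions = regions, class = c("cohort_table", "data.frame"))
}

#' Equilibrium diagnostic: relative in-window TAC slope
#'
#' Operationalises the visual inspection of tracer kinetics: for every
#' (subject, region) — reference included — an ordinary least squares line of
#' activity against frame midpoint is fitted within the window, and the slope
#' relative to the mean in-window activity is compared against `slope_tol`.
#' Cells with fewer than two in-window frames are marked indeterminate rather
#' than failing. The diagnostic never alters DVR values.
#'
#' @inheritParams equilibrium_dvr
#' @param slope_tol Tolerated |slope|/mean in fraction per minute
#'   (default 0.005).
#' @return Data frame with one row per (subject, region): `rel_slope`
#'   (per minute), `flagged`, `indeterminate`.
#' @export
check_equilibrium <- function(tacs, window = equilibrium_window(),
                              slope_tol = 0.005) {
  window <- as_window(window)
  key <- interaction(tacs$subject_id, tacs$region, drop = TRUE)
  res <- lapply(split(tacs, key), function(ts) {
    keep <- in_window(ts$frame_start_min, ts$frame_end_min, window)
    ts <- ts[keep, , drop = FALSE]
    if (nrow(ts) < 2L) {
      return(data.frame(subject_id = ts$subject_id[1L] %||% NA,
                        region = ts$region[1L] %||% NA,
                        rel_slope = NA_real_, flagged = FALSE,
                        indeterminate = TRUE, stringsAsFactors = FALSE))
    }
    mid <- (ts$frame_start_min + ts$frame_end_min) / 2
    mu <- mean(ts$activity)
    slope <- if (stats::var(mid) == 0) 0 else
      stats::cov(mid, ts$activity) / stats::var(mid)
    rel <- if (mu == 0) Inf else slope / mu
    data.frame(subject_id = ts$subject_id[1L], region = ts$region[1L],
               rel_slope = rel, flagged = abs(rel) > slope_tol,
               indeterminate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
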