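# shared fixtures and independent oracles

# small region set with the coupled ACC-straight-gyrus pair present
tiny_regions <- function() {
  region_set(c("amygdala", "anterior_cingulate_gyrus", "straight_gyrus",
               "hippocampus", "insula"))
}

tiny_config <- function(n = 14L, ...) {
  make_default_config(n_patients = n, n_controls = n,
                      regions = tiny_regions(), ...)
}

# hand-built TAC set: one subject, constant activities per region
const_tacs <- function(activities, frames = standard_frames(),
                       subject = "S01", group = "patient",
                       reference = "cerebellum") {
  stopifnot(reference %in% names(activities))
  rows <- lapply(names(activities), function(r)
    data.frame(subject_id = subject, group = group, region = r,
               frame_start_min = frames$start_min,
               frame_end_min = frames$end_min,
               activity = activities[[r]], stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  structure(d, regions = region_set(setdiff(names(activities), reference),
                                    reference),
            class = c("tac_set", "data.frame"))
}

# brute-force Pearson matrix via explicit covariance / SD loops
brute_corr <- function(x) {
  p <- ncol(x)
  out <- diag(1, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    a <- x[, i] - mean(x[, i]); b <- x[, j] - mean(x[, j])
    out[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  dimnames(out) <- list(colnames(x), colnames(x))
  out
}

# pooled-variance two-sample t statistic (for the F = t^2 identity)
pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# brute-force DVR: resample each frame to per-minute activities, average
# minutes whose centre lies in the window, ratio to reference
brute_dvr <- function(tacs, region, subject, window = c(45, 60),
                      reference = "cerebellum") {
  per_minute <- function(r) {
    ts <- tacs[tacs$subject_id == subject & tacs$region == r, ]
    mins <- acts <- numeric(0)
    for (k in seq_len(nrow(ts))) {
      m <- seq(ts$frame_start_min[k] + 0.5, ts$frame_end_min[k] - 0.5, by = 1)
      mins <- c(mins, m); acts <- c(acts, rep(ts$activity[k], length(m)))
    }
    keep <- mins >= window[1] & mins < window[2]
    mean(acts[keep])
  }
  per_minute(region) / per_minute(reference)
}
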