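#' Welch's two-sample t test (unequal variances)
#'
#' Welch's t statistic `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch–Satterthwaite degrees of freedom
#' `df = (v1 + v2)^2 / (v1^2/(n1-1) + v2^2/(n2-1))`, `vi = si^2/ni`.
#' Accepts either raw samples or summary statistics (`list(mean, sd, n)`);
#' both give identical results, so printed summary tables can be re-tested
#' without raw data.
#'
#' @param x,y Numeric samples (length >= 2), or `list(mean=, sd=, n=)`
#'   summaries.
#' @param tail `"two_sided"` (default), `"greater"` (alternative: mean of `x`
#'   larger) or `"less"`.
#' @return A `welch_result`: list with `t`, `df`, `p`, `tail`, `mean_1`,
#'   `mean_2`, `sd_1`, `sd_2`, `n_1`, `n_2`.
#' @export
#' @examples
#' # printed-summary recomputation: BDI 3.5 (3.2) vs 1.1 (1.7), n = 14 each
#' welch_test(list(mean = 3.5, sd = 3.2, n = 14),
#'            list(mean = 1.1, sd = 1.7, n = 14))
welch_test <- function(x, y, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  sx <- as_summary(x, "x")
  sy <- as_summary(y, "y")
  if (sx$sd == 0 && sy$sd == 0) stop_("degenerate samples: both SDs are zero")
  v1 <- sx$sd^2 / sx$n
  v2 <- sy$sd^2 / sy$n
  t <- (sx$mean - sy$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (sx$n - 1) + v2^2 / (sy$n - 1))
  p <- switch(tail,
    two_sided = 2 * stats::pt(-abs(t), df),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df)
  )
  structure(list(t = t, df = df, p = p, tail = tail,
                 mean_1 = sx$mean, mean_2 = sy$mean,
                 sd_1 = sx$sd, sd_2 = sy$sd, n_1 = sx$n, n_2 = sy$n),
            class = "welch_result")
}

as_summary <- function(x, label) {
  if (is.list(x)) {
    if (!all(c("mean", "sd", "n") %in% names(x)))
      stop_("summary input '", label, "' needs mean, sd, n")
    s <- list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
              n = as.numeric(x$n))
  } else {
    x <- as.numeric(x)
    if (length(x) < 2L) stop_("sample '", label, "' needs >= 2 observations")
    s <- list(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
  if (s$n < 2) stop_("sample '", label, "' needs n >= 2")
  if (s$sd < 0) stop_("negative SD for '", label, "'")
  s
}

#' @export
print.welch_result <- function(x, digits = 4, ...) {
  cat(sprintf("Welch two-sample t test (%s)\n", x$tail))
  cat(sprintf("  t = %.*g, df = %.*g, p = %.*g\n",
              digits, x$t, digits, x$df, digits, x$p))
  cat(sprintf("  group 1: mean %.*g (SD %.*g), n = %g\n",
              digits, x$mean_1, digits, x$sd_1, x$n_1))
  cat(sprintf("  group 2: mean %.*g (SD %.*g), n = %g\n",
              digits, x$mean_2, digits, x$sd_2, x$n_2))
  invisible(x)
}
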