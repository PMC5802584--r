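#' Render a correlation or difference heatmap
#'
#' Deterministic PNG rendering of a symmetric region-by-region matrix.
#' `style = "correlation"` uses a sequential white-to-red scale over [0, 1]
#' (negative values are shown at the scale floor); `style = "difference"`
#' uses a diverging scale symmetric about 0 with red for positive entries
#' (pair more strongly coupled in controls, for a controls-minus-patients
#' map) and blue for negative entries (more strongly coupled in patients).
#'
#' @param m Square symmetric numeric matrix.
#' @param style `"correlation"` or `"difference"`.
#' @param file Output PNG path.
#' @param size Image size in pixels (default 900).
#' @return `file`, invisibly.
#' @export
render_heatmap <- function(m, style = c("correlation", "difference"), file,
                           size = 900) {
  style <- match.arg(style)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_("input must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8) stop_("input must be symmetric")
  r <- nrow(m)
  if (style == "correlation") {
    breaks <- seq(0, 1, length.out = 101L)
    pal <- grDevices::colorRampPalette(c("white", "#fdd49e", "#d7301f"))(100L)
    z <- pmin(pmax(m, 0), 1)
  } else {
    lim <- max(abs(m), 1e-12)
    breaks <- seq(-lim, lim, length.out = 101L)
    pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(100L)
    z <- m
  }
  grDevices::png(file, width = size, height = size)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(8, 8, 2, 2))
  # flip rows so the first region is plotted at the top
  graphics::image(seq_len(r), seq_len(r), t(z[r:1, , drop = FALSE]),
                  col = pal, breaks = breaks, axes = FALSE, xlab = "",
                  ylab = "", useRaster = TRUE)
  lab <- colnames(m) %||% as.character(seq_len(r))
  cexl <- min(0.8, 25 / r)
  graphics::axis(1, at = seq_len(r), labels = lab, las = 2, cex.axis = cexl,
                 tick = FALSE)
  graphics::axis(2, at = seq_len(r), labels = rev(lab), las = 2,
                 cex.axis = cexl, tick = FALSE)
  graphics::box()
  invisible(file)
}
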