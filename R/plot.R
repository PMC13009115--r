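#' @include bullseye.R
NULL

#' Polar bullseye plot of a 24-segment map
#'
#' Draws the biventricular 24-segment model as two polar plots (LV left,
#' RV right) with basal segments outermost, colored by segment value;
#' masked segments are hatched grey.
#'
#' @param bullseye a \linkS4class{SegmentBullseye}.
#' @param model segment model.
#' @param palette color ramp function (values low to high).
#' @param main plot title.
#' @return invisibly, the value range used for the color scale.
#' @export
plotBullseye <- function(bullseye, model = buildSegmentModel(),
                         palette = grDevices::colorRampPalette(
                           c("#b2182b", "#f7f7f7", "#2166ac")),
                         main = "") {
  v <- bullseye@values
  rng <- range(v, na.rm = TRUE)
  cols <- palette(64)
  colOf <- function(x) {
    if (is.na(x)) return("grey85")
    if (diff(rng) == 0) return(cols[32])
    cols[1 + round(63 * (x - rng[1]) / diff(rng))]
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op))
  ringRadius <- c(basal = 1, mid = 2 / 3, apical = 1 / 3)
  for (ch in c("LV", "RV")) {
    graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
      axes = FALSE, xlab = "", ylab = "",
      main = if (ch == "LV") main else "")
    graphics::mtext(ch, side = 3, line = -1)
    for (lev in c("basal", "mid", "apical")) {
      segs <- model[model$chamber == ch & model$level == lev, ]
      nS <- nrow(segs)
      r1 <- ringRadius[[lev]]; r0 <- r1 - 1 / 3
      for (k in seq_len(nS)) {
        th <- seq((k - 1) * 2 * pi / nS, k * 2 * pi / nS, length.out = 30) +
          pi / 2
        xs <- c(r0 * cos(th), rev(r1 * cos(th)))
        ys <- c(r0 * sin(th), rev(r1 * sin(th)))
        val <- v[[segs$segment[k]]]
        graphics::polygon(xs, ys, col = colOf(val), border = "grey30",
          density = if (is.na(val)) 12 else NULL)
      }
    }
  }
  invisible(rng)
}
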