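#' 2-D density histogram of a phasor field
#'
#' Bins the defined (and mask-included) `(g, s)` pairs on a regular grid
#' over the region of the phasor plot that contains the universal circle,
#' `g` in [-0.005, 1.005] and `s` in [-0.005, 0.605] by default. Bins are
#' half-open with the last bin closed, so every in-domain point lands in
#' exactly one bin; points outside the domain are counted in `n_outside`.
#'
#' @param field A `phasor_field`.
#' @param mask Optional [flim_mask()].
#' @param bins Number of bins per axis (>= 10).
#' @param g_range,s_range Histogram domain.
#' @return Object of class `phasor_histogram`: `counts` (bins x bins matrix,
#'   g along rows), `g_edges`, `s_edges`, `n_defined` (points binned),
#'   `n_outside`, and the field's `harmonic`.
#' @export
phasor_histogram <- function(field, mask = NULL, bins = 256L,
                             g_range = c(-0.005, 1.005),
                             s_range = c(-0.005, 0.605)) {
  stopifnot(inherits(field, "phasor_field"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 10L) stop("bins must be >= 10")
  keep <- defined_pixels(field)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "flim_mask"),
              identical(dim(mask$include), dim(field$g)))
    keep <- keep & mask$include
  }
  if (!any(keep)) stop("no defined pixels to bin")
  gv <- field$g[keep]; sv <- field$s[keep]
  g_edges <- seq(g_range[1], g_range[2], length.out = bins + 1L)
  s_edges <- seq(s_range[1], s_range[2], length.out = bins + 1L)
  gi <- findInterval(gv, g_edges, rightmost.closed = TRUE)
  si <- findInterval(sv, s_edges, rightmost.closed = TRUE)
  inside <- gi >= 1L & gi <= bins & si >= 1L & si <= bins
  counts <- matrix(0L, bins, bins)
  if (any(inside)) {
    tab <- table(factor(gi[inside], levels = seq_len(bins)),
                 factor(si[inside], levels = seq_len(bins)))
    counts <- matrix(as.integer(tab), bins, bins)
  }
  structure(list(counts = counts, g_edges = g_edges, s_edges = s_edges,
                 n_defined = sum(inside), n_outside = sum(!inside),
                 harmonic = field$params$harmonic),
            class = "phasor_histogram")
}

#' Draw a phasor histogram on the current graphics device
#'
#' Density colour map (log-scaled by default), the universal semicircle of
#' radius 1/2 centred at (1/2, 0), the harmonic annotated in the top corner,
#' and optional species markers and cursor circles.
#'
#' @param hist A [phasor_histogram()].
#' @param species List of [species_location()]s to mark.
#' @param cursors List of cursor circles, each `list(g, s, radius)`.
#' @param log_scale Log-scale the density colours? Default `TRUE`.
#' @param main Plot title.
#' @export
draw_phasor_plot <- function(hist, species = list(), cursors = list(),
                             log_scale = TRUE, main = "Phasor plot") {
  stopifnot(inherits(hist, "phasor_histogram"))
  z <- hist$counts
  z <- if (log_scale) log1p(z) else z * 1.0
  z[z == 0] <- NA
  gm <- (hist$g_edges[-1] + hist$g_edges[-length(hist$g_edges)]) / 2
  sm <- (hist$s_edges[-1] + hist$s_edges[-length(hist$s_edges)]) / 2
  graphics::image(gm, sm, z, col = grDevices::hcl.colors(256, "Inferno"),
                  xlab = "g", ylab = "s", main = main, useRaster = TRUE,
                  xlim = range(hist$g_edges), ylim = range(hist$s_edges))
  ang <- seq(0, pi, length.out = 361)
  graphics::lines(0.5 + 0.5 * cos(ang), 0.5 * sin(ang), col = "grey30")
  graphics::text(max(hist$g_edges), max(hist$s_edges),
                 sprintf("harmonic %d", hist$harmonic),
                 adj = c(1, 1), cex = 0.9)
  for (sp in species) {
    graphics::points(sp$g, sp$s, pch = 4, lwd = 2, col = "red3")
    graphics::text(sp$g, sp$s, sp$name, pos = 3, cex = 0.8, col = "red3")
  }
  for (cu in cursors)
    graphics::symbols(cu$g, cu$s, circles = cu$radius, inches = FALSE,
                      add = TRUE, fg = "dodgerblue3")
  invisible(hist)
}

#' Render a phasor histogram to a PNG file
#'
#' @param hist A [phasor_histogram()].
#' @param out_path Output PNG path.
#' @param ... Passed to [draw_phasor_plot()].
#' @param width,height Figure size in pixels.
#' @return `out_path`, invisibly.
#' @export
render_phasor_plot <- function(hist, out_path, ..., width = 700L,
                               height = 480L) {
  grDevices::png(out_path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  draw_phasor_plot(hist, ...)
  invisible(out_path)
}

#' Render a contrast map to a PNG file with a colour bar
#'
#' Values are clamped to `[lo, hi]`; undefined (NaN) pixels render black.
#'
#' @param map Numeric matrix (row 1 = top image row).
#' @param out_path Output PNG path.
#' @param lo,hi Display range, `lo < hi`.
#' @param colormap_name Palette name understood by
#'   [grDevices::hcl.colors()], default `"Viridis"`.
#' @param title Figure title.
#' @param width,height Figure size in pixels.
#' @return `out_path`, invisibly.
#' @export
render_map <- function(map, out_path, lo, hi, colormap_name = "Viridis",
                       title = "", width = 640L, height = 520L) {
  stopifnot(is.matrix(map))
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("display range must satisfy lo < hi")
  z <- pmin(pmax(map, lo), hi)
  # image() draws x along rows, y upward: transpose and flip so row 1 is top
  zt <- t(z[rev(seq_len(nrow(z))), , drop = FALSE])
  cols <- grDevices::hcl.colors(256, colormap_name)
  grDevices::png(out_path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  graphics::par(mar = c(2, 2, 3, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, ncol(z)), ylim = c(0, nrow(z)),
                        asp = 1, xaxs = "i", yaxs = "i")
  graphics::rect(0, 0, ncol(z), nrow(z), col = "black", border = NA)
  graphics::image(seq(0.5, ncol(z) - 0.5), seq(0.5, nrow(z) - 0.5), zt,
                  zlim = c(lo, hi), col = cols, add = TRUE,
                  useRaster = TRUE)
  graphics::title(main = title)
  graphics::par(mar = c(2, 1, 3, 3))
  ramp <- seq(lo, hi, length.out = 256)
  graphics::image(1, ramp, matrix(ramp, 1), zlim = c(lo, hi), col = cols,
                  xlab = "", ylab = "", axes = FALSE)
  graphics::axis(4)
  invisible(out_path)
}
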