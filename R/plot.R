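#' Render an orientation-preference map
#'
#' Standard OP map rendering: preferred orientation \eqn{\theta =
#' \arg z / 2} as cyclic hue, optionally modulated in brightness by
#' selectivity \eqn{|z|}, with zero contours of a real (ocular dominance)
#' field and charge-coded pinwheel markers superimposed.
#'
#' @param state a [field_state()] (or a bare complex matrix with `grid`
#'   supplied).
#' @param grid the [grid_spec()] (taken from `state` if available).
#' @param selectivity modulate brightness by \eqn{|z|}.
#' @param od_contours overlay zero contours of the first real field.
#' @param pinwheels overlay pinwheel markers (`+` charge: star, `-`:
#'   cross); `NULL` disables, `TRUE` detects them, or pass a
#'   `pinwheel_set`.
#' @param main plot title.
#' @return invisibly, the `pinwheel_set` used for the overlay (or `NULL`).
#' @export
render_map <- function(state, grid = NULL, selectivity = FALSE,
                       od_contours = TRUE, pinwheels = NULL, main = NULL) {
  if (inherits(state, "field_state")) {
    z <- state$z; o <- if (length(state$o)) state$o[[1]]
    grid <- state$grid
    if (is.null(main)) main <- sprintf("t = %.3g", state$t)
  } else {
    z <- state; o <- NULL
    if (is.null(grid)) stop("grid required for a bare matrix")
  }
  os <- orientation_and_selectivity(z)
  hue <- os$theta / pi
  val <- if (selectivity) {
    s <- os$selectivity / max(os$selectivity, 1e-300)
    0.25 + 0.75 * s
  } else 1
  hue[is.na(hue)] <- 0
  col <- grDevices::hsv(hue, 1, val)
  xy <- grid_coords(grid)
  graphics::plot(NA, xlim = c(0, grid$lx), ylim = c(0, grid$ly), asp = 1,
                 xlab = "x / Lambda", ylab = "y / Lambda", main = main)
  graphics::rasterImage(grDevices::as.raster(matrix(col, grid$ny, grid$nx)[grid$ny:1, ]),
                        0, 0, grid$lx, grid$ly, interpolate = FALSE)
  if (od_contours && !is.null(o))
    graphics::contour(xy$x, xy$y, t(o), levels = 0, add = TRUE,
                      drawlabels = FALSE, col = "black", lwd = 1.5)
  pw <- NULL
  if (!is.null(pinwheels) && !isFALSE(pinwheels)) {
    pw <- if (inherits(pinwheels, "pinwheel_set")) pinwheels
          else find_pinwheels(z, grid)
    if (nrow(pw))
      graphics::points(pw$x, pw$y, pch = ifelse(pw$q > 0, 8, 4),
                       col = "white", cex = 0.8, lwd = 1.4)
  }
  invisible(pw)
}

#' @export
plot.field_state <- function(x, ...) render_map(x, ...)

#' @export
#' @importFrom graphics plot lines legend
plot.frame_set <- function(x, which = c("power", "energy"), ...) {
  which <- match.arg(which)
  d <- x$diagnostics
  tp <- pmax(d$t, min(d$t[d$t > 0]))
  if (which == "power") {
    cols <- grep("^power_", names(d), value = TRUE)
    graphics::matplot(tp, as.matrix(d[, cols, drop = FALSE]), type = "l",
                      log = "x", lty = 1, xlab = "t / τ", ylab = "power",
                      ...)
    graphics::legend("topleft", legend = cols, lty = 1,
                     col = seq_along(cols), bty = "n")
  } else {
    graphics::plot(tp, d$energy, type = "l", log = "x",
                   xlab = "t / τ", ylab = "energy per unit area", ...)
  }
  invisible(x)
}

#' @export
plot.pinwheel_set <- function(x, ...) {
  g <- attr(x, "grid")
  graphics::plot(x$x, x$y, pch = ifelse(x$q > 0, 8, 4),
                 col = ifelse(x$flagged, "red", "black"),
                 xlim = c(0, g$lx), ylim = c(0, g$ly), asp = 1,
                 xlab = "x / Lambda", ylab = "y / Lambda", ...)
  invisible(x)
}
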