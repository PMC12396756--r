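#' Rectangular observation window
#'
#' The bounded region a point pattern lives in. Coordinates are continuous
#' pixel units with the origin at the lower-left corner; `pixel_size_um`
#' converts pixels to microns (the default corresponds to CODEX imaging at
#' 0.37745 um per pixel).
#'
#' @param x_min,x_max,y_min,y_max Window edges in pixels.
#' @param pixel_size_um Microns per pixel; must be positive.
#' @return An object of class `ms_window`.
#' @examples
#' w <- pattern_window(0, 1000, 0, 500)
#' window_area(w)
#' @export
pattern_window <- function(x_min, x_max, y_min, y_max, pixel_size_um = 0.37745) {
  stopifnot(is.numeric(x_min), is.numeric(x_max), is.numeric(y_min),
            is.numeric(y_max), length(pixel_size_um) == 1L)
  if (!(x_max > x_min) || !(y_max > y_min))
    stop("window must have positive extent: x_max > x_min and y_max > y_min")
  if (!(pixel_size_um > 0)) stop("pixel_size_um must be > 0")
  structure(
    list(x_min = as.numeric(x_min), x_max = as.numeric(x_max),
         y_min = as.numeric(y_min), y_max = as.numeric(y_max),
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "ms_window"
  )
}

#' @rdname pattern_window
#' @param window An `ms_window`.
#' @export
window_area <- function(window) {
  (window$x_max - window$x_min) * (window$y_max - window$y_min)
}

#' @export
print.ms_window <- function(x, ...) {
  cat(sprintf("window [%g, %g] x [%g, %g] px (%.5g um/px)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$pixel_size_um))
  invisible(x)
}

# bounding-box window of a coordinate table; degenerate extents (single
# point or collinear cells) are padded so the window stays valid
bbox_window <- function(x, y, pixel_size_um = 0.37745) {
  pad_x <- if (max(x) > min(x)) 0 else 0.5
  pad_y <- if (max(y) > min(y)) 0 else 0.5
  pattern_window(min(x) - pad_x, max(x) + pad_x,
                 min(y) - pad_y, max(y) + pad_y, pixel_size_um)
}

as_ms_window <- function(w) {
  if (inherits(w, "ms_window")) return(w)
  if (is.list(w) && all(c("x_min", "x_max", "y_min", "y_max") %in% names(w)))
    return(pattern_window(w$x_min, w$x_max, w$y_min, w$y_max,
                          w$pixel_size_um %||% 0.37745))
  stop("cannot interpret `window`; use pattern_window()")
}
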