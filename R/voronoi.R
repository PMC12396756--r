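# clip a convex polygon (matrix of vertices) to the halfplane a.p <= c
clip_halfplane <- function(poly, a, cval) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  keep <- drop(poly %*% a) <= cval + 1e-12
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    if (keep[i]) out <- rbind(out, p)
    if (keep[i] != keep[j]) {
      t <- (cval - sum(a * p)) / sum(a * (q - p))
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

#' Truncated Voronoi cell shapes
#'
#' Builds one convex polygon per center: the intersection of its Voronoi
#' cell, the window, and a disc of `max_radius` pixels around the center
#' (the disc approximated by a regular 64-gon). Polygons are pairwise
#' non-overlapping, shared Voronoi edges apart, and every vertex lies
#' within `max_radius` of its center.
#'
#' @param centers A `cell_pattern` or tibble with `x`, `y`.
#' @param window An [pattern_window()]; defaults to the pattern's window.
#' @param max_radius Truncation radius, pixels.
#' @param n_disc Number of vertices of the disc polygon.
#' @return A tibble with columns `cell` (center index), `vertex`, `x`,
#'   `y`, in drawing order.
#' @export
truncated_voronoi <- function(centers, window = NULL, max_radius = 20,
                              n_disc = 64) {
  if (inherits(centers, "cell_pattern") && is.null(window))
    window <- pattern_window_of(centers)
  stopifnot(!is.null(window), nrow(centers) >= 1)
  window <- as_ms_window(window)
  x <- centers$x; y <- centers$y
  n <- length(x)
  if (anyDuplicated(cbind(x, y))) stop("duplicate centers")
  ang <- 2 * pi * (seq_len(n_disc) - 1) / n_disc
  disc <- cbind(cos(ang), sin(ang)) * max_radius

  out <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- sweep(disc, 2, c(x[i], y[i]), "+")
    # window edges
    poly <- clip_halfplane(poly, c(1, 0), window$x_max)
    poly <- clip_halfplane(poly, c(-1, 0), -window$x_min)
    poly <- clip_halfplane(poly, c(0, 1), window$y_max)
    poly <- clip_halfplane(poly, c(0, -1), -window$y_min)
    # perpendicular bisectors of neighbors close enough to cut the disc
    d2 <- (x - x[i])^2 + (y - y[i])^2
    nb <- which(d2 > 0 & d2 < (2 * max_radius)^2)
    for (j in nb) {
      a <- c(x[j] - x[i], y[j] - y[i])
      cval <- sum(a * c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2))
      poly <- clip_halfplane(poly, a, cval)
      if (nrow(poly) == 0) break
    }
    if (nrow(poly))
      out[[i]] <- tibble(cell = i, vertex = seq_len(nrow(poly)),
                         x = poly[, 1], y = poly[, 2])
  }
  dplyr::bind_rows(out)
}

# polygon areas of a truncated_voronoi() result (shoelace formula)
polygon_areas <- function(shapes) {
  vapply(split(shapes, shapes$cell), function(p) {
    xx <- p$x; yy <- p$y
    abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
  }, numeric(1))
}
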