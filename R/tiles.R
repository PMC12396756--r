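#' Extract random square tiles with halos
#'
#' Samples axis-aligned square subregions of a pattern for heterogeneity
#' analysis. Each tile must (i) lie at least `edge_margin` pixels inside the
#' source window, (ii) contain every cell type with at least
#' `min_cells_per_type` cells of each, and (iii) hold at least
#' `min_fraction_of_mean` of the expected number of cells per tile (tile
#' area times the overall density). Candidate tiles violating a constraint
#' are resampled up to `max_tries` draws.
#'
#' Each tile carries a *halo*: the source cells outside the tile but within
#' the outermost interaction range of the tile rectangle. Fitting on a tile
#' with its halo makes boundary cells' neighbor counts complete without an
#' edge correction.
#'
#' @param pattern A `cell_pattern`.
#' @param tile_size Side length of the square tiles, pixels.
#' @param n_tiles Number of tiles to return.
#' @param range_spec A [range_spec()]; its outermost breakpoint sets the
#'   halo depth.
#' @param min_cells_per_type Minimum count of every type inside a tile.
#' @param min_fraction_of_mean Minimum fraction of the density-expected
#'   cells per tile.
#' @param edge_margin Minimum distance from tile edges to window edges, px.
#' @param allow_overlap Allow tiles to overlap each other (tiles are
#'   sampled independently); set `FALSE` to reject overlapping candidates.
#' @param seed Optional seed.
#' @param max_tries Total candidate draws before giving up.
#' @return A `tile_set` tibble with one row per tile: the tile pattern and
#'   its halo cells as list-columns plus the tile origin.
#' @export
extract_tiles <- function(pattern, tile_size, n_tiles,
                          range_spec = multistrauss::range_spec(),
                          min_cells_per_type = 100,
                          min_fraction_of_mean = 0.2,
                          edge_margin = 500,
                          allow_overlap = TRUE,
                          seed = NULL, max_tries = 100 * n_tiles) {
  w <- pattern_window_of(pattern)
  lo_x <- w$x_min + edge_margin
  hi_x <- w$x_max - edge_margin - tile_size
  lo_y <- w$y_min + edge_margin
  hi_y <- w$y_max - edge_margin - tile_size
  if (hi_x < lo_x || hi_y < lo_y)
    stop("tile_size + 2*edge_margin does not fit in the window")
  halo_r <- r_max(range_spec)
  dens <- nrow(pattern) / window_area(w)
  min_cells_total <- min_fraction_of_mean * dens * tile_size^2
  ts <- type_set(pattern)

  fails <- c(types = 0L, total = 0L, overlap = 0L)
  tiles <- list()
  with_seed(seed, {
    tries <- 0L
    while (length(tiles) < n_tiles && tries < max_tries) {
      tries <- tries + 1L
      ox <- runif(1, lo_x, hi_x)
      oy <- runif(1, lo_y, hi_y)
      if (!allow_overlap && length(tiles)) {
        prev <- vapply(tiles, function(t) c(t$ox, t$oy), numeric(2))
        if (any(abs(prev[1, ] - ox) < tile_size &
                abs(prev[2, ] - oy) < tile_size)) {
          fails["overlap"] <- fails["overlap"] + 1L
          next
        }
      }
      inside <- pattern$x >= ox & pattern$x <= ox + tile_size &
        pattern$y >= oy & pattern$y <= oy + tile_size
      cells <- as_tibble(pattern)[inside, ]
      cnt <- table(factor(cells$type, levels = ts))
      if (any(cnt < min_cells_per_type)) { fails["types"] <- fails["types"] + 1L; next }
      if (nrow(cells) < min_cells_total) { fails["total"] <- fails["total"] + 1L; next }
      # halo: cells outside the tile within halo_r of the tile rectangle
      dx <- pmax(ox - pattern$x, pattern$x - (ox + tile_size), 0)
      dy <- pmax(oy - pattern$y, pattern$y - (oy + tile_size), 0)
      in_halo <- !inside & sqrt(dx^2 + dy^2) <= halo_r
      tw <- pattern_window(ox, ox + tile_size, oy, oy + tile_size,
                           w$pixel_size_um)
      tp <- new_cell_pattern(cells[c("x", "y", "type")], tw, ts,
                             sprintf("%s.tile%02d",
                                     pattern_id(pattern) %||% "pattern",
                                     length(tiles) + 1L))
      tiles[[length(tiles) + 1L]] <-
        list(ox = ox, oy = oy, tile = tp,
             halo = as_tibble(pattern)[in_halo, c("x", "y", "type")])
    }
  })
  if (length(tiles) < n_tiles)
    stop(sprintf(paste0("could not place %d tiles in %d draws ",
                        "(failed: %d type-count, %d total-count, %d overlap)"),
                 n_tiles, max_tries, fails["types"], fails["total"],
                 fails["overlap"]))
  out <- tibble(
    tile_id = vapply(tiles, function(t) pattern_id(t$tile), character(1)),
    x0 = vapply(tiles, function(t) t$ox, numeric(1)),
    y0 = vapply(tiles, function(t) t$oy, numeric(1)),
    tile = lapply(tiles, function(t) t$tile),
    halo = lapply(tiles, function(t) t$halo)
  )
  structure(out, tile_size = tile_size, range_spec = range_spec,
            constraints = list(min_cells_per_type = min_cells_per_type,
                               min_fraction_of_mean = min_fraction_of_mean,
                               edge_margin = edge_margin),
            class = c("tile_set", class(out)))
}
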