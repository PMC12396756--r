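# ---- neighbor counting -----------------------------------------------------

# pooled cells (pattern + optional halo) as a plain list of vectors
pool_cells <- function(pattern, halo = NULL) {
  ts <- type_set(pattern)
  x <- pattern$x; y <- pattern$y; tc <- type_codes(pattern)
  if (!is.null(halo) && nrow(halo)) {
    x <- c(x, halo$x); y <- c(y, halo$y)
    tc <- c(tc, match(as.character(halo$type), ts))
    if (anyNA(tc)) stop("halo contains type labels not in the pattern's type_set")
  }
  list(x = x, y = y, type = tc, type_set = ts)
}

# low-level wrapper around the compiled counter; returns counts matrix
# (rows = queries, cols = type-within-bin) and a hardcore flag per query
neighbor_counts_raw <- function(qx, qy, pool, range_spec, exclude = NULL) {
  exclude <- exclude %||% integer(length(qx))
  res <- cpp_neighbor_counts(as.numeric(qx), as.numeric(qy),
                             pool$x, pool$y, as.integer(pool$type),
                             length(pool$type_set),
                             range_spec$hardcore, range_spec$breakpoints,
                             as.integer(exclude))
  colnames(res$counts) <- as.vector(outer(pool$type_set,
                                          seq_len(n_ranges(range_spec)),
                                          function(t, k) paste0(t, ":r", k)))
  res
}

#' Count typed neighbors by distance range
#'
#' Counts, for a query location, the cells of each type whose distance d
#' falls in each interaction bin of `range_spec`. Bins are half-open
#' `[r_{k-1}, r_k)` except the last, which is closed at the outermost
#' breakpoint; a cell at exactly a breakpoint is counted in the outer bin.
#' Cells closer than the hardcore radius are not counted but set the
#' `hardcore` attribute of the result, signalling a forbidden location.
#'
#' @param pattern A `cell_pattern` supplying the cells to count.
#' @param location Numeric length-2 vector `c(x, y)`.
#' @param range_spec A [range_spec()].
#' @param halo Optional tibble of extra cells (columns x, y, type) just
#'   outside the pattern's window, counted alongside the pattern's cells.
#' @param exclude_cell Optional row index of a pattern cell to leave out
#'   (used for the cell's own location).
#' @return An integer matrix with one row per type and one column per
#'   range, with attribute `hardcore`.
#' @examples
#' p <- as_cell_pattern(data.frame(x = c(50, 150, 250), y = 0,
#'                                 type = c("A", "B", "A")),
#'                      window = pattern_window(-10, 400, -10, 10))
#' count_neighbors(p, c(0, 0), range_spec(1, c(100, 200, 300)))
#' @export
count_neighbors <- function(pattern, location, range_spec, halo = NULL,
                            exclude_cell = NULL) {
  pool <- pool_cells(pattern, halo)
  res <- neighbor_counts_raw(location[1], location[2], pool, range_spec,
                             exclude = as.integer(exclude_cell %||% 0L))
  m <- n_ranges(range_spec)
  out <- matrix(res$counts[1, ], nrow = length(pool$type_set), ncol = m,
                dimnames = list(pool$type_set,
                                paste0("r", seq_len(m))))
  attr(out, "hardcore") <- res$hardcore[1]
  out
}

# ---- Berman-Turner quadrature ---------------------------------------------

#' Build a Berman-Turner quadrature scheme
#'
#' Converts the pseudolikelihood integral into a finite weighted sum: dummy
#' marked points are laid out at the centers of a `dummy_grid_n` x
#' `dummy_grid_n` rectangular grid plus the four window corners (each
#' carrying every type), and at every data cell's location dummies of all
#' *other* types are co-located with it. Each quadrature location gets the
#' counting weight `w = (grid cell area) / (number of quadrature locations
#' in that grid cell)`, so weights partition the window area. The response
#' is `1/w` for data points and 0 for dummies.
#'
#' Neighbor-count features at a data cell's location exclude that cell
#' itself, both for the data point and for its co-located other-type
#' dummies (the "replacement" reading of the conditional intensity).
#' Locations with any cell closer than the hardcore radius are flagged
#' `forbidden` and excluded from fitting.
#'
#' @param pattern A `cell_pattern` with at least one cell and every type of
#'   its `type_set` present.
#' @param range_spec A [range_spec()].
#' @param halo Optional halo cells (see [extract_tiles()]): counted as
#'   neighbors but not treated as data.
#' @param dummy_grid_n Dummy/weight grid resolution per side; default
#'   `max(32, ceiling(2 * sqrt(n)))`, i.e. about four dummy locations per
#'   data location — coarser grids bias the pseudolikelihood estimates
#'   noticeably at hardcore radii of a few pixels.
#' @return A `quad_scheme` object.
#' @export
build_quadrature <- function(pattern, range_spec = multistrauss::range_spec(),
                             halo = NULL, dummy_grid_n = NULL) {
  n <- nrow(pattern)
  if (n < 1) stop("pattern must contain at least one cell")
  ts <- type_set(pattern)
  C <- length(ts)
  present <- ts %in% unique(pattern$type)
  if (!all(present))
    stop("type(s) absent from pattern (model unidentifiable): ",
         paste(ts[!present], collapse = ", "))
  w <- pattern_window_of(pattern)
  g <- dummy_grid_n %||% max(32L, ceiling(2 * sqrt(n)))

  cx <- w$x_min + (seq_len(g) - 0.5) / g * (w$x_max - w$x_min)
  cy <- w$y_min + (seq_len(g) - 0.5) / g * (w$y_max - w$y_min)
  gx <- rep(cx, times = g); gy <- rep(cy, each = g)
  corners_x <- c(w$x_min, w$x_max, w$x_min, w$x_max)
  corners_y <- c(w$y_min, w$y_min, w$y_max, w$y_max)

  qx <- c(pattern$x, gx, corners_x)
  qy <- c(pattern$y, gy, corners_y)
  nloc <- length(qx)

  # counting weights on the same grid
  ix <- pmin(pmax(ceiling((qx - w$x_min) / (w$x_max - w$x_min) * g), 1L), g)
  iy <- pmin(pmax(ceiling((qy - w$y_min) / (w$y_max - w$y_min) * g), 1L), g)
  cell <- (iy - 1L) * g + ix
  per_cell <- tabulate(cell, nbins = g * g)
  w_loc <- (window_area(w) / (g * g)) / per_cell[cell]

  if (is.null(range_spec)) {
    # intensity-only scheme: no interaction features, no hardcore
    res <- list(counts = matrix(0L, nloc, 0), hardcore = rep(FALSE, nloc))
  } else {
    pool <- pool_cells(pattern, halo)
    res <- neighbor_counts_raw(qx, qy, pool, range_spec,
                               exclude = c(seq_len(n), integer(nloc - n)))
  }

  is_data_loc <- c(rep(TRUE, n), rep(FALSE, nloc - n))
  true_type <- c(pattern$type, rep(NA_character_, nloc - n))
  points <- tibble(
    loc_id = rep(seq_len(nloc), each = C),
    x = rep(qx, each = C), y = rep(qy, each = C),
    mark = rep(ts, times = nloc)
  )
  points$is_data <- rep(is_data_loc, each = C) &
    !is.na(rep(true_type, each = C)) & points$mark == rep(true_type, each = C)
  points$w <- rep(w_loc, each = C)
  points$response <- ifelse(points$is_data, 1 / points$w, 0)
  points$forbidden <- rep(res$hardcore, each = C)

  structure(
    list(points = points, counts = res$counts,
         type_set = ts, range_spec = range_spec, window = w,
         pattern_id = pattern_id(pattern),
         n_real = n, n_dummy = nloc * C - n,
         dummy_grid_n = g),
    class = "quad_scheme"
  )
}

#' @export
print.quad_scheme <- function(x, ...) {
  cat(sprintf(paste0("quad_scheme '%s': %d real + %d dummy points, ",
                     "%d types, %d range(s), grid %d\n"),
              x$pattern_id %||% "<unnamed>", x$n_real, x$n_dummy,
              length(x$type_set), n_ranges(x$range_spec), x$dummy_grid_n))
  invisible(x)
}

# "delta:<pair>:<bin>" column names; empty when there are no ranges
delta_colnames <- function(pair_labels, m) {
  if (m == 0 || length(pair_labels) == 0) return(character(0))
  as.vector(t(outer(pair_labels, seq_len(m),
                    function(p, k) paste0("delta:", p, ":", k))))
}

# canonical unordered pair table for a type set
pair_table <- function(ts) {
  C <- length(ts)
  idx <- which(upper.tri(matrix(0, C, C), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble(a = idx[, "row"], b = idx[, "col"],
         label = paste(ts[idx[, "row"]], ts[idx[, "col"]], sep = "|"))
}

#' Design matrix of a quadrature scheme
#'
#' One row per quadrature point: type indicator columns (the log base
#' intensities) followed by one pooled symmetric column per unordered type
#' pair and range (the log interaction coefficients). For a point of mark
#' i, the column for pair \{i,j\} at range k holds the count of type-j
#' neighbors in bin k at the point's location; pair columns not involving
#' the point's mark are 0.
#'
#' @param scheme A `quad_scheme`.
#' @return A numeric matrix with attributes `y` (response), `w` (weights)
#'   and `forbidden`.
#' @export
feature_matrix <- function(scheme) {
  ts <- scheme$type_set
  C <- length(ts)
  m <- n_ranges(scheme$range_spec)
  pts <- scheme$points
  N <- nrow(pts)
  mark_i <- match(pts$mark, ts)
  cnt <- scheme$counts[pts$loc_id, , drop = FALSE] # N x (C*m)

  pairs <- pair_table(ts)
  X <- matrix(0, N, C + nrow(pairs) * m)
  colnames(X) <- c(paste0("beta:", ts), delta_colnames(pairs$label, m))
  X[cbind(seq_len(N), mark_i)] <- 1
  col0 <- C
  for (p in seq_len(nrow(pairs))) {
    a <- pairs$a[p]; b <- pairs$b[p]
    for (k in seq_len(m)) {
      v <- numeric(N)
      ia <- mark_i == a
      v[ia] <- cnt[ia, (k - 1L) * C + b]
      if (a != b) {
        ib <- mark_i == b
        v[ib] <- cnt[ib, (k - 1L) * C + a]
      }
      X[, col0 + (p - 1L) * m + k] <- v
    }
  }
  attr(X, "y") <- pts$response
  attr(X, "w") <- pts$w
  attr(X, "forbidden") <- pts$forbidden
  attr(X, "is_data") <- pts$is_data
  X
}

#' @export
as_tibble.quad_scheme <- function(x, ...) {
  X <- feature_matrix(x)
  out <- as_tibble(as.data.frame(X))
  dplyr::bind_cols(
    tibble(pattern_id = x$pattern_id %||% NA_character_,
           response = attr(X, "y"), mark = x$points$mark,
           weight = attr(X, "w"), is_data = x$points$is_data,
           forbidden = attr(X, "forbidden")),
    out[-seq_along(x$type_set)]
  )
}
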