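#' Typed cell point patterns
#'
#' A `cell_pattern` is a tibble of cell centers with columns `x`, `y`
#' (continuous pixel coordinates) and `type` (cell-type label), carrying a
#' rectangular observation window, an ordered set of type labels and an
#' optional pattern id as attributes. It is the realization the point
#' process model is fitted to.
#'
#' Duplicate coordinates are rejected: two cells at the same location
#' violate the hardcore assumption of the model. Pass
#' `jitter_duplicates = TRUE` to break ties with a deterministic sub-pixel
#' offset instead.
#'
#' @param df A data frame with coordinate and type columns.
#' @param window An [pattern_window()]; defaults to the bounding box of the
#'   coordinates.
#' @param pattern_id Optional identifier for the pattern.
#' @param type_set Ordered character vector of type labels; defaults to the
#'   sorted distinct labels present. Types absent from the data may be
#'   listed here.
#' @param x,y,type Column names to read coordinates and labels from.
#' @param jitter_duplicates Resolve duplicated coordinates by a
#'   deterministic 1e-3-pixel spiral offset instead of erroring.
#' @return A `cell_pattern` tibble.
#' @examples
#' df <- data.frame(x = c(10, 20, 30), y = c(5, 15, 25),
#'                  type = c("A", "B", "A"))
#' p <- as_cell_pattern(df, window = pattern_window(0, 100, 0, 100))
#' type_set(p)
#' @export
as_cell_pattern <- function(df, window = NULL, pattern_id = NULL,
                            type_set = NULL, x = "x", y = "y", type = NULL,
                            jitter_duplicates = FALSE) {
  df <- as.data.frame(df)
  if (is.null(type)) {
    type <- if ("type" %in% names(df)) "type" else "cell_type"
  }
  missing_cols <- setdiff(c(x, y, type), names(df))
  if (length(missing_cols))
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "))
  xs <- df[[x]]; ys <- df[[y]]
  for (nm in list(c(x, "x"), c(y, "y"))) {
    v <- df[[nm[1]]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("parse error: non-numeric %s coordinate at row(s) %s",
                     nm[2], paste(head(bad, 5), collapse = ", ")))
      if (nm[2] == "x") xs <- vn else ys <- vn
    }
  }
  if (anyNA(xs) || anyNA(ys)) {
    bad <- which(is.na(xs) | is.na(ys))
    stop("parse error: missing coordinate at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  labels <- as.character(df[[type]])
  if (anyNA(labels)) stop("missing type label(s)")

  dup <- duplicated(cbind(xs, ys))
  if (any(dup)) {
    if (jitter_duplicates) {
      idx <- which(dup)
      k <- seq_along(idx)
      xs[idx] <- xs[idx] + 1e-3 * cos(2.399963 * k) * k
      ys[idx] <- ys[idx] + 1e-3 * sin(2.399963 * k) * k
    } else {
      stop("validation error: duplicate coordinates at row(s) ",
           paste(head(which(dup), 10), collapse = ", "))
    }
  }

  if (is.null(window)) {
    window <- if (length(xs)) bbox_window(xs, ys) else pattern_window(0, 1, 0, 1)
  } else {
    window <- as_ms_window(window)
  }
  inside <- xs >= window$x_min & xs <= window$x_max &
    ys >= window$y_min & ys <= window$y_max
  if (!all(inside))
    stop("validation error: cell(s) outside window at row(s) ",
         paste(head(which(!inside), 5), collapse = ", "))

  ts <- type_set %||% sort(unique(labels))
  if (!all(labels %in% ts))
    stop("type label(s) not in type_set: ",
         paste(setdiff(unique(labels), ts), collapse = ", "))

  new_cell_pattern(tibble(x = xs, y = ys, type = labels), window,
                   as.character(ts), pattern_id)
}

new_cell_pattern <- function(cells, window, type_set, pattern_id = NULL) {
  structure(cells,
            window = window, type_set = type_set, pattern_id = pattern_id,
            class = c("cell_pattern", class(tibble())))
}

#' Pattern accessors
#'
#' @param pattern A `cell_pattern`.
#' @return The window, ordered type labels, or pattern id attached to the
#'   pattern.
#' @export
pattern_window_of <- function(pattern) attr(pattern, "window", exact = TRUE)

#' @rdname pattern_window_of
#' @export
type_set <- function(pattern) attr(pattern, "type_set", exact = TRUE)

#' @rdname pattern_window_of
#' @export
pattern_id <- function(pattern) attr(pattern, "pattern_id", exact = TRUE)

# integer type codes aligned with type_set order
type_codes <- function(pattern, types = type_set(pattern)) {
  match(pattern$type, types)
}

#' @export
print.cell_pattern <- function(x, ...) {
  w <- pattern_window_of(x)
  cat(sprintf("cell_pattern '%s': %d cells, %d type(s) [%s]\n",
              pattern_id(x) %||% "<unnamed>", nrow(x), length(type_set(x)),
              paste(type_set(x), collapse = ", ")))
  print(w)
  NextMethod()
}

#' Read and write cell tables
#'
#' Reads a delimited single-cell table (default comma-separated with
#' columns `x`, `y`, `cell_type`) into a [as_cell_pattern()] object. A JSON
#' sidecar file `<path>.window.json` with fields
#' `x_min/x_max/y_min/y_max/pixel_size_um`, when present, supplies the
#' window; otherwise the coordinate bounding box is used. Multi-image
#' tables carrying an id column can be split with `id`.
#'
#' @param path File path.
#' @param window Optional [pattern_window()] overriding the sidecar.
#' @param col_names Named list mapping `x`, `y`, `type` (and optionally
#'   `id`) to column names in the file.
#' @param delim Field delimiter.
#' @param id Optional id column name; when given, a named list of patterns
#'   (one per distinct id) is returned.
#' @param ... Passed on to [as_cell_pattern()].
#' @return A `cell_pattern`, or a named list of them when `id` is used.
#' @export
read_pattern <- function(path, window = NULL,
                         col_names = list(x = "x", y = "y", type = "cell_type"),
                         delim = ",", id = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(readr::read_delim(path, delim = delim,
                                        show_col_types = FALSE,
                                        progress = FALSE))
  if (is.null(window)) {
    sidecar <- paste0(path, ".window.json")
    if (file.exists(sidecar))
      window <- as_ms_window(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  mk <- function(d, pid) {
    as_cell_pattern(d, window = window, pattern_id = pid,
                    x = col_names$x %||% "x", y = col_names$y %||% "y",
                    type = col_names$type %||% "cell_type", ...)
  }
  if (!is.null(id)) {
    if (!id %in% names(df)) stop("format error: missing id column: ", id)
    split_df <- split(df, df[[id]])
    return(lapply(split_df, function(d) mk(d, as.character(d[[id]][1]))))
  }
  mk(df, sub("\\.[^.]+$", "", basename(path)))
}

#' @rdname read_pattern
#' @param pattern A `cell_pattern` to write.
#' @param write_window Also write the window sidecar JSON.
#' @export
write_pattern <- function(pattern, path, write_window = TRUE) {
  out <- tibble(x = pattern$x, y = pattern$y, cell_type = pattern$type)
  readr::write_csv(out, path)
  if (write_window) {
    w <- pattern_window_of(pattern)
    jsonlite::write_json(w[c("x_min", "x_max", "y_min", "y_max",
                             "pixel_size_um")],
                         paste0(path, ".window.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Randomize cell types in place
#'
#' Permutes the type labels over the fixed cell locations, the unit step of
#' the non-randomness shuffle test: the location pattern and the per-type
#' abundances are preserved exactly, only the assignment of labels to
#' locations is randomized.
#'
#' @param pattern A `cell_pattern` with at least one cell.
#' @param seed Optional integer seed for a reproducible permutation.
#' @return A `cell_pattern` with permuted labels.
#' @export
shuffle_types <- function(pattern, seed = NULL) {
  stopifnot(nrow(pattern) >= 1L)
  perm <- with_seed(seed, sample.int(nrow(pattern)))
  new_cell_pattern(tibble(x = pattern$x, y = pattern$y,
                          type = pattern$type[perm]),
                   pattern_window_of(pattern), type_set(pattern),
                   pattern_id(pattern))
}

#' @export
autoplot.cell_pattern <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type)) +
    ggplot2::geom_point(size = 0.4, ...) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "cell type") +
    ggplot2::theme_minimal()
}
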