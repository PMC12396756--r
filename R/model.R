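# ---- model object ----------------------------------------------------------

# coefficient vector in feature_matrix column order
coef_vector <- function(type_set, log_beta, log_delta) {
  m <- ncol(log_delta)
  pairs <- pair_table(type_set)
  stats::setNames(
    c(log_beta, as.vector(t(log_delta))),
    c(paste0("beta:", type_set), delta_colnames(pairs$label, m))
  )
}

new_mrss <- function(type_set, range_spec, log_beta, log_delta,
                     coef_table = NULL, dispersion = NA_real_, vcov = NULL,
                     fit_info = list()) {
  structure(
    list(type_set = type_set, range_spec = range_spec,
         log_beta = log_beta, log_delta = log_delta,
         coefficients = coef_vector(type_set, log_beta, log_delta),
         coef_table = coef_table, dispersion = dispersion, vcov = vcov,
         fit_info = fit_info),
    class = "mrss")
}

#' Construct a multirange Strauss-hardcore model from known coefficients
#'
#' Builds a model object directly from per-type log base intensities and
#' per-(pair, range) log interaction coefficients, without fitting. Used to
#' specify generating models for simulation and for worked examples.
#' Coefficients are on the log scale: positive log-delta means attraction
#' (delta > 1), negative repulsion.
#'
#' @param type_set Ordered character vector of type labels.
#' @param range_spec A [range_spec()].
#' @param log_beta Per-type log intensities (cells per square pixel), in
#'   `type_set` order or named by type.
#' @param log_delta Either a matrix with one row per unordered type pair
#'   (rows ordered/named `"A|A", "A|B", ..."`) and one column per range, or
#'   a named list like `list("A|B" = c(-2, -0.5))` giving rows of that
#'   matrix (unlisted pairs and ranges default to 0).
#' @return An `mrss` model object.
#' @examples
#' m <- mrss_model(c("A", "B", "C"), range_spec(1, 100),
#'                 log_beta = log(c(1, 1, 1)),
#'                 log_delta = list("A|B" = log(0.1), "B|C" = log(20)))
#' @export
mrss_model <- function(type_set, range_spec, log_beta, log_delta = NULL) {
  type_set <- as.character(type_set)
  C <- length(type_set)
  m <- n_ranges(range_spec)
  pairs <- pair_table(type_set)
  if (!is.null(names(log_beta))) log_beta <- log_beta[type_set]
  stopifnot(length(log_beta) == C, all(is.finite(log_beta)))
  log_beta <- stats::setNames(as.numeric(log_beta), type_set)

  D <- matrix(0, nrow(pairs), m, dimnames = list(pairs$label,
                                                 paste0("r", seq_len(m))))
  if (is.matrix(log_delta)) {
    stopifnot(nrow(log_delta) == nrow(pairs), ncol(log_delta) == m)
    if (!is.null(rownames(log_delta))) {
      key <- normalize_pair_labels(rownames(log_delta), type_set)
      D[key, ] <- log_delta
    } else D[, ] <- log_delta
  } else if (is.list(log_delta)) {
    for (nm in names(log_delta)) {
      key <- normalize_pair_labels(nm, type_set)
      v <- log_delta[[nm]]
      stopifnot(length(v) <= m)
      D[key, seq_along(v)] <- v
    }
  } else if (!is.null(log_delta)) {
    stop("log_delta must be a matrix or a named list")
  }
  if (!all(is.finite(D))) stop("log_delta must be finite")
  new_mrss(type_set, range_spec, log_beta, D,
           fit_info = list(source = "constructed"))
}

# "B|A" -> "A|B" etc., validating the type names
normalize_pair_labels <- function(labels, type_set) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2 || !all(p %in% type_set))
      stop("unknown type pair label: ", paste(p, collapse = "|"))
    i <- sort(match(p, type_set))
    paste(type_set[i[1]], type_set[i[2]], sep = "|")
  }, character(1))
}

#' @export
print.mrss <- function(x, ...) {
  cat(sprintf("mrss model: %d types [%s], %d range(s), hardcore %g px\n",
              length(x$type_set), paste(x$type_set, collapse = ", "),
              n_ranges(x$range_spec), x$range_spec$hardcore %||% 0))
  cat(sprintf("  log base intensities: %s\n",
              paste(sprintf("%s=%.3g", x$type_set, x$log_beta),
                    collapse = ", ")))
  if (!is.null(x$fit_info$converged))
    cat(sprintf("  fit: %d real + %d dummy points, converged: %s, dispersion %.3g\n",
                x$fit_info$n_real, x$fit_info$n_dummy,
                x$fit_info$converged, x$dispersion))
  invisible(x)
}

# ---- interaction function and conditional intensity ------------------------

#' Pairwise interaction multiplier at a distance
#'
#' Evaluates the piecewise-constant interaction function for a type pair:
#' 0 below the hardcore radius, `exp(log_delta)` of the bin containing d
#' within the ranges, and 1 beyond the outermost breakpoint.
#'
#' @param model An `mrss` model.
#' @param type_a,type_b Type labels of the pair (order irrelevant).
#' @param d Distances in pixels (vectorized).
#' @return Nonnegative multipliers, same length as `d`.
#' @export
interaction_value <- function(model, type_a, type_b, d) {
  lab <- normalize_pair_labels(paste(type_a, type_b, sep = "|"), model$type_set)
  stopifnot(all(d >= 0))
  rs <- model$range_spec
  br <- rs$breakpoints
  out <- numeric(length(d))
  out[d < rs$hardcore] <- 0
  out[d > r_max(rs)] <- 1
  mid <- d >= rs$hardcore & d <= r_max(rs)
  if (any(mid)) {
    k <- findInterval(d[mid], br, left.open = FALSE) + 1L
    k[d[mid] == r_max(rs)] <- length(br) # closed last bin
    out[mid] <- exp(model$log_delta[lab, k])
  }
  out
}

# C x m matrix of log-deltas seen from one focal type
delta_rows_for_type <- function(model, type) {
  ts <- model$type_set
  labs <- normalize_pair_labels(paste(type, ts, sep = "|"), ts)
  model$log_delta[labs, , drop = FALSE]
}

#' Conditional intensity of a type at a location
#'
#' Evaluates `lambda = exp(log_beta[type] + sum_jk counts[j,k] *
#' log_delta[{type,j},k])` from a neighbor-count matrix as returned by
#' [count_neighbors()]. A hardcore violation forces `lambda = 0`.
#'
#' @param model An `mrss` model.
#' @param counts Type-by-range neighbor count matrix (rows in `type_set`
#'   order, as from [count_neighbors()]).
#' @param type The focal type label.
#' @param hardcore Logical; when `TRUE` (or when `counts` carries a
#'   `hardcore` attribute that is `TRUE`) the location is forbidden.
#' @return A nonnegative intensity (cells per square pixel).
#' @export
conditional_intensity <- function(model, counts, type,
                                  hardcore = isTRUE(attr(counts, "hardcore"))) {
  if (hardcore) return(0)
  stopifnot(type %in% model$type_set)
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(model$type_set),
            ncol(counts) == n_ranges(model$range_spec))
  exp(model$log_beta[[type]] + sum(counts * delta_rows_for_type(model, type)))
}

#' Predicted type probabilities at a location
#'
#' Normalizes the conditional intensities of all types at a location into a
#' probability vector: `P(c) = lambda(c) / sum_c' lambda(c')`.
#'
#' @inheritParams conditional_intensity
#' @return A named probability vector over `type_set`, summing to 1.
#' @export
predict_type_probs <- function(model, counts,
                               hardcore = isTRUE(attr(counts, "hardcore"))) {
  if (hardcore)
    stop("all conditional intensities are zero (hardcore violation)")
  lam <- vapply(model$type_set, function(tt)
    conditional_intensity(model, counts, tt, hardcore = FALSE), numeric(1))
  if (!any(lam > 0)) stop("all conditional intensities are zero")
  lam / sum(lam)
}

#' Per-cell type prediction for a whole pattern
#'
#' Computes each cell's neighbor counts (excluding the cell itself),
#' conditional intensities and normalized type probabilities under a
#' model, the basis of the self-prediction AUC evaluation.
#'
#' @param object An `mrss` model.
#' @param pattern A `cell_pattern` with the model's `type_set`.
#' @param halo Optional halo cells.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `type`, one `prob_<type>` column
#'   per type and `pred` (the most probable type).
#' @export
predict.mrss <- function(object, pattern, halo = NULL, ...) {
  ts <- object$type_set
  stopifnot(identical(sort(ts), sort(type_set(pattern))))
  C <- length(ts)
  m <- n_ranges(object$range_spec)
  pool <- pool_cells(pattern, halo)
  # align pool type codes with the model's type order
  pool$type <- match(type_set(pattern)[pool$type], ts)
  pool$type_set <- ts
  res <- neighbor_counts_raw(pattern$x, pattern$y, pool, object$range_spec,
                             exclude = seq_len(nrow(pattern)))
  cnt <- res$counts # n x (C*m), bin-major type-fastest
  eta <- vapply(ts, function(tt) {
    D <- delta_rows_for_type(object, tt) # C x m
    drop(cnt %*% as.vector(D)) + object$log_beta[[tt]]
  }, numeric(nrow(pattern)))
  lam <- exp(eta)
  if (any(res$hardcore)) {
    warning(sum(res$hardcore), " cell(s) violate the hardcore radius; ",
            "their probabilities are NA")
    lam[res$hardcore, ] <- NA_real_
  }
  probs <- lam / rowSums(lam)
  colnames(probs) <- paste0("prob_", ts)
  out <- tibble(x = pattern$x, y = pattern$y, type = pattern$type)
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(probs)))
  out$pred <- ts[max.col(replace(probs, is.na(probs), -Inf))]
  out$pred[res$hardcore] <- NA_character_
  out
}

# ---- deviance --------------------------------------------------------------

#' Deviance of a model on a pattern's quadrature
#'
#' Twice the pseudolikelihood gap to the saturated fit,
#' `D = 2 sum_i w_i (y_i log(y_i / mu_i) - (y_i - mu_i))` with the
#' convention `y log y = 0` at `y = 0`, evaluated over the real and dummy
#' points of a Berman-Turner scheme, and normalized per point for the
#' `all`, `real` and `dummy` subsets. Forbidden locations have `mu = 0`;
#' a forbidden *real* cell makes the deviance infinite, which is reported
#' explicitly.
#'
#' @param model An `mrss` model.
#' @param pattern A `cell_pattern` (ignored when `scheme` is given).
#' @param scheme Optional pre-built [build_quadrature()] scheme.
#' @param halo,dummy_grid_n Passed to [build_quadrature()].
#' @return An `mrss_deviance` object with the total deviance, per-cell
#'   averages for all/real/dummy subsets, subset sizes and their log10
#'   convenience values.
#' @export
deviance_report <- function(model, pattern = NULL, scheme = NULL,
                            halo = NULL, dummy_grid_n = NULL) {
  if (is.null(scheme)) {
    stopifnot(!is.null(pattern))
    scheme <- build_quadrature(pattern, model$range_spec, halo = halo,
                               dummy_grid_n = dummy_grid_n)
  }
  stopifnot(identical(scheme$type_set, model$type_set),
            identical(scheme$range_spec$breakpoints %||% numeric(0),
                      model$range_spec$breakpoints %||% numeric(0)))
  X <- feature_matrix(scheme)
  deviance_from_matrix(model$coefficients, X)
}

# shared with the shuffle test, which evaluates many models on pre-built
# feature matrices
deviance_from_matrix <- function(coefs, X) {
  stopifnot(identical(names(coefs), colnames(X)))
  y <- attr(X, "y"); w <- attr(X, "w")
  forb <- attr(X, "forbidden"); is_data <- attr(X, "is_data")
  mu <- exp(drop(X %*% coefs))
  mu[forb] <- 0
  d <- ifelse(y > 0,
              2 * w * (y * log(y / mu) - (y - mu)),
              2 * w * mu)
  inf_real <- sum(is_data & forb)
  if (inf_real > 0) d[is_data & forb] <- Inf
  D_real <- sum(d[is_data]); D_dummy <- sum(d[!is_data])
  n_real <- sum(is_data); n_dummy <- sum(!is_data)
  structure(
    list(total = D_real + D_dummy,
         avg_all = (D_real + D_dummy) / (n_real + n_dummy),
         avg_real = D_real / n_real,
         avg_dummy = D_dummy / n_dummy,
         n_real = n_real, n_dummy = n_dummy,
         n_infinite_real = inf_real),
    class = "mrss_deviance")
}

#' @export
print.mrss_deviance <- function(x, ...) {
  cat(sprintf(paste0("deviance: total %.6g; per cell: all %.6g, ",
                     "real %.6g, dummy %.6g (n = %d + %d)\n"),
              x$total, x$avg_all, x$avg_real, x$avg_dummy,
              x$n_real, x$n_dummy))
  if (x$n_infinite_real > 0)
    cat(sprintf("  %d real cell(s) forbidden -> infinite deviance\n",
                x$n_infinite_real))
  invisible(x)
}

#' @export
tidy.mrss_deviance <- function(x, ...) {
  tibble(total = x$total, avg_all = x$avg_all, avg_real = x$avg_real,
         avg_dummy = x$avg_dummy, n_real = x$n_real, n_dummy = x$n_dummy,
         log10_avg_all = log10(x$avg_all), log10_avg_real = log10(x$avg_real),
         log10_avg_dummy = log10(x$avg_dummy),
         n_infinite_real = x$n_infinite_real)
}
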