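#' Fit a multirange multitype Strauss-hardcore model
#'
#' Maximum pseudolikelihood estimation through the Berman-Turner device:
#' each pattern is converted to a quadrature scheme
#' ([build_quadrature()]) and the pooled points are fitted with a weighted
#' quasi-likelihood GLM (log link, variance proportional to the mean) whose
#' predictors are the type indicators (log base intensities) and the pooled
#' symmetric pair-range neighbor counts (log interaction coefficients).
#' Forbidden (hardcore-violating) points are excluded. 95% intervals are
#' Wald intervals using the Pearson-dispersion-scaled covariance.
#'
#' Multiple patterns are concatenated with per-pattern features, i.e. one
#' shared coefficient vector fitted to all of them. Pair-range columns that
#' are identically zero (a pair never observed in a range) are dropped from
#' the fit and reported with coefficient 0 and NA intervals.
#'
#' @param patterns A `cell_pattern` or a list of them. All patterns must
#'   share a type set and every type must be present in each pattern.
#' @param range_spec A [range_spec()].
#' @param halos Optional halo tibble (single pattern) or list of halos.
#' @param dummy_grid_n Dummy grid resolution, see [build_quadrature()].
#' @param caseweight Optional per-pattern positive weight multiplying the
#'   quadrature weights of that pattern.
#' @param max_iter,epsilon IRLS iteration cap and relative convergence
#'   tolerance.
#' @param coef_cap Log-scale magnitude above which a coefficient is treated
#'   as training divergence (error).
#' @return An `mrss` model; see [mrss_model()] for the coefficient layout.
#'   `tidy()` returns the coefficient table, `glance()` the fit summary.
#' @examples
#' \donttest{
#' p <- synth_csr_pattern(window = pattern_window(0, 600, 0, 600),
#'                        intensity = c(A = 2e-3, B = 2e-3), seed = 1)
#' fit <- fit_mrss(p, range_spec(1, c(50, 100)))
#' tidy(fit)
#' }
#' @export
fit_mrss <- function(patterns, range_spec = multistrauss::range_spec(),
                     halos = NULL, dummy_grid_n = NULL, caseweight = NULL,
                     max_iter = 100, epsilon = 1e-8, coef_cap = 50) {
  if (inherits(patterns, "cell_pattern")) {
    patterns <- list(patterns)
    if (!is.null(halos) && !is.list(halos)) halos <- list(halos)
    if (is.data.frame(halos)) halos <- list(halos)
  }
  np <- length(patterns)
  stopifnot(np >= 1)
  ts <- type_set(patterns[[1]])
  for (p in patterns) {
    if (!identical(type_set(p), ts))
      stop("all patterns must share the same type_set")
  }
  caseweight <- caseweight %||% rep(1, np)
  stopifnot(length(caseweight) == np, all(caseweight > 0))

  schemes <- lapply(seq_len(np), function(i)
    build_quadrature(patterns[[i]], range_spec,
                     halo = if (!is.null(halos)) halos[[i]] else NULL,
                     dummy_grid_n = dummy_grid_n))
  mats <- lapply(schemes, feature_matrix)
  X <- do.call(rbind, mats)
  y <- unlist(lapply(mats, attr, "y"), use.names = FALSE)
  w <- unlist(lapply(seq_len(np), function(i)
    attr(mats[[i]], "w") * caseweight[i]), use.names = FALSE)
  forb <- unlist(lapply(mats, attr, "forbidden"), use.names = FALSE)
  is_data <- unlist(lapply(mats, attr, "is_data"), use.names = FALSE)

  keep <- !forb
  Xk <- X[keep, , drop = FALSE]
  nonzero <- colSums(abs(Xk)) > 0
  fit <- suppressWarnings(
    glm.fit(Xk[, nonzero, drop = FALSE], y[keep], weights = w[keep],
            family = quasi(link = "log", variance = "mu"),
            control = glm.control(epsilon = epsilon, maxit = max_iter))
  )
  cf <- fit$coefficients
  if (anyNA(cf) || any(!is.finite(cf)))
    stop("fit error: non-finite coefficients (training divergence); ",
         "consider coarser ranges or pooling patterns")
  if (any(abs(cf) > coef_cap))
    stop(sprintf(paste0("fit error: training divergence (|coefficient| > %g ",
                        "on the log scale for %s)"),
                 coef_cap, paste(names(cf)[abs(cf) > coef_cap], collapse = ", ")))
  if (!fit$converged)
    warning("IRLS did not converge in ", max_iter, " iterations")

  # dispersion-scaled Wald covariance, as summary.glm computes it
  p_rank <- fit$rank
  mu <- fit$fitted.values
  pearson <- sum(w[keep] * (y[keep] - mu)^2 / mu)
  df_res <- sum(keep) - p_rank
  dispersion <- pearson / df_res
  Qr <- fit$qr
  cov_unscaled <- matrix(NA_real_, sum(nonzero), sum(nonzero))
  piv <- Qr$pivot[seq_len(p_rank)]
  cov_unscaled[piv, piv] <- chol2inv(Qr$qr[seq_len(p_rank), seq_len(p_rank),
                                           drop = FALSE])
  se_nz <- sqrt(pmax(diag(cov_unscaled), 0) * dispersion)

  est <- stats::setNames(numeric(ncol(X)), colnames(X))
  se <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  est[names(cf)] <- cf
  se[names(cf)] <- se_nz
  z <- qnorm(0.975)
  ci_low <- est - z * se
  ci_high <- est + z * se

  C <- length(ts)
  m <- n_ranges(range_spec)
  pairs <- pair_table(ts)
  log_beta <- stats::setNames(est[seq_len(C)], ts)
  log_delta <- matrix(est[-seq_len(C)], nrow(pairs), m, byrow = TRUE,
                      dimnames = list(pairs$label,
                                      if (m > 0) paste0("r", seq_len(m))))

  coef_table <- tibble(
    term = colnames(X),
    kind = rep(c("beta", "delta"), c(C, nrow(pairs) * m)),
    type_a = c(ts, rep(ts[pairs$a], each = m)),
    type_b = c(rep(NA_character_, C), rep(ts[pairs$b], each = m)),
    bin = c(rep(NA_integer_, C), rep(seq_len(m), nrow(pairs))),
    estimate = unname(est), std_error = unname(se),
    ci_low = unname(ci_low), ci_high = unname(ci_high)
  )

  vc <- matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X),
                                                           colnames(X)))
  vc[names(cf), names(cf)] <- cov_unscaled * dispersion

  new_mrss(ts, range_spec, log_beta, log_delta, coef_table = coef_table,
           dispersion = dispersion, vcov = vc,
           fit_info = list(
             source = "fit", iterations = fit$iter,
             converged = fit$converged,
             n_real = sum(is_data), n_dummy = sum(!is_data),
             n_forbidden = sum(forb), n_patterns = np,
             dummy_grid_n = schemes[[1]]$dummy_grid_n,
             df_residual = df_res,
             dropped_terms = colnames(X)[!nonzero],
             deviance = fit$deviance))
}

#' @export
tidy.mrss <- function(x, ...) {
  if (!is.null(x$coef_table)) return(x$coef_table)
  C <- length(x$type_set)
  m <- n_ranges(x$range_spec)
  pairs <- pair_table(x$type_set)
  tibble(term = names(x$coefficients),
         kind = rep(c("beta", "delta"), c(C, nrow(pairs) * m)),
         type_a = c(x$type_set, rep(x$type_set[pairs$a], each = m)),
         type_b = c(rep(NA_character_, C), rep(x$type_set[pairs$b], each = m)),
         bin = c(rep(NA_integer_, C), rep(seq_len(m), nrow(pairs))),
         estimate = unname(x$coefficients),
         std_error = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
}

#' @export
glance.mrss <- function(x, ...) {
  fi <- x$fit_info
  tibble(n_types = length(x$type_set), n_ranges = n_ranges(x$range_spec),
         n_real = fi$n_real %||% NA_integer_,
         n_dummy = fi$n_dummy %||% NA_integer_,
         n_forbidden = fi$n_forbidden %||% NA_integer_,
         dispersion = x$dispersion,
         converged = fi$converged %||% NA,
         iterations = fi$iterations %||% NA_integer_)
}

#' Leave-one-out cross-validation over patterns
#'
#' Sequentially holds out one pattern, fits the model to the rest and
#' evaluates the average deviance per cell on the held-out pattern's own
#' quadrature.
#'
#' @param patterns List of at least two `cell_pattern`s with a shared type
#'   set.
#' @param range_spec A [range_spec()].
#' @param dummy_grid_n Quadrature resolution used both for fitting and for
#'   the held-out evaluation (average deviance per cell depends on the
#'   quadrature, so one resolution is used throughout).
#' @param ... Passed to [fit_mrss()].
#' @return A tibble with one row per held-out pattern: its id, the fitted
#'   model (list-column) and the deviance summary columns.
#' @export
loo_cross_validate <- function(patterns, range_spec = multistrauss::range_spec(),
                               dummy_grid_n = NULL, ...) {
  stopifnot(length(patterns) >= 2)
  ids <- vapply(seq_along(patterns), function(i)
    pattern_id(patterns[[i]]) %||% as.character(i), character(1))
  rows <- lapply(seq_along(patterns), function(i) {
    model <- tryCatch(fit_mrss(patterns[-i], range_spec,
                               dummy_grid_n = dummy_grid_n, ...),
                      error = function(e)
                        stop("fit failed with pattern '", ids[i],
                             "' held out: ", conditionMessage(e)))
    dev <- deviance_report(model, patterns[[i]], dummy_grid_n = dummy_grid_n)
    dplyr::bind_cols(tibble(held_out_id = ids[i], model = list(model)),
                     tidy(dev))
  })
  dplyr::bind_rows(rows)
}
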