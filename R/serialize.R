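#' Save and load fitted models as JSON
#'
#' The JSON carries the type set, range specification, the coefficient
#' table (estimate and 95% interval per named term `beta:TYPE` /
#' `delta:T1|T2:bin`), the dispersion and the fit metadata, so a model can
#' be archived and reloaded without refitting.
#'
#' @param model An `mrss` model.
#' @param path Output path.
#' @return `write_model()` the path invisibly; `read_model()` the model.
#' @export
write_model <- function(model, path) {
  tab <- tidy(model)
  obj <- list(
    type_set = model$type_set,
    range_spec = list(hardcore = model$range_spec$hardcore,
                      breakpoints = model$range_spec$breakpoints),
    coefficients = tab[c("term", "estimate", "ci_low", "ci_high")],
    dispersion = model$dispersion,
    fit_info = model$fit_info[setdiff(names(model$fit_info), "trace")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rs <- range_spec(obj$range_spec$hardcore, obj$range_spec$breakpoints)
  ts <- obj$type_set
  cf <- obj$coefficients
  est <- stats::setNames(cf$estimate, cf$term)
  C <- length(ts)
  m <- n_ranges(rs)
  pairs <- pair_table(ts)
  log_beta <- stats::setNames(est[paste0("beta:", ts)], ts)
  log_delta <- matrix(0, nrow(pairs), m,
                      dimnames = list(pairs$label, paste0("r", seq_len(m))))
  for (p in seq_len(nrow(pairs)))
    for (k in seq_len(m))
      log_delta[p, k] <- est[[paste0("delta:", pairs$label[p], ":", k)]]
  mdl <- new_mrss(ts, rs, log_beta, log_delta,
                  dispersion = obj$dispersion %||% NA_real_,
                  fit_info = as.list(obj$fit_info))
  ct <- tidy(mdl)
  ct$ci_low <- cf$ci_low[match(ct$term, cf$term)]
  ct$ci_high <- cf$ci_high[match(ct$term, cf$term)]
  mdl$coef_table <- ct
  mdl
}

#' Export the coefficient table as CSV
#'
#' @param model An `mrss` model.
#' @param path Output path.
#' @export
write_coefficients_csv <- function(model, path) {
  readr::write_csv(tidy(model), path)
  invisible(path)
}
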