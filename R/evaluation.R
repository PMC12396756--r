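# ---- multiclass AUC --------------------------------------------------------

# one-vs-rest ROC AUC with the trapezoidal mid-rank tie convention
# (equivalent to the normalized Mann-Whitney U statistic)
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass one-vs-rest AUC report
#'
#' Per-class one-vs-rest ROC AUCs plus three aggregates: micro (all
#' indicator/score pairs pooled), macro (unweighted mean over classes) and
#' weighted macro (mean weighted by class frequency, the headline accuracy
#' metric for cell-type prediction). Ties in scores are handled by the
#' mid-rank convention. Classes with no positive cases have undefined AUC
#' and are excluded from the means with a warning.
#'
#' @param truth Character/factor vector of true class labels.
#' @param probs Numeric matrix or data frame of class scores, one column
#'   per class; column names (optionally prefixed `"prob_"`) identify the
#'   classes.
#' @return An `auc_report` with elements `micro`, `macro`,
#'   `weighted_macro`, `per_class` (tibble of class AUCs and frequencies).
#' @export
multiclass_auc <- function(truth, probs) {
  probs <- as.matrix(probs)
  colnames(probs) <- sub("^prob_", "", colnames(probs))
  stopifnot(nrow(probs) == length(truth))
  truth <- as.character(truth)
  classes <- colnames(probs)
  if (length(unique(truth)) < 2) stop("need at least 2 classes present")
  stopifnot(all(truth %in% classes))
  keep <- stats::complete.cases(probs)
  truth <- truth[keep]; probs <- probs[keep, , drop = FALSE]

  per <- tibble(
    class = classes,
    n = unname(vapply(classes, function(cl) sum(truth == cl), numeric(1))),
    auc = unname(vapply(classes, function(cl)
      auc_rank(probs[, cl], truth == cl), numeric(1)))
  )
  per$freq <- per$n / sum(per$n)
  if (anyNA(per$auc))
    warning("class(es) without positives excluded from macro means: ",
            paste(per$class[is.na(per$auc)], collapse = ", "))
  ok <- !is.na(per$auc)
  onehot <- outer(truth, classes, "==")
  micro <- auc_rank(as.vector(probs), as.vector(onehot))
  structure(
    list(micro = micro,
         macro = mean(per$auc[ok]),
         weighted_macro = sum(per$freq[ok] * per$auc[ok]) / sum(per$freq[ok]),
         per_class = per),
    class = "auc_report")
}

#' @export
print.auc_report <- function(x, ...) {
  cat(sprintf("AUC: micro %.4f, macro %.4f, weighted macro %.4f\n",
              x$micro, x$macro, x$weighted_macro))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.auc_report <- function(x, ...) x$per_class

#' @export
glance.auc_report <- function(x, ...) {
  tibble(micro = x$micro, macro = x$macro, weighted_macro = x$weighted_macro)
}

#' Self-prediction weighted macro AUC of a model on a pattern
#'
#' Convenience wrapper: predict per-cell type probabilities with the model
#' and score them against the true types.
#'
#' @param model An `mrss` model.
#' @param pattern A `cell_pattern`.
#' @param halo Optional halo cells.
#' @return An `auc_report`.
#' @export
prediction_auc <- function(model, pattern, halo = NULL) {
  pred <- predict(model, pattern, halo = halo)
  multiclass_auc(pred$type,
                 pred[grep("^prob_", names(pred))])
}

# ---- shuffle randomization test -------------------------------------------

#' Type-shuffle test of non-randomness
#'
#' Tests the null hypothesis that cell types are randomly assigned to the
#' observed locations. For each of `n_shuffles` type permutations a model
#' is fitted to the shuffled pattern and its average deviance per cell is
#' evaluated both on a *different* random shuffle and on the original
#' pattern. Under spatial type structure the shuffled models describe other
#' shuffles far better than the original, and the empirical p-value
#' `max(#\{dev_on_original <= dev_on_shuffle\}, 1) / n_shuffles`
#' reaches its floor `1/n_shuffles`.
#'
#' The default model is the single-range setting of the published
#' protocol: one Strauss radius of 100 px and hardcore radius 1 px.
#' Because all shuffles share the cell locations, the quadrature geometry
#' and weights are computed once and only the type-dependent features are
#' rebuilt per shuffle.
#'
#' @param pattern A `cell_pattern`.
#' @param n_shuffles Number of shuffled replicates.
#' @param range_spec A [range_spec()]; default single 100-px range.
#' @param seed Optional seed.
#' @param subset Which deviance average to compare: `"all"`, `"real"` or
#'   `"dummy"` cells.
#' @param p_rule `"floor"` (default) reports `max(x, 1)/S`; `"add_one"`
#'   reports `(1 + x)/(1 + S)`.
#' @param dummy_grid_n Passed to [build_quadrature()].
#' @return A `shuffle_test` object: per-shuffle deviances, the empirical
#'   p-value, log-scale summaries and the ids of dropped (divergent)
#'   replicates.
#' @export
shuffle_test <- function(pattern, n_shuffles = 100,
                         range_spec = multistrauss::range_spec(
                           hardcore = 1, breakpoints = 100),
                         seed = NULL, subset = c("all", "real", "dummy"),
                         p_rule = c("floor", "add_one"),
                         dummy_grid_n = NULL) {
  subset <- match.arg(subset)
  p_rule <- match.arg(p_rule)
  stopifnot(n_shuffles >= 2)
  avg_of <- function(dev) switch(subset, all = dev$avg_all,
                                 real = dev$avg_real, dummy = dev$avg_dummy)
  with_seed(seed, {
    # features of the original pattern (fixed geometry)
    scheme0 <- build_quadrature(pattern, range_spec,
                                dummy_grid_n = dummy_grid_n)
    X0 <- feature_matrix(scheme0)
    shuffles <- lapply(seq_len(n_shuffles), function(s) shuffle_types(pattern))
    Xs <- lapply(shuffles, function(p) {
      sc <- build_quadrature(p, range_spec, dummy_grid_n = dummy_grid_n)
      feature_matrix(sc)
    })
    partner <- vapply(seq_len(n_shuffles), function(s) {
      r <- sample.int(n_shuffles - 1L, 1L)
      if (r >= s) r + 1L else r
    }, integer(1))

    dev_shuf <- dev_orig <- rep(NA_real_, n_shuffles)
    dropped <- integer(0)
    for (s in seq_len(n_shuffles)) {
      model <- tryCatch(
        fit_mrss(shuffles[[s]], range_spec, dummy_grid_n = dummy_grid_n),
        error = function(e) NULL)
      if (is.null(model)) { dropped <- c(dropped, s); next }
      dev_shuf[s] <- avg_of(deviance_from_matrix(model$coefficients,
                                                 Xs[[partner[s]]]))
      dev_orig[s] <- avg_of(deviance_from_matrix(model$coefficients, X0))
    }
  })
  ok <- !is.na(dev_shuf)
  S <- sum(ok)
  if (S == 0) stop("all shuffle replicates failed to fit")
  x <- sum(dev_orig[ok] <= dev_shuf[ok])
  p <- switch(p_rule,
              floor = max(x, 1) / S,
              add_one = (1 + x) / (1 + S))
  structure(
    list(n_shuffles = n_shuffles,
         replicates = tibble(shuffle = seq_len(n_shuffles),
                             partner = partner,
                             dev_on_shuffle = dev_shuf,
                             dev_on_original = dev_orig),
         empirical_p = p, p_rule = p_rule, subset = subset,
         dropped = dropped,
         log_mean_shuffle = mean(log(dev_shuf[ok])),
         log_sd_shuffle = sd(log(dev_shuf[ok])),
         log_mean_original = mean(log(dev_orig[ok])),
         log_sd_original = sd(log(dev_orig[ok])),
         log10_mean_shuffle = mean(log10(dev_shuf[ok])),
         log10_mean_original = mean(log10(dev_orig[ok]))),
    class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf(paste0("shuffle test (%d shuffles, %s cells): empirical p = %g\n",
                     "  log avg deviance/cell: on shuffles %.3f (sd %.3f), ",
                     "on original %.3f (sd %.3f)\n"),
              x$n_shuffles, x$subset, x$empirical_p,
              x$log_mean_shuffle, x$log_sd_shuffle,
              x$log_mean_original, x$log_sd_original))
  if (length(x$dropped))
    cat("  dropped replicates (fit divergence): ",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.shuffle_test <- function(x, ...) x$replicates

#' @export
glance.shuffle_test <- function(x, ...) {
  tibble(n_shuffles = x$n_shuffles, n_dropped = length(x$dropped),
         empirical_p = x$empirical_p,
         log_mean_shuffle = x$log_mean_shuffle,
         log_sd_shuffle = x$log_sd_shuffle,
         log_mean_original = x$log_mean_original,
         log_sd_original = x$log_sd_original)
}

# ---- Gaussian kernel similarity and MMD ------------------------------------

#' Gaussian kernel similarity between two vectors
#'
#' `exp(-||a - b||^2 / two_sigma_sq)`; the default bandwidth `2 sigma^2 =
#' 0.08` is the one used throughout the modeling workflow.
#'
#' @param vec_a,vec_b Equal-length numeric vectors.
#' @param two_sigma_sq Kernel bandwidth (`2 sigma^2`).
#' @return A similarity in (0, 1].
#' @export
kernel_similarity <- function(vec_a, vec_b, two_sigma_sq = 0.08) {
  if (length(vec_a) != length(vec_b)) stop("length mismatch")
  exp(-sum((vec_a - vec_b)^2) / two_sigma_sq)
}

#' Gaussian-kernel two-sample statistic
#'
#' The three-term kernel discrepancy
#' `T = 1/m^2 sum K(Xi,Xj) - 2/(mn) sum K(Xi,Yj) + 1/n^2 sum K(Yi,Yj)`
#' with diagonal terms included (the biased V-statistic form). Lower T
#' means more similar samples; T = 0 when the samples coincide.
#'
#' @param sample_x,sample_y Numeric matrices (rows = observations) or
#'   vectors.
#' @param two_sigma_sq Kernel bandwidth.
#' @return A nonnegative scalar.
#' @export
mmd_statistic <- function(sample_x, sample_y, two_sigma_sq = 0.08) {
  X <- as.matrix(sample_x); Y <- as.matrix(sample_y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty sample")
  if (ncol(X) != ncol(Y)) stop("dimension mismatch")
  gram <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / two_sigma_sq)
  }
  mean(gram(X, X)) - 2 * mean(gram(X, Y)) + mean(gram(Y, Y))
}

#' Mean kernel similarity between two sets of fitted models
#'
#' Pairwise Gaussian kernel similarity between the concatenated log
#' interaction coefficient vectors of every model in set A against every
#' model in set B, plus the mean over all pairs — the tissue-to-tissue
#' similarity measure.
#'
#' @param models_a,models_b Lists of `mrss` models sharing type set and
#'   ranges.
#' @param two_sigma_sq Kernel bandwidth.
#' @return A list with `mean` and the `matrix` of pairwise similarities.
#' @export
cross_model_similarity <- function(models_a, models_b, two_sigma_sq = 0.08) {
  if (inherits(models_a, "mrss")) models_a <- list(models_a)
  if (inherits(models_b, "mrss")) models_b <- list(models_b)
  va <- lapply(models_a, delta_vector)
  vb <- lapply(models_b, delta_vector)
  lens <- unique(vapply(c(va, vb), length, integer(1)))
  nms <- unique(lapply(c(va, vb), names))
  if (length(lens) != 1 || length(nms) != 1)
    stop("incompatible coefficient layouts across models")
  M <- outer(seq_along(va), seq_along(vb),
             Vectorize(function(i, j)
               kernel_similarity(va[[i]], vb[[j]], two_sigma_sq)))
  list(mean = mean(M), matrix = M)
}

# concatenated log interaction coefficients of a model
delta_vector <- function(model) {
  v <- as.vector(t(model$log_delta))
  names(v) <- names(model$coefficients)[-seq_along(model$type_set)]
  v
}

# ---- heterogeneity ---------------------------------------------------------

#' Tile-model heterogeneity analysis
#'
#' Stacks the interaction-coefficient vectors of models fitted to tiles
#' into a matrix, extracts the two major modes of variation by PCA
#' (centered, unscaled by default), projects the global model with the
#' fitted transform, and computes the heterogeneity metric: the median
#' Euclidean distance, in the full coefficient space, between each tile
#' model's coefficients and the global model's.
#'
#' @param tile_models List of at least 3 `mrss` models (tiles).
#' @param global_model The `mrss` model fitted to the full data.
#' @param scale. Scale coefficients to unit variance before PCA.
#' @return A `heterogeneity` object: `scores` (tibble of PC1/PC2 per tile
#'   plus the projected global model) and `metric`.
#' @export
heterogeneity_analysis <- function(tile_models, global_model, scale. = FALSE) {
  stopifnot(length(tile_models) >= 3)
  V <- do.call(rbind, lapply(tile_models, delta_vector))
  g <- delta_vector(global_model)
  stopifnot(ncol(V) == length(g), identical(colnames(V), names(g)))
  use <- rep(TRUE, ncol(V))
  # constant columns carry no variation and would break unit scaling
  if (scale.) use <- apply(V, 2, function(col) diff(range(col)) > 0)
  pca <- prcomp(V[, use, drop = FALSE], center = TRUE, scale. = scale.)
  k <- min(2L, ncol(pca$x))
  sc <- pca$x[, seq_len(k), drop = FALSE]
  gsc <- predict(pca, newdata = rbind(g[use]))[1, seq_len(k)]
  if (k < 2L) { sc <- cbind(sc, 0); gsc <- c(gsc, 0) }
  dists <- sqrt(rowSums((V - matrix(g, nrow(V), length(g), byrow = TRUE))^2))
  scores <- tibble(
    id = c(paste0("tile_", seq_len(nrow(V))), "global"),
    role = c(rep("tile", nrow(V)), "global"),
    pc1 = c(sc[, 1], gsc[1]), pc2 = c(sc[, 2], gsc[2]),
    dist_to_global = c(dists, 0)
  )
  structure(list(scores = scores, metric = median(dists),
                 coefficients = V, pca = pca),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("heterogeneity over %d tile models: median distance %.4g\n",
              nrow(x$coefficients), x$metric))
  invisible(x)
}

#' @export
tidy.heterogeneity <- function(x, ...) x$scores

#' @export
glance.heterogeneity <- function(x, ...) {
  tibble(n_tiles = nrow(x$coefficients), metric = x$metric)
}

#' @export
autoplot.heterogeneity <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               colour = .data$role, shape = .data$role)) +
    ggplot2::geom_point(size = 2, ...) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

# ---- robust cohort summaries ----------------------------------------------

#' Trimmed mean and Winsorized spread
#'
#' Trims `floor(trim_fraction * n)` values from each tail for the mean;
#' Winsorizes the same tails (clamping them to the retained extremes) for
#' the standard deviation; the standard error divides by `sqrt(n)` of the
#' full sample.
#'
#' @param values Numeric vector, length >= 3.
#' @param trim_fraction Fraction trimmed/Winsorized per tail.
#' @return A one-row tibble with `trimmed_mean`, `winsorized_sd`,
#'   `winsorized_se`, `n`, `n_trimmed_per_tail`.
#' @examples
#' robust_summary(c(1, 2, 3, 4, 100), trim_fraction = 0.2)
#' @export
robust_summary <- function(values, trim_fraction = 0.05) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 3, trim_fraction >= 0, trim_fraction < 0.5)
  n <- length(values)
  k <- floor(trim_fraction * n)
  s <- sort(values)
  retained <- s[(k + 1):(n - k)]
  wins <- pmin(pmax(s, retained[1]), retained[length(retained)])
  wsd <- sd(wins)
  tibble(trimmed_mean = mean(retained),
         winsorized_sd = wsd,
         winsorized_se = wsd / sqrt(n),
         n = n, n_trimmed_per_tail = k)
}
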