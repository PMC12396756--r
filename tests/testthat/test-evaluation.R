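test_that("multiclass AUC handles perfect, tied and hand-counted cases", {
  truth <- c("A", "A", "B", "B", "C", "C")
  perfect <- diag(3)[match(truth, c("A", "B", "C")), ]
  colnames(perfect) <- c("A", "B", "C")
  rep_perfect <- multiclass_auc(truth, perfect)
  expect_equal(rep_perfect$micro, 1)
  expect_equal(rep_perfect$macro, 1)
  expect_equal(rep_perfect$weighted_macro, 1)

  # identical scores: mid-rank ties give 0.5 everywhere
  flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("A", "B", "C")))
  rep_flat <- multiclass_auc(truth, flat)
  expect_equal(rep_flat$per_class$auc, rep(0.5, 3))
  expect_equal(rep_flat$micro, 0.5)

  # 6-sample 2-class case vs exhaustive Mann-Whitney pair counting
  t2 <- c("A", "A", "A", "B", "B", "B")
  sc <- c(0.9, 0.4, 0.6, 0.35, 0.6, 0.1) # one tie across classes
  probs <- cbind(A = sc, B = 1 - sc)
  got <- multiclass_auc(t2, probs)$per_class$auc[1]
  pairs <- expand.grid(pos = sc[t2 == "A"], neg = sc[t2 == "B"])
  want <- mean(ifelse(pairs$pos > pairs$neg, 1,
                      ifelse(pairs$pos == pairs$neg, 0.5, 0)))
  expect_equal(got, want)

  # weighted macro = frequency-weighted mean of per-class AUCs
  t3 <- c(rep("A", 8), rep("B", 2))
  set.seed(1)
  p3 <- cbind(A = runif(10), B = runif(10))
  r3 <- multiclass_auc(t3, p3)
  expect_equal(r3$weighted_macro,
               sum(r3$per_class$auc * r3$per_class$freq))
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(7)
  truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
  probs <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("A", "B", "C")))
  a1 <- multiclass_auc(truth, probs)
  a2 <- multiclass_auc(truth, exp(3 * probs))
  expect_equal(a1$per_class$auc, a2$per_class$auc)
  expect_equal(a1$weighted_macro, a2$weighted_macro)
  expect_equal(a1$micro, a2$micro)
})

test_that("a class with no positives is excluded with a warning", {
  truth <- c("A", "A", "B")
  probs <- matrix(1 / 3, 3, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_warning(r <- multiclass_auc(truth, probs), "without positives")
  expect_true(is.na(r$per_class$auc[3]))
  expect_equal(r$macro, 0.5)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  truth <- sample(c("A", "B"), 80, replace = TRUE)
  score <- runif(80) + (truth == "A") * 0.3
  probs <- cbind(A = score, B = 1 - score)
  ours <- multiclass_auc(truth, probs)$per_class$auc[1]
  ref <- as.numeric(pROC::auc(pROC::roc(truth == "A", score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("kernel similarity matches the closed form at the default bandwidth", {
  expect_equal(kernel_similarity(c(1, 2), c(1, 2)), 1)
  # squared distance exactly 0.08 -> e^-1
  a <- c(0, 0); b <- c(sqrt(0.08), 0)
  expect_equal(kernel_similarity(a, b), exp(-1), tolerance = 1e-12)
  # strictly decreasing in distance
  ds <- seq(0.1, 2, by = 0.1)
  vals <- vapply(ds, function(d) kernel_similarity(c(0, 0), c(d, 0)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(kernel_similarity(1:2, 1:3), "length")
})

test_that("the two-sample kernel statistic follows its algebra", {
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(mmd_statistic(X, X), 0, tolerance = 1e-12)
  # singletons reduce to 2 - 2K(x, y)
  x <- matrix(c(0.1, 0.2), 1); y <- matrix(c(0.3, 0.4), 1)
  expect_equal(mmd_statistic(x, y),
               2 - 2 * kernel_similarity(c(0.1, 0.2), c(0.3, 0.4)),
               tolerance = 1e-12)
  expect_error(mmd_statistic(X[0, , drop = FALSE], X), "empty")
  # brute-force triple-sum oracle on a small case
  set.seed(3)
  A <- matrix(rnorm(8, sd = 0.1), 4, 2)
  B <- matrix(rnorm(6, sd = 0.1), 3, 2)
  K <- function(u, v) exp(-sum((u - v)^2) / 0.08)
  s1 <- mean(outer(1:4, 1:4, Vectorize(function(i, j) K(A[i, ], A[j, ]))))
  s2 <- mean(outer(1:4, 1:3, Vectorize(function(i, j) K(A[i, ], B[j, ]))))
  s3 <- mean(outer(1:3, 1:3, Vectorize(function(i, j) K(B[i, ], B[j, ]))))
  expect_equal(mmd_statistic(A, B), s1 - 2 * s2 + s3, tolerance = 1e-12)
})

test_that("separated samples score a larger discrepancy than same-source draws", {
  set.seed(5)
  larger <- 0
  for (rep in 1:20) {
    X <- matrix(rnorm(40, 0, 0.05), 20, 2)
    Y_near <- matrix(rnorm(40, 0, 0.05), 20, 2)
    Y_far <- matrix(rnorm(40, 1, 0.05), 20, 2)
    larger <- larger + (mmd_statistic(X, Y_far) > mmd_statistic(X, Y_near))
  }
  expect_equal(larger, 20)
})

test_that("cross-model similarity averages pairwise kernels on log coefficients", {
  m1 <- mrss_model(c("A", "B"), range_spec(1, 100),
                   log_beta = log(c(A = 1e-3, B = 1e-3)),
                   log_delta = list("A|B" = -0.5))
  m2 <- mrss_model(c("A", "B"), range_spec(1, 100),
                   log_beta = log(c(A = 2e-3, B = 1e-3)),
                   log_delta = list("A|B" = -0.4))
  self <- cross_model_similarity(m1, m1)
  expect_equal(self$mean, 1)
  ab <- cross_model_similarity(list(m1, m2), list(m2))
  ba <- cross_model_similarity(list(m2), list(m1, m2))
  expect_equal(ab$mean, ba$mean)
  expect_equal(ab$matrix[1, 1], kernel_similarity(-0.5, -0.4))
  # base intensities are not part of the similarity (interaction space only)
  m3 <- mrss_model(c("A", "B"), range_spec(1, 100),
                   log_beta = log(c(A = 9e-3, B = 9e-3)),
                   log_delta = list("A|B" = -0.5))
  expect_equal(cross_model_similarity(m1, m3)$mean, 1)
  bad <- mrss_model(c("A", "C"), range_spec(1, 100),
                    log_beta = log(c(A = 1, C = 1)))
  expect_error(cross_model_similarity(m1, bad), "incompatible")
})

test_that("model sets from different generators separate in mean similarity", {
  set.seed(13)
  make_set <- function(center) {
    lapply(1:4, function(i)
      mrss_model(c("A", "B"), range_spec(1, 100),
                 log_beta = log(c(A = 1e-3, B = 1e-3)),
                 log_delta = list("A|A" = center + rnorm(1, 0, 0.05),
                                  "A|B" = -center + rnorm(1, 0, 0.05))))
  }
  for (rep in 1:10) {
    setA <- make_set(0.3)
    setB <- make_set(-0.3)
    within <- cross_model_similarity(setA, setA)$mean
    between <- cross_model_similarity(setA, setB)$mean
    expect_gt(within, between)
  }
})

test_that("heterogeneity metric and PC scores behave as defined", {
  base <- mrss_model(c("A", "B"), range_spec(1, 100),
                     log_beta = log(c(A = 1e-3, B = 1e-3)),
                     log_delta = list("A|A" = 0.1, "A|B" = -0.1, "B|B" = 0.2))
  # identical tiles: metric 0, scores at the origin
  h0 <- heterogeneity_analysis(list(base, base, base), base)
  expect_equal(h0$metric, 0)
  expect_equal(max(abs(h0$scores$pc1)), 0, tolerance = 1e-12)

  # hand 4 x 2 case: deltas differ in two coordinates only
  mk <- function(aa, ab) mrss_model(c("A", "B"), range_spec(1, 100),
                                    log_beta = log(c(A = 1e-3, B = 1e-3)),
                                    log_delta = list("A|A" = aa, "A|B" = ab))
  tiles <- list(mk(1, 0), mk(0, 1), mk(-1, 0), mk(0, -1))
  global <- mk(0, 0)
  h <- heterogeneity_analysis(tiles, global)
  expect_equal(h$metric, 1) # every tile at distance 1 from the global
  # rank-2 coefficients: the 2 PCs reproduce pairwise distances exactly
  sc <- as.matrix(h$scores[h$scores$role == "tile", c("pc1", "pc2")])
  V <- h$coefficients
  expect_equal(unname(as.matrix(dist(sc))), unname(as.matrix(dist(V))),
               tolerance = 1e-12)
  expect_error(heterogeneity_analysis(tiles[1:2], global), "3")
})

test_that("heterogeneity metric is translation invariant", {
  mk <- function(aa, ab, bb = 0)
    mrss_model(c("A", "B"), range_spec(1, 100),
               log_beta = log(c(A = 1e-3, B = 1e-3)),
               log_delta = list("A|A" = aa, "A|B" = ab, "B|B" = bb))
  tiles <- list(mk(0.5, 0.1), mk(0.2, -0.3), mk(-0.1, 0.4))
  h1 <- heterogeneity_analysis(tiles, mk(0.1, 0))
  shift <- 2.5
  tiles2 <- list(mk(0.5 + shift, 0.1 + shift), mk(0.2 + shift, -0.3 + shift),
                 mk(-0.1 + shift, 0.4 + shift))
  h2 <- heterogeneity_analysis(tiles2, mk(0.1 + shift, shift))
  expect_equal(h1$metric, h2$metric, tolerance = 1e-12)
})

test_that("robust summaries trim and Winsorize symmetrically", {
  r0 <- robust_summary(rep(4.2, 5))
  expect_equal(r0$trimmed_mean, 4.2)
  expect_equal(r0$winsorized_sd, 0)
  expect_equal(r0$winsorized_se, 0)

  r1 <- robust_summary(c(1, 2, 3, 4, 100), trim_fraction = 0.2)
  expect_equal(r1$trimmed_mean, 3) # retained {2, 3, 4}
  expect_equal(r1$n_trimmed_per_tail, 1)
  # Winsorized sample is {2,2,3,4,4}
  expect_equal(r1$winsorized_sd, sd(c(2, 2, 3, 4, 4)))
  expect_equal(r1$winsorized_se, sd(c(2, 2, 3, 4, 4)) / sqrt(5))

  # inflating the maximum does not move the trimmed mean
  r2 <- robust_summary(c(1, 2, 3, 4, 1e6), trim_fraction = 0.2)
  expect_equal(r2$trimmed_mean, r1$trimmed_mean)
  expect_equal(r2$winsorized_sd, r1$winsorized_sd)
})

test_that("shuffle test is deterministic given a seed and p is floored", {
  p <- synth_csr_pattern(pattern_window(0, 500, 0, 500),
                         c(A = 2e-3, B = 2e-3), seed = 17)
  st1 <- shuffle_test(p, n_shuffles = 5, seed = 9, dummy_grid_n = 24)
  st2 <- shuffle_test(p, n_shuffles = 5, seed = 9, dummy_grid_n = 24)
  expect_identical(st1$replicates, st2$replicates)
  expect_gte(st1$empirical_p, 1 / 5)
  expect_lte(st1$empirical_p, 1)
  # add-one rule
  st3 <- shuffle_test(p, n_shuffles = 5, seed = 9, p_rule = "add_one",
                      dummy_grid_n = 24)
  expect_equal(st3$empirical_p,
               (1 + sum(st3$replicates$dev_on_original <=
                          st3$replicates$dev_on_shuffle)) / 6)
})

test_that("shuffle test on CSR does not fabricate significance", {
  # a no-interaction pattern is its own shuffle: the original should not
  # stand out (hardcore-thinned so no real cell sits below the hardcore)
  p <- synth_hardcore_pattern(pattern_window(0, 600, 0, 600),
                              c(A = 2e-3, B = 2e-3), hardcore = 3,
                              seed = 23)
  st <- shuffle_test(p, n_shuffles = 12, seed = 3, dummy_grid_n = 24)
  dd <- st$replicates$dev_on_original - st$replicates$dev_on_shuffle
  dd <- dd[!is.na(dd)]
  # paired sign test: differences should not be one-sided
  nb <- sum(dd > 0)
  pval <- stats::binom.test(nb, length(dd))$p.value
  expect_gt(pval, 0.05)
  expect_gt(st$empirical_p, 0.1)
})
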