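test_that("Poisson centers have the right moments and determinism", {
  w <- pattern_window(0, 1000, 0, 1000)
  counts <- vapply(1:200, function(s)
    nrow(simulate_poisson_centers(1e-3, w, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 200))
  cen <- simulate_poisson_centers(5e-4, w, seed = 1)
  expect_true(all(cen$x >= 0 & cen$x <= 1000 & cen$y >= 0 & cen$y <= 1000))
  expect_identical(simulate_poisson_centers(5e-4, w, seed = 1), cen)
  expect_error(simulate_poisson_centers(0, w), "> 0")
})

test_that("hardcore thinning enforces the minimum separation", {
  w <- pattern_window(0, 500, 0, 500)
  p <- synth_hardcore_pattern(w, c(A = 2e-3, B = 2e-3), hardcore = 12,
                              seed = 4)
  d <- dist(cbind(p$x, p$y))
  expect_gte(min(d), 12)
  expect_gt(nrow(p), 0)
})

test_that("the Gibbs sampler reduces to multitype Poisson when deltas vanish", {
  w <- pattern_window(0, 1200, 0, 1200)
  m0 <- mrss_model(c("A", "B"), range_spec(1, 100),
                   log_beta = log(c(A = 4e-4, B = 8e-4)))
  ps <- simulate_gibbs(m0, w, seed = 61, n_burn = 2e5, n_samples = 25,
                       thin = 1e4)
  cnts <- vapply(ps, function(p)
    as.numeric(table(factor(p$type, c("A", "B")))), numeric(2))
  expA <- 4e-4 * window_area(w)
  expB <- 8e-4 * window_area(w)
  # sample means within 3 standard errors (correlated draws: be generous
  # by using the per-draw sd rather than sd/sqrt(k))
  expect_lt(abs(mean(cnts[1, ]) - expA), 3 * sqrt(expA))
  expect_lt(abs(mean(cnts[2, ]) - expB), 3 * sqrt(expB))
})

test_that("Gibbs samples respect the hardcore and the seed", {
  w <- pattern_window(0, 500, 0, 500)
  m <- mrss_model(c("A", "B"), range_spec(8, c(50, 100)),
                  log_beta = log(c(A = 1e-3, B = 1e-3)),
                  log_delta = list("A|B" = c(-0.5, 0)))
  p1 <- simulate_gibbs(m, w, seed = 5, n_burn = 1e5)
  p2 <- simulate_gibbs(m, w, seed = 5, n_burn = 1e5)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_gte(min(dist(cbind(p1$x, p1$y))), 8)
  # impossible settings are flagged
  expect_error(simulate_gibbs(m, pattern_window(0, 5, 0, 5), seed = 1),
               "non-ergodic")
})

test_that("baseline assignment reproduces multinomial frequencies", {
  w <- pattern_window(0, 2000, 0, 2000)
  cen <- simulate_poisson_centers(1e-3, w, seed = 2)
  eq <- assign_types_baseline(cen, c("A", "B", "C", "D"), seed = 3,
                              window = w)
  cnt <- table(factor(eq$type, c("A", "B", "C", "D")))
  n <- nrow(cen)
  expect_true(all(abs(cnt - n / 4) < 3 * sqrt(n * 0.25 * 0.75)))
  fr <- assign_types_baseline(cen, c("A", "B"), frequencies = c(0.8, 0.2),
                              seed = 3, window = w)
  expect_lt(abs(mean(fr$type == "A") - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  expect_identical(assign_types_baseline(cen, c("A", "B"),
                                         frequencies = c(0.8, 0.2),
                                         seed = 3, window = w)$type,
                   fr$type)
  expect_error(assign_types_baseline(cen, c("A", "B"),
                                     frequencies = c(0.5, 0.2)), "1")
})

test_that("method 1 at zero resampling is the frequency baseline", {
  w <- pattern_window(0, 800, 0, 800)
  cen <- simulate_poisson_centers(8e-4, w, seed = 11)
  m <- mrss_model(c("A", "B"), range_spec(1, 60),
                  log_beta = log(c(A = 6e-4, B = 2e-4)),
                  log_delta = list("A|A" = 0.5))
  t0 <- assign_types_method1(cen, m, resample_percent = 0, seed = 7,
                             window = w, trace_points = 0)
  n <- nrow(cen)
  pA <- 0.75 # exp(log_beta) normalized
  cnt <- sum(t0$pattern$type == "A")
  expect_lt(abs(cnt - n * pA), 3 * sqrt(n * pA * (1 - pA)))
  # determinism
  t0b <- assign_types_method1(cen, m, resample_percent = 0, seed = 7,
                              window = w, trace_points = 0)
  expect_identical(t0$pattern$type, t0b$pattern$type)
  expect_equal(t0$provenance$method, "method1")
})

test_that("method 1 resampling moves assignments toward the model", {
  w <- pattern_window(0, 700, 0, 700)
  cen <- simulate_poisson_centers(1e-3, w, seed = 12)
  # strong self-affinity model: resampling should create same-type patches
  m <- mrss_model(c("A", "B"), range_spec(1, 60),
                  log_beta = log(c(A = 5e-4, B = 5e-4)),
                  log_delta = list("A|A" = 0.8, "B|B" = 0.8,
                                   "A|B" = -0.8))
  t4 <- assign_types_method1(cen, m, resample_percent = 300, seed = 5,
                             window = w, trace_points = 1)
  tr <- t4$provenance$trace
  expect_equal(nrow(tr), 2) # endpoints 0% and 300%
  expect_true(all(tr$wmauc >= 0 & tr$wmauc <= 1))
  expect_gte(tr$wmauc[2], tr$wmauc[1])
})

test_that("method 2 assigns every cell and respects the score contract", {
  w <- pattern_window(0, 600, 0, 600)
  cen <- simulate_poisson_centers(8e-4, w, seed = 21)
  # dominant type: log-beta gap 3 with no interactions
  m <- mrss_model(c("A", "B"), range_spec(1, 60),
                  log_beta = log(c(A = 1e-3, B = 1e-3 * exp(-3))))
  tt <- assign_types_method2(cen, m, seed = 9, window = w)
  expect_true(all(tt$pattern$type %in% c("A", "B")))
  expect_equal(nrow(tt$pattern), nrow(cen))
  # softmax bound: P(A) = e^3/(e^3+1) ~ 0.953 everywhere
  expect_gte(mean(tt$pattern$type == "A"), 0.9)
  expect_equal(tt$provenance$termination, "score_threshold")
  expect_true(all(tt$provenance$trace$score >= 0 &
                    tt$provenance$trace$score <= 1))
  expect_true(tt$provenance$final_score > 0.9)
})

test_that("method 2 hitting max_iters warns and still returns a total assignment", {
  w <- pattern_window(0, 500, 0, 500)
  cen <- simulate_poisson_centers(6e-4, w, seed = 31)
  # an anti-affine model that cannot reach a 0.99 agreement score
  m <- mrss_model(c("A", "B"), range_spec(1, 80),
                  log_beta = log(c(A = 3e-4, B = 3e-4)),
                  log_delta = list("A|A" = -0.8, "B|B" = -0.8))
  expect_warning(
    tt <- assign_types_method2(cen, m, score_threshold = 0.99,
                               streak_length = 50, max_iters = 200,
                               seed = 2, window = w),
    "max_iters")
  expect_equal(tt$provenance$termination, "max_iters")
  expect_true(all(tt$pattern$type %in% c("A", "B")))
})

test_that("neighbor matrices count ordered in-range pairs", {
  p <- as_cell_pattern(
    data.frame(x = c(0, 50, 200), y = 0, type = c("A", "A", "B")),
    window = pattern_window(-10, 300, -10, 10))
  M <- neighbor_matrix(p, radius = 100)
  expect_equal(M["A", "A"], 2) # one unordered pair counted both ways
  expect_equal(sum(M) - M["A", "A"], 0)
  # empty pattern handled by construction: a single faraway pair
  p2 <- as_cell_pattern(data.frame(x = c(0, 500), y = 0,
                                   type = c("A", "B")),
                        window = pattern_window(-10, 600, -10, 10))
  expect_true(all(neighbor_matrix(p2, 100) == 0))
  # symmetry on a random fixture
  p3 <- csr_fixture(seed = 44, side = 400,
                    intensity = c(A = 2e-3, B = 1e-3, C = 5e-4))
  M3 <- neighbor_matrix(p3, 80)
  expect_true(isSymmetric(unname(M3)))
  # brute-force check of one off-diagonal entry
  d <- as.matrix(dist(cbind(p3$x, p3$y)))
  want <- sum(d[p3$type == "A", p3$type == "B"] <= 80)
  expect_equal(M3["A", "B"], want)
})

test_that("pattern-set distances form a metric summary table", {
  ps <- lapply(1:3, function(s)
    synth_csr_pattern(pattern_window(0, 400, 0, 400),
                      c(A = 2e-3, B = 2e-3), seed = 50 + s,
                      pattern_id = paste0("p", s)))
  self <- pattern_set_distance(ps[[1]], ps[[1]])
  expect_equal(self$distances$distance, 0)
  d12 <- pattern_set_distance(ps[[1]], ps[[2]])$distances$distance
  d21 <- pattern_set_distance(ps[[2]], ps[[1]])$distances$distance
  expect_equal(d12, d21)
  d13 <- pattern_set_distance(ps[[1]], ps[[3]])$distances$distance
  d23 <- pattern_set_distance(ps[[2]], ps[[3]])$distances$distance
  expect_lte(d13, d12 + d23) # triangle inequality via shared matrices
  full <- pattern_set_distance(ps[1:2], ps)
  expect_equal(nrow(full$distances), 6)
  expect_true(all(c("q1", "median", "q3") %in% names(full$summary)))
  bad <- synth_csr_pattern(pattern_window(0, 400, 0, 400), c(X = 1e-3),
                           seed = 3)
  expect_error(pattern_set_distance(ps[[1]], bad), "type-set")
})

test_that("truncated Voronoi cells are discs when isolated and clipped bisectors otherwise", {
  w <- pattern_window(0, 200, 0, 200)
  # single center mid-window: a 64-gon of radius 20
  shp <- truncated_voronoi(data.frame(x = 100, y = 100), w, max_radius = 20)
  expect_equal(length(unique(shp$cell)), 1)
  area <- multistrauss:::polygon_areas(shp)
  expect_lt(abs(area - pi * 400) / (pi * 400), 0.01)
  expect_true(all(sqrt((shp$x - 100)^2 + (shp$y - 100)^2) <= 20 + 1e-9))

  # two centers 10 px apart share the perpendicular bisector
  shp2 <- truncated_voronoi(data.frame(x = c(95, 105), y = c(100, 100)), w,
                            max_radius = 20)
  s1 <- shp2[shp2$cell == 1, ]
  s2 <- shp2[shp2$cell == 2, ]
  expect_true(all(s1$x <= 100 + 1e-9))
  expect_true(all(s2$x >= 100 - 1e-9))
  expect_true(any(abs(s1$x - 100) < 1e-9))

  # vertices always within max_radius of their center; no overlap: total
  # area bounded by both the window and the disc packing
  set.seed(6)
  cen <- data.frame(x = runif(40, 0, 200), y = runif(40, 0, 200))
  shp3 <- truncated_voronoi(cen, w, max_radius = 20)
  for (i in unique(shp3$cell)) {
    s <- shp3[shp3$cell == i, ]
    expect_true(all(sqrt((s$x - cen$x[i])^2 + (s$y - cen$y[i])^2)
                    <= 20 + 1e-6))
  }
  areas <- multistrauss:::polygon_areas(shp3)
  expect_lte(sum(areas), min(window_area(w), 40 * pi * 400) + 1e-6)
  expect_error(truncated_voronoi(data.frame(x = c(1, 1), y = c(1, 1)), w),
               "duplicate")
})

test_that("synthetic tissues carry shapes and export to disk", {
  w <- pattern_window(0, 300, 0, 300)
  cen <- simulate_poisson_centers(8e-4, w, seed = 41)
  m <- mrss_model(c("A", "B"), range_spec(1, 60),
                  log_beta = log(c(A = 4e-4, B = 4e-4)))
  tis <- assign_types_baseline(cen, c("A", "B"), seed = 1, window = w)
  tis <- multistrauss:::new_synthetic_tissue(tis, method = "baseline",
                                             seed = 1)
  tis <- add_cell_shapes(tis, max_radius = 20)
  expect_tibble(tis$shapes)
  base <- file.path(withr::local_tempdir(), "tissue")
  write_synthetic_tissue(tis, base)
  expect_true(file.exists(paste0(base, ".csv")))
  expect_true(file.exists(paste0(base, ".geojson")))
  gj <- jsonlite::read_json(paste0(base, ".geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), length(unique(tis$shapes$cell)))
  back <- read_pattern(paste0(base, ".csv"))
  expect_equal(nrow(back), nrow(tis$pattern))
})
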