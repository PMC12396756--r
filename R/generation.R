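# ---- primitive generators --------------------------------------------------

#' Homogeneous Poisson cell centers
#'
#' Draws `N ~ Poisson(total_intensity * area)` uniformly placed centers,
#' the starting arrangement for synthetic tissue generation.
#'
#' @param total_intensity Cells per square pixel (> 0).
#' @param window An [pattern_window()].
#' @param seed Optional seed.
#' @return A tibble of `x`, `y` coordinates.
#' @export
simulate_poisson_centers <- function(total_intensity, window, seed = NULL) {
  stopifnot(total_intensity > 0)
  window <- as_ms_window(window)
  with_seed(seed, {
    n <- rpois(1, total_intensity * window_area(window))
    tibble(x = runif(n, window$x_min, window$x_max),
           y = runif(n, window$y_min, window$y_max))
  })
}

#' Multitype complete spatial randomness fixture
#'
#' Independent homogeneous Poisson patterns per type: the no-interaction
#' ground truth used to validate that fitted interaction coefficients
#' cover zero.
#'
#' @param window An [pattern_window()].
#' @param intensity Named per-type intensities (cells per square pixel).
#' @param seed Optional seed.
#' @param pattern_id Optional id.
#' @return A `cell_pattern`.
#' @export
synth_csr_pattern <- function(window, intensity, seed = NULL,
                              pattern_id = "csr") {
  window <- as_ms_window(window)
  stopifnot(!is.null(names(intensity)), all(intensity > 0))
  with_seed(seed, {
    parts <- lapply(names(intensity), function(tt) {
      cen <- simulate_poisson_centers(intensity[[tt]], window)
      cen$type <- tt
      cen
    })
    df <- dplyr::bind_rows(parts)
  })
  as_cell_pattern(df, window = window, pattern_id = pattern_id,
                  type_set = sort(names(intensity)))
}

#' Hardcore-thinned pattern fixture
#'
#' Draws a multitype Poisson pattern and removes, in a random order, every
#' cell closer than `hardcore` to an already-retained cell (Matern-style
#' sequential thinning). The result respects the hardcore constraint but
#' has no other interaction structure.
#'
#' @inheritParams synth_csr_pattern
#' @param hardcore Minimum separation in pixels.
#' @return A `cell_pattern` with minimum pairwise distance >= `hardcore`.
#' @export
synth_hardcore_pattern <- function(window, intensity, hardcore,
                                   seed = NULL, pattern_id = "hardcore") {
  p <- synth_csr_pattern(window, intensity, seed = seed,
                         pattern_id = pattern_id)
  keep <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                    hardcore_thin_idx(p$x, p$y, hardcore))
  new_cell_pattern(as_tibble(p)[keep, ], pattern_window_of(p),
                   type_set(p), pattern_id)
}

# indices retained by sequential hardcore thinning in a random scan order
hardcore_thin_idx <- function(x, y, hardcore) {
  n <- length(x)
  ord <- sample.int(n)
  kept <- logical(n)
  kx <- numeric(0); ky <- numeric(0); kid <- integer(0)
  for (i in ord) {
    if (length(kx) == 0 ||
        min((kx - x[i])^2 + (ky - y[i])^2) >= hardcore^2) {
      kx <- c(kx, x[i]); ky <- c(ky, y[i]); kid <- c(kid, i)
    }
  }
  sort(kid)
}

# ---- Gibbs sampling from a model ------------------------------------------

#' Simulate a pattern from a multirange Strauss-hardcore model
#'
#' Birth-death-shift Metropolis-Hastings sampling of the model's Gibbs
#' density. Acceptance ratios use conditional intensities only, so the
#' intractable normalizing constant never appears. The chain starts from a
#' hardcore-thinned Poisson draw at the model's base intensities (or
#' empty), runs `n_burn` proposals, and returns the state; with
#' `n_samples > 1`, further states are collected every `thin` proposals.
#' The returned pattern always respects the hardcore radius.
#'
#' @param model An `mrss` model with finite coefficients.
#' @param window An [pattern_window()].
#' @param seed Optional seed.
#' @param n_burn Burn-in proposals.
#' @param n_samples Number of patterns to return.
#' @param thin Proposals between successive retained samples.
#' @param p_birth,p_death Proposal mix; the remainder are shifts
#'   (relocations).
#' @param init `"poisson"` or `"empty"` starting state, or a
#'   `cell_pattern` (same type set) to start the chain from — useful to
#'   reach metastable structured configurations that a cold start cannot
#'   nucleate.
#' @param pattern_id Optional id (suffixed when `n_samples > 1`).
#' @return A `cell_pattern`, or a list of them when `n_samples > 1`.
#' @export
simulate_gibbs <- function(model, window, seed = NULL,
                           n_burn = 1e5, n_samples = 1, thin = 2e4,
                           p_birth = 0.4, p_death = 0.4,
                           init = c("poisson", "empty"),
                           pattern_id = "gibbs") {
  if (!inherits(init, "cell_pattern")) init <- match.arg(init)
  window <- as_ms_window(window)
  if (!all(is.finite(model$coefficients)))
    stop("model coefficients must be finite")
  rh <- model$range_spec$hardcore
  side <- min(window$x_max - window$x_min, window$y_max - window$y_min)
  if (rh >= side)
    stop("non-ergodic settings: hardcore radius ", rh,
         " leaves no room for points in the window")
  ts <- model$type_set
  with_seed(seed, {
    if (inherits(init, "cell_pattern")) {
      stopifnot(identical(type_set(init), ts))
      x <- init$x; y <- init$y; tc <- type_codes(init)
      keep <- if (rh > 0) hardcore_thin_idx(x, y, rh) else seq_along(x)
      x <- x[keep]; y <- y[keep]; tc <- tc[keep]
    } else if (init == "poisson") {
      p0 <- synth_csr_pattern(window, exp(model$log_beta))
      keep <- if (rh > 0) hardcore_thin_idx(p0$x, p0$y, rh) else seq_len(nrow(p0))
      x <- p0$x[keep]; y <- p0$y[keep]
      tc <- match(p0$type[keep], ts)
    } else {
      x <- numeric(0); y <- numeric(0); tc <- integer(0)
    }
    run <- function(x, y, tc, nprop) {
      cpp_gibbs(model$log_beta, model$log_delta,
                rh, model$range_spec$breakpoints,
                window$x_min, window$x_max, window$y_min, window$y_max,
                x, y, as.integer(tc), as.integer(nprop), p_birth, p_death)
    }
    st <- run(x, y, tc, n_burn)
    out <- list(state_to_pattern(st, ts, window, pattern_id))
    if (n_samples > 1) {
      for (s in 2:n_samples) {
        st <- run(st$x, st$y, st$type, thin)
        out[[s]] <- state_to_pattern(st, ts, window,
                                     sprintf("%s.%02d", pattern_id, s))
      }
    }
  })
  if (n_samples == 1) out[[1]] else out
}

state_to_pattern <- function(st, ts, window, id) {
  new_cell_pattern(tibble(x = st$x, y = st$y, type = ts[st$type]),
                   window, ts, id)
}

# ---- study fixtures --------------------------------------------------------

#' Generating model and sampler for a segregated multitype pattern
#'
#' A stable (all interaction multipliers <= 1) three-type Gibbs model in
#' which every cross-type pair is strongly inhibited in the first range
#' (log-delta -1.5 within 50 px) and mildly inhibited in the second (-0.3
#' within 50-100 px). Sampling it produces a mosaic of essentially
#' single-type domains: a strongly non-random type arrangement with
#' magnitude past 1 on the log scale in the first range, while remaining
#' a well-defined, integrable density (strong *attraction* in a pairwise
#' model degenerates into hardcore-packed clumps and is therefore not used
#' as a fixture).
#'
#' Base intensities are set so a 1500 x 1500 px window carries roughly
#' `n_target` cells at equilibrium.
#'
#' @param n_target Approximate expected cell count.
#' @param window An [pattern_window()]; default 1500 x 1500 px.
#' @return `segregated_model()` returns the generating `mrss` model;
#'   `synth_segregated_pattern()` a sampled `cell_pattern`.
#' @export
segregated_model <- function(n_target = 2000,
                             window = pattern_window(0, 1500, 0, 1500)) {
  window <- as_ms_window(window)
  # cross-type inhibition thins the realized pattern well below beta; the
  # 3.5 factor compensates so equilibrium counts land near n_target
  beta <- 3.5 * n_target / 3 / window_area(window)
  mrss_model(
    c("A", "B", "C"), range_spec(hardcore = 1, breakpoints = c(50, 100)),
    log_beta = log(c(A = beta, B = beta, C = beta)),
    log_delta = list("A|B" = c(-1.5, -0.3), "A|C" = c(-1.5, -0.3),
                     "B|C" = c(-1.5, -0.3))
  )
}

#' @rdname segregated_model
#' @param seed Seed for the sampler.
#' @param n_burn Burn-in proposals.
#' @export
synth_segregated_pattern <- function(seed, n_target = 2000,
                                     window = pattern_window(0, 1500, 0, 1500),
                                     n_burn = 6e5) {
  simulate_gibbs(segregated_model(n_target, window), window, seed = seed,
                 n_burn = n_burn, pattern_id = "segregated")
}

#' Generating model and sampler for a clustered-territory pattern
#'
#' A five-type Gibbs model combining same-type attraction in the first
#' range (log-delta +1.0 within 60 px) with cross-type inhibition
#' (log-delta -2 within 60 px, -0.5 within 60-120 px) over a 4 px
#' hardcore, at unequal type abundances (35/25/20/12/8%) and
#' confluent-tissue density (about 2,000 cells in a 600 x 600 px window).
#' Because pairwise attraction is only conditionally integrable, the
#' pattern is sampled *canonically*: the chain starts from a
#' hardcore-thinned Poisson draw with the target counts and runs
#' shift-only proposals (no births or deaths), so the number of cells of
#' each type is fixed by construction and the attraction reorganizes
#' locations into same-type clusters aggregated into territories. The
#' chain length is part of the fixture definition. The result mimics real
#' multiplexed-tissue structure -- same-type cell clusters of unequal
#' abundance with segregated neighborhoods -- and is the standard
#' strongly-non-random fixture for the shuffle test.
#'
#' @param n_target Approximate total cell count.
#' @param window An [pattern_window()]; default 600 x 600 px.
#' @return `clustered_territory_model()` the generating `mrss` model;
#'   `synth_structured_pattern()` a sampled `cell_pattern`.
#' @export
clustered_territory_model <- function(n_target = 2000,
                                      window = pattern_window(0, 600, 0, 600)) {
  window <- as_ms_window(window)
  b <- n_target / window_area(window)
  freqs <- c(A = 0.35, B = 0.25, C = 0.20, D = 0.12, E = 0.08)
  ts <- names(freqs)
  ld <- list()
  for (t1 in ts) ld[[paste0(t1, "|", t1)]] <- c(1, 0)
  cross <- utils::combn(ts, 2)
  for (k in seq_len(ncol(cross)))
    ld[[paste(cross[, k], collapse = "|")]] <- c(-2, -0.5)
  mrss_model(ts, range_spec(hardcore = 4, breakpoints = c(60, 120)),
             log_beta = log(b * freqs), log_delta = ld)
}

#' @rdname clustered_territory_model
#' @param seed Seed (drives the initial draw and the chain).
#' @param n_prop Shift proposals for the canonical chain.
#' @export
synth_structured_pattern <- function(seed, n_target = 2000,
                                     window = pattern_window(0, 600, 0, 600),
                                     n_prop = 2e6) {
  window <- as_ms_window(window)
  model <- clustered_territory_model(n_target, window)
  init <- synth_hardcore_pattern(window, 1.15 * exp(model$log_beta),
                                 model$range_spec$hardcore, seed = seed,
                                 pattern_id = "init")
  simulate_gibbs(model, window, seed = seed + 1L, n_burn = n_prop,
                 p_birth = 0, p_death = 0, init = init,
                 pattern_id = "structured")
}

#' Generating model and sampler for coefficient-recovery studies
#'
#' A stable two-type model with known repulsive and null coefficients
#' (log-deltas: A|A -1.0 in the first range; A|B -1.5 and -0.5 in the
#' first and second ranges; all else 0) over ranges 30 and 60 px with a
#' 10 px hardcore, in a 3500 x 3500 px window at about 2,000 cells. The
#' interaction pressure is kept low enough that the mixed (unsegregated)
#' phase is stable, so every coefficient is identifiable from a single
#' realization; the base intensities compensate the repulsive thinning so
#' equilibrium counts stay near `n_target`.
#'
#' `synth_recovery_pattern()` simulates on a window enlarged by the
#' outermost range and returns the core-window pattern together with the
#' halo of cells just outside it, so fits see edge-complete neighbor
#' counts (the same device the tile analysis uses).
#'
#' @param n_target Approximate expected cell count in the core window.
#' @param window Core [pattern_window()]; default 3500 x 3500 px.
#' @return `recovery_model()` an `mrss` model;
#'   `synth_recovery_pattern()` a list with elements `pattern` (core) and
#'   `halo` (tibble of out-of-window cells within the outermost range).
#' @export
recovery_model <- function(n_target = 2000,
                           window = pattern_window(0, 3500, 0, 3500)) {
  window <- as_ms_window(window)
  rho <- n_target / 2 / window_area(window)
  mrss_model(
    c("A", "B"), range_spec(hardcore = 10, breakpoints = c(30, 60)),
    log_beta = log(c(A = 2.3 * rho, B = 1.75 * rho)),
    log_delta = list("A|A" = c(-1.0, 0), "A|B" = c(-1.5, -0.5))
  )
}

#' @rdname recovery_model
#' @param seed Seed for the sampler.
#' @param n_burn Burn-in proposals.
#' @export
synth_recovery_pattern <- function(seed, n_target = 2000,
                                   window = pattern_window(0, 3500, 0, 3500),
                                   n_burn = 5e5) {
  window <- as_ms_window(window)
  model <- recovery_model(n_target, window)
  margin <- r_max(model$range_spec)
  big <- pattern_window(window$x_min - margin, window$x_max + margin,
                        window$y_min - margin, window$y_max + margin,
                        window$pixel_size_um)
  pbig <- simulate_gibbs(model, big, seed = seed, n_burn = n_burn,
                         pattern_id = "recovery")
  inside <- pbig$x >= window$x_min & pbig$x <= window$x_max &
    pbig$y >= window$y_min & pbig$y <= window$y_max
  core <- as_cell_pattern(as.data.frame(pbig)[inside, ], window = window,
                          type_set = type_set(pbig),
                          pattern_id = "recovery")
  list(pattern = core,
       halo = as_tibble(pbig)[!inside, c("x", "y", "type")])
}

# ---- baseline and model-guided type assignment -----------------------------

#' Random type assignment baselines
#'
#' Assigns types to fixed centers i.i.d., either with given frequencies or
#' uniformly — the two baseline generators synthetic tissues are compared
#' against.
#'
#' @param centers Tibble/data frame of `x`, `y` columns.
#' @param type_set Type labels.
#' @param frequencies Optional probabilities (summing to 1, in `type_set`
#'   order or named); default equal frequencies.
#' @param window Window for the returned pattern (default bounding box).
#' @param seed Optional seed.
#' @return A `cell_pattern`.
#' @export
assign_types_baseline <- function(centers, type_set, frequencies = NULL,
                                  window = NULL, seed = NULL) {
  C <- length(type_set)
  freq <- frequencies %||% rep(1 / C, C)
  if (!is.null(names(freq))) freq <- freq[type_set]
  stopifnot(length(freq) == C, abs(sum(freq) - 1) < 1e-8)
  labels <- with_seed(seed,
                      sample(type_set, nrow(centers), replace = TRUE,
                             prob = freq))
  as_cell_pattern(tibble(x = centers$x, y = centers$y, type = labels),
                  window = window, type_set = type_set,
                  pattern_id = "baseline")
}

# neighbor incidence lists of a fixed center arrangement under a model's
# ranges: for each cell, the indices and bins of its in-range neighbors
incidence_lists <- function(x, y, range_spec) {
  prs <- cpp_neighbor_pairs(x, y, range_spec$hardcore,
                            range_spec$breakpoints)
  keep <- prs$bin > 0 # drop sub-hardcore pairs from counting
  split_i <- split(seq_along(prs$i)[keep], prs$i[keep])
  list(j = lapply(split_i, function(ix) prs$j[ix]),
       bin = lapply(split_i, function(ix) prs$bin[ix]),
       who = as.integer(names(split_i)))
}

# per-cell type-by-bin counts from incidence lists and current types
# (0 = unassigned, ignored); returns n x (C*m) bin-major type-fastest
counts_from_incidence <- function(inc, types, n, C, m) {
  cnt <- matrix(0L, n, C * m)
  for (ii in seq_along(inc$who)) {
    i <- inc$who[ii]
    j <- inc$j[[ii]]; b <- inc$bin[[ii]]
    tj <- types[j]
    ok <- tj > 0L
    if (any(ok)) {
      idx <- (b[ok] - 1L) * C + tj[ok]
      tab <- tabulate(idx, nbins = C * m)
      cnt[i, ] <- tab
    }
  }
  cnt
}

# lambda row for one cell given its counts row (length C*m) under `model`
lambda_row <- function(model, cnt_row) {
  vapply(model$type_set, function(tt) {
    D <- delta_rows_for_type(model, tt)
    exp(model$log_beta[[tt]] + sum(cnt_row * as.vector(D)))
  }, numeric(1))
}

#' Model-guided type assignment, method 1 (global resampling)
#'
#' Starts from an i.i.d. assignment at the model's implied type
#' frequencies (normalized `exp(log_beta)`), then performs
#' `ceiling(resample_percent/100 * n)` single-cell updates: each update
#' picks a random cell (with replacement) and redraws its type from the
#' model's predicted type probabilities given the current neighborhood.
#' The self-prediction weighted-macro AUC is recorded along the way,
#' tracing how the arrangement converges toward the model.
#'
#' @param centers Tibble of `x`, `y` centers.
#' @param model An `mrss` model.
#' @param resample_percent Update budget as a percentage of the cell count
#'   (values above 100 mean multiple passes on average).
#' @param seed Optional seed.
#' @param window Window (default bounding box of the centers).
#' @param trace_points Number of evenly spaced wmAUC trace checkpoints
#'   (0 disables tracing).
#' @return A `synthetic_tissue` object (pattern + provenance, including
#'   the wmAUC trace).
#' @export
assign_types_method1 <- function(centers, model, resample_percent = 400,
                                 seed = NULL, window = NULL,
                                 trace_points = 8) {
  stopifnot(resample_percent >= 0)
  n <- nrow(centers)
  ts <- model$type_set
  C <- length(ts)
  m <- n_ranges(model$range_spec)
  window <- if (is.null(window)) bbox_window(centers$x, centers$y)
            else as_ms_window(window)
  freq <- exp(model$log_beta); freq <- freq / sum(freq)
  inc <- incidence_lists(centers$x, centers$y, model$range_spec)
  n_upd <- ceiling(resample_percent / 100 * n)
  checkpoints <- if (trace_points > 0 && n_upd > 0)
    unique(round(seq(0, n_upd, length.out = trace_points + 1))) else 0L

  with_seed(seed, {
    types <- sample.int(C, n, replace = TRUE, prob = freq)
    cnt <- counts_from_incidence(inc, types, n, C, m)
    trace <- list()
    note_trace <- function(upd) {
      pat <- new_cell_pattern(tibble(x = centers$x, y = centers$y,
                                     type = ts[types]),
                              window, ts, "method1")
      w <- tryCatch(
        suppressWarnings(glance(prediction_auc(model, pat))$weighted_macro),
        error = function(e) NA_real_)
      trace[[length(trace) + 1]] <<- tibble(updates = upd,
                                            resample_percent = 100 * upd / n,
                                            wmauc = w)
    }
    if (0L %in% checkpoints) note_trace(0L)
    upd_targets <- sample.int(n, n_upd, replace = TRUE)
    for (u in seq_len(n_upd)) {
      i <- upd_targets[u]
      old <- types[i]
      lam <- lambda_row(model, cnt[i, ])
      newt <- sample.int(C, 1, prob = lam / sum(lam))
      if (newt != old) {
        types[i] <- newt
        ii <- match(i, inc$who)
        if (!is.na(ii)) {
          j <- inc$j[[ii]]; b <- inc$bin[[ii]]
          cnt[cbind(j, (b - 1L) * C + old)] <-
            cnt[cbind(j, (b - 1L) * C + old)] - 1L
          cnt[cbind(j, (b - 1L) * C + newt)] <-
            cnt[cbind(j, (b - 1L) * C + newt)] + 1L
        }
      }
      if (u %in% checkpoints) note_trace(u)
    }
    pat <- new_cell_pattern(tibble(x = centers$x, y = centers$y,
                                   type = ts[types]),
                            window, ts, "method1")
  })
  new_synthetic_tissue(pat, method = "method1", seed = seed,
                       trace = dplyr::bind_rows(trace),
                       params = list(resample_percent = resample_percent))
}

#' Model-guided type assignment, method 2 (gradual seeding)
#'
#' Starts with every cell unassigned. Each iteration picks a random cell,
#' assigns (or reassigns) its type from the model probabilities given the
#' currently assigned neighbors, and likewise assigns its still-unassigned
#' neighbors within the first interaction range. The agreement score — the
#' mean model probability of the currently assigned types — is tracked
#' incrementally, and sampling stops once the score exceeds
#' `score_threshold` for `streak_length` consecutive iterations, or at
#' `max_iters` (flagged in the provenance).
#'
#' @inheritParams assign_types_method1
#' @param score_threshold Agreement score needed to begin terminating.
#' @param streak_length Consecutive above-threshold iterations required.
#' @param max_iters Iteration cap; default `50 * n`.
#' @return A `synthetic_tissue`; provenance carries the score trace and
#'   termination reason.
#' @export
assign_types_method2 <- function(centers, model, score_threshold = 0.9,
                                 streak_length = 1000, max_iters = NULL,
                                 seed = NULL, window = NULL) {
  n <- nrow(centers)
  ts <- model$type_set
  C <- length(ts)
  m <- n_ranges(model$range_spec)
  max_iters <- max_iters %||% (50L * n)
  window <- if (is.null(window)) bbox_window(centers$x, centers$y)
            else as_ms_window(window)
  inc <- incidence_lists(centers$x, centers$y, model$range_spec)

  with_seed(seed, {
    types <- integer(n) # 0 = unassigned
    cnt <- counts_from_incidence(inc, types, n, C, m)
    probs <- rep(NA_real_, n) # model prob of the assigned type
    set_type <- function(i, newt) {
      old <- types[i]
      if (old == newt) return(invisible())
      types[i] <<- newt
      ii <- match(i, inc$who)
      if (!is.na(ii)) {
        j <- inc$j[[ii]]; b <- inc$bin[[ii]]
        if (old > 0L)
          cnt[cbind(j, (b - 1L) * C + old)] <<-
            cnt[cbind(j, (b - 1L) * C + old)] - 1L
        cnt[cbind(j, (b - 1L) * C + newt)] <<-
          cnt[cbind(j, (b - 1L) * C + newt)] + 1L
        # refresh neighbors' assigned-type probabilities
        for (jj in j[types[j] > 0L]) {
          lamj <- lambda_row(model, cnt[jj, ])
          probs[jj] <<- lamj[types[jj]] / sum(lamj)
        }
      }
      lam <- lambda_row(model, cnt[i, ])
      probs[i] <<- lam[newt] / sum(lam)
    }
    draw_type <- function(i) {
      lam <- lambda_row(model, cnt[i, ])
      sample.int(C, 1, prob = lam / sum(lam))
    }
    streak <- 0L
    it <- 0L
    score_trace <- numeric(0)
    while (it < max_iters) {
      it <- it + 1L
      i <- sample.int(n, 1)
      set_type(i, draw_type(i))
      ii <- match(i, inc$who)
      if (!is.na(ii)) {
        r1_unassigned <- inc$j[[ii]][inc$bin[[ii]] == 1L &
                                       types[inc$j[[ii]]] == 0L]
        for (j in r1_unassigned) set_type(j, draw_type(j))
      }
      score <- mean(probs[types > 0L])
      if (it %% 50L == 0L) score_trace <- c(score_trace, score)
      streak <- if (all(types > 0L) && score > score_threshold) streak + 1L
                else 0L
      if (streak >= streak_length) break
    }
    reason <- if (streak >= streak_length) "score_threshold" else "max_iters"
    if (reason == "max_iters") {
      warning("method 2 reached max_iters before a stable agreement score")
      # complete any unassigned cells so the returned tissue is total
      for (i in which(types == 0L)) set_type(i, draw_type(i))
    }
    pat <- new_cell_pattern(tibble(x = centers$x, y = centers$y,
                                   type = ts[types]),
                            window, ts, "method2")
    final_score <- mean(probs)
  })
  new_synthetic_tissue(pat, method = "method2", seed = seed,
                       trace = tibble(iteration = seq_along(score_trace) * 50L,
                                      score = score_trace),
                       params = list(score_threshold = score_threshold,
                                     streak_length = streak_length,
                                     max_iters = max_iters,
                                     iterations = it,
                                     termination = reason,
                                     final_score = final_score))
}

# ---- synthetic tissue container -------------------------------------------

new_synthetic_tissue <- function(pattern, method, seed = NULL, trace = NULL,
                                 params = list(), shapes = NULL) {
  structure(list(pattern = pattern, shapes = shapes,
                 provenance = c(list(method = method, seed = seed,
                                     trace = trace), params)),
            class = "synthetic_tissue")
}

#' Attach truncated-Voronoi cell shapes to a synthetic tissue
#'
#' @param tissue A `synthetic_tissue`.
#' @param max_radius Truncation radius in pixels (default 20 px, about
#'   7.5 microns at CODEX pixel size).
#' @return The tissue with a `shapes` polygon tibble (see
#'   [truncated_voronoi()]).
#' @export
add_cell_shapes <- function(tissue, max_radius = 20) {
  tissue$shapes <- truncated_voronoi(tissue$pattern,
                                     pattern_window_of(tissue$pattern),
                                     max_radius = max_radius)
  tissue
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("synthetic tissue (%s): %d cells%s\n",
              x$provenance$method, nrow(x$pattern),
              if (!is.null(x$shapes)) ", with cell shapes" else ""))
  invisible(x)
}

#' @export
autoplot.synthetic_tissue <- function(object, ...) {
  if (!is.null(object$shapes)) {
    shp <- dplyr::left_join(object$shapes,
                            tibble(cell = seq_len(nrow(object$pattern)),
                                   type = object$pattern$type),
                            by = "cell")
    ggplot2::ggplot(shp, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$cell,
                                      fill = .data$type)) +
      ggplot2::geom_polygon(colour = "white", linewidth = 0.1) +
      ggplot2::coord_equal() +
      ggplot2::theme_void()
  } else {
    autoplot(object$pattern, ...)
  }
}

#' Write a synthetic tissue to disk
#'
#' Writes the cell table as CSV (same dialect as [write_pattern()]) and,
#' when shapes are present, the polygons as GeoJSON.
#'
#' @param tissue A `synthetic_tissue`.
#' @param path Base path; `.csv` and `.geojson` suffixes are appended.
#' @export
write_synthetic_tissue <- function(tissue, path) {
  write_pattern(tissue$pattern, paste0(path, ".csv"))
  if (!is.null(tissue$shapes)) {
    polys <- split(tissue$shapes, tissue$shapes$cell)
    features <- lapply(polys, function(p) {
      ring <- cbind(p$x, p$y)
      ring <- rbind(ring, ring[1, ])
      list(type = "Feature",
           properties = list(cell = p$cell[1]),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                                                     function(i) ring[i, ]))))
    })
    jsonlite::write_json(list(type = "FeatureCollection",
                              features = unname(features)),
                         paste0(path, ".geojson"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- neighbor-count matrices ----------------------------------------------

#' Type-by-type neighbor count matrix
#'
#' Entry (i, j) counts ordered pairs of distinct cells (a cell of type i,
#' a cell of type j) within `radius` of each other; the matrix is
#' symmetric and each unordered same-type pair contributes 2 to the
#' diagonal. This is the summary used to compare synthetic arrangements
#' with real ones.
#'
#' @param pattern A `cell_pattern`.
#' @param radius Pixels; default 100.
#' @return A K x K integer matrix with type labels as dimnames.
#' @export
neighbor_matrix <- function(pattern, radius = 100) {
  stopifnot(radius > 0)
  ts <- type_set(pattern)
  C <- length(ts)
  pool <- pool_cells(pattern, NULL)
  rs <- list(hardcore = 0, breakpoints = radius)
  class(rs) <- "range_spec"
  res <- neighbor_counts_raw(pattern$x, pattern$y, pool, rs,
                             exclude = seq_len(nrow(pattern)))
  M <- matrix(0L, C, C, dimnames = list(ts, ts))
  tc <- type_codes(pattern)
  for (i in seq_len(C)) {
    rows <- tc == i
    if (any(rows)) M[i, ] <- as.integer(colSums(res$counts[rows, , drop = FALSE]))
  }
  M
}

#' Pairwise distances between neighbor matrices of two pattern sets
#'
#' Euclidean (Frobenius) distance between the [neighbor_matrix()] of every
#' pattern in set A and every pattern in set B, with box-plot quartiles.
#'
#' @param set_a,set_b Lists of `cell_pattern`s sharing a type set.
#' @param radius Pixels; default 100.
#' @return A list with the `distances` tibble (a, b, distance) and
#'   `summary` quartiles.
#' @export
pattern_set_distance <- function(set_a, set_b, radius = 100) {
  if (inherits(set_a, "cell_pattern")) set_a <- list(set_a)
  if (inherits(set_b, "cell_pattern")) set_b <- list(set_b)
  ts <- type_set(set_a[[1]])
  for (p in c(set_a, set_b))
    if (!identical(type_set(p), ts)) stop("type-set mismatch across patterns")
  Ma <- lapply(set_a, neighbor_matrix, radius = radius)
  Mb <- lapply(set_b, neighbor_matrix, radius = radius)
  grid <- expand.grid(a = seq_along(Ma), b = seq_along(Mb))
  d <- vapply(seq_len(nrow(grid)), function(r)
    sqrt(sum((Ma[[grid$a[r]]] - Mb[[grid$b[r]]])^2)), numeric(1))
  distances <- tibble(a = grid$a, b = grid$b, distance = d)
  list(distances = distances,
       summary = tibble(q1 = quantile(d, 0.25), median = median(d),
                        q3 = quantile(d, 0.75), mean = mean(d)))
}
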