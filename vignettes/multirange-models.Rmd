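---
title: "Multirange multitype Strauss-hardcore models of cell-type spatial relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multirange multitype Strauss-hardcore models of cell-type spatial relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(multistrauss)
```

## The model

A segmented multiplexed-tissue image reduces to a *multitype point
pattern*: cell centers $x_i$ with categorical type labels $c_i$ in a
rectangular window $W$. `multistrauss` treats such a pattern as a
realization of a multitype Gibbs point process whose unnormalized density
over configurations is

$$ f(p) \;\propto\; \prod_i \beta_{c_i} \prod_{i<j}
   \gamma_{c_i c_j}\!\big(d(x_i, x_j)\big), $$

where $\beta_c$ is the base intensity of type $c$ (cells per px$^2$) and
$\gamma_{cc'}(d)$ is a pairwise interaction function. The package's
interaction family is *hardcore + multirange Strauss*: for an increasing
sequence of breakpoints $r_1 < \dots < r_m$ and hardcore radius $r_h$,

$$ \gamma_{cc'}(d) = \begin{cases}
   0 & d < r_h \\
   \delta^{(k)}_{cc'} & r_{k-1} \le d < r_k \quad (r_0 \equiv r_h)\\
   1 & d > r_m,
   \end{cases} $$

with the last bin closed at $r_m$. One coefficient per unordered type
pair and distance bin captures attraction ($\delta > 1$) or repulsion
($\delta < 1$) that can differ across distance ranges — the central
modeling idea. Coefficients are stored and reported on the log scale, so
attraction is positive and repulsion negative, and are symmetric by
construction ($\delta_{cc'} = \delta_{c'c}$, one shared column per
unordered pair).

The *conditional intensity* of finding a type-$c$ cell at location $u$
given the rest of the pattern is

$$ \lambda(u, c \mid p) = \beta_c \prod_{j} \gamma_{c c_j}(d(u, x_j))
   = \exp\Big( \log\beta_c + \sum_{c', k} n_{c'k}(u) \,
     \log\delta^{(k)}_{cc'} \Big), $$

where $n_{c'k}(u)$ counts type-$c'$ cells in bin $k$ around $u$. Although
the terms are pairwise, products of coefficients produce *multipartner*
effects: with one range, $\delta_{AB} = 0.1$ and $\delta_{BC} = 20$, a
location near one A cell has $\lambda(u, B) \propto 0.1$, but adding a C
neighbor multiplies in the attraction and gives
$\lambda(u, B) \propto 0.1 \times 20 = 2$ — A repels B alone but the pair
(A, C) attracts B:

```{r multipartner}
m <- mrss_model(c("A", "B", "C"), range_spec(hardcore = 1, breakpoints = 100),
                log_beta = log(c(A = 1, B = 1, C = 1)),
                log_delta = list("A|B" = log(0.1), "B|C" = log(20)))
counts <- matrix(0, 3, 1, dimnames = list(c("A", "B", "C"), "r1"))
counts["A", 1] <- 1
conditional_intensity(m, counts, "B")
counts["C", 1] <- 1
conditional_intensity(m, counts, "B")
```

## Fitting: pseudolikelihood and the Berman-Turner device

The normalizing constant of $f$ is intractable, so fitting maximizes the
log *pseudolikelihood*

$$ \log \mathrm{PL}(\theta; p) = \sum_i \log \lambda(x_i, c_i \mid p)
   - \sum_c \int_W \lambda(u, c \mid p)\, du. $$

The integral is discretized with the Berman-Turner device
(`build_quadrature()`): dummy marked points are placed at the centers of a
$g \times g$ grid plus the four window corners (all types at each
location), and at each data cell's location dummies of all *other* types
are added. Counting weights $w$ = (grid cell area) / (locations in the
cell) partition the window, the response is $y = 1/w$ for data points and
0 for dummies, and the pseudolikelihood becomes a weighted Poisson-type
likelihood. `fit_mrss()` maximizes it with `stats::glm.fit` under the
quasi family with log link and variance proportional to the mean; the
design matrix holds one indicator per type (giving $\log\hat\beta$) and
one pooled count column per pair-range (giving $\log\hat\delta$). Wald
95% intervals use the Pearson-dispersion-scaled covariance.

Numerical conventions:

* Distance bins are half-open $[r_{k-1}, r_k)$ with the last closed; a
  boundary distance falls in the outer bin, $d = r_h$ in bin 1.
* When a quadrature point sits at a data cell's location with another
  mark, that data cell is excluded from its neighbor counts (the
  "replacement" reading of the conditional intensity). Without the
  exclusion every co-located dummy would be hardcore-forbidden at
  distance 0 and dummy-cell diagnostics would be degenerate.
* Quadrature points with any neighbor inside the hardcore are *forbidden*
  (conditional intensity 0) and dropped from the fit; a forbidden real
  cell makes the deviance infinite and is reported, never silently fixed.
* IRLS runs to relative tolerance $10^{-8}$ or 100 iterations; any
  coefficient beyond 50 on the log scale raises a training-divergence
  error rather than returning a nonsensical model.
* Pair-range columns never observed in the data are dropped and reported
  with coefficient 0 and `NA` intervals.

**Dummy grid resolution.** The default is
$g = \max(32, \lceil 2\sqrt{n}\rceil)$, about four dummy locations per
cell. This is deliberately denser than the minimum that makes the scheme
well-defined: refitting a hardcore-only simulation at increasing
resolutions showed that grids with only $\sim n$ dummy locations bias the
first-range coefficients upward by several tenths on the log scale at
$n \approx 2000$, while the bias disappears from $g \approx 2\sqrt n$ on.
For models whose hardcore radius spans several pixels it pays to choose
$g$ so grid cells are no larger than $r_h$ (the coefficient-recovery
study below uses that rule).

**Edge effects.** Counts are truncated at the window for full images; no
edge correction is applied. For subregions the package instead uses
*halos*: cells just outside a tile within the outermost range are counted
as neighbors but carry no likelihood contribution
(`extract_tiles()`, and the `halos` argument of `fit_mrss()`). Edge
truncation attenuates coefficient estimates by roughly the boundary area
fraction; fits on windows whose side is $\gtrsim 50$ times the outermost
range are essentially unaffected, and halo-complete fits remove the
effect entirely.

## Goodness of fit: average deviance per cell

Model quality is measured by the quasi-deviance

$$ D = 2 \sum_i w_i \big( y_i \log(y_i / \mu_i) - (y_i - \mu_i) \big),
  \qquad \mu_i = \exp(\eta_i), $$

with $y \log y = 0$ at $y = 0$, normalized per point over the real,
dummy, or combined subsets (`deviance_report()`). Because $\mu$ is
exponential in the linear predictor, a model evaluated far outside its
fitted regime produces astronomically large deviances; reports therefore
carry log10 values as well. Average deviance per cell depends on the
quadrature resolution through the saturated term, so comparisons always
evaluate all models on the same scheme (`loo_cross_validate()` does this
internally).

## Evaluation tools

* `prediction_auc()` / `multiclass_auc()` — one-vs-rest ROC AUC per type
  with mid-rank tie handling, aggregated as micro, macro, and
  frequency-weighted macro (wmAUC), the headline accuracy number for
  predicting a cell's type from its neighborhood alone.
* `shuffle_test()` — the non-randomness test: fit a model to each of
  `n_shuffles` random type permutations (locations fixed), and compare
  its average deviance per cell on a *different* shuffle against the
  original pattern. The empirical p-value is the floored fraction of
  shuffles that describe the original at least as well,
  $\max(x, 1)/S$, so complete separation with 100 shuffles reports 0.01
  (an add-one variant is available). The default model is the
  single-range protocol: one 100 px Strauss radius, 1 px hardcore.
* `kernel_similarity()` / `mmd_statistic()` — Gaussian-kernel similarity
  ($2\sigma^2 = 0.08$) and the three-term two-sample discrepancy with
  diagonal terms included; `cross_model_similarity()` averages pairwise
  kernels over the concatenated log interaction coefficients of two model
  sets (the log scale is the fitting scale; base intensities are
  excluded so the similarity reflects interactions, not abundances).
* `heterogeneity_analysis()` — PCA (centered, unscaled by default) of
  tile-model coefficient rows with the global model projected through the
  fitted rotation; the heterogeneity metric is the median Euclidean
  distance between tile and global coefficients in the *full* coefficient
  space, not the PC plane.
* `robust_summary()` — trimmed mean (floor of the trim fraction per
  tail) with Winsorized standard deviation and a standard error that
  divides by $\sqrt n$ of the full sample.

## Simulation

`simulate_gibbs()` samples the model by birth-death-shift
Metropolis-Hastings; acceptance ratios use conditional intensities only,
so the normalizing constant never appears, and the hardcore is respected
exactly. The proposal mix defaults to 40% births, 40% deaths, 20%
relocations; chains start from a hardcore-thinned Poisson draw at the base
intensities (or an empty state, or any supplied pattern). The sampler is
validated two ways: with all interactions zero it must reproduce a
multitype Poisson process, and on a window small enough that only a few
points fit, its state frequencies are compared in total variation against
Monte-Carlo integration of the density itself — including an attractive
cross-type term, which is well-defined at such bounded occupancies.

**Stability of attraction.** A pairwise attractive coefficient makes the
grand-canonical process explosive: configurations packing ever more
mutually-within-range points gain density weight faster than the base
intensity penalizes them, and the only brake is the hardcore packing
bound, so equilibrium is a degenerate hard-packed clump. Grand-canonical
sampling with attraction is therefore only used on tiny windows where
occupancy is bounded. For realistic clustered fixtures the package
samples *canonically* instead: `p_birth = 0, p_death = 0` gives a
shift-only chain that holds the number and types of cells fixed and lets
attraction reorganize locations. This is the standard conditional-on-n
device; the chain length becomes part of the fixture definition and is
recorded with it.

## Synthetic tissue generation

Starting from Poisson cell centers at the density of a reference pattern
(`simulate_poisson_centers()`), types are assigned by:

* `assign_types_baseline()` — i.i.d. at given or equal frequencies;
* `assign_types_method1()` — initial frequency draw, then single-cell
  resampling from `predict_type_probs()` at the current neighborhood,
  with the update budget expressed as a percentage of the cell count
  (sampling with replacement, so 400% means four expected passes) and a
  wmAUC trace recorded along the way;
* `assign_types_method2()` — gradual seeding: each iteration assigns a
  random cell and its still-unassigned first-range neighbors from the
  model, tracking the agreement score — operationalized as the mean model
  probability of the currently assigned types, maintained incrementally —
  until it stays above 0.9 for 1000 consecutive iterations (or a
  `max_iters` cap of 50n, flagged in the provenance).

Cell shapes come from a Voronoi diagram truncated at 20 px (a 64-gon
disc intersection, `truncated_voronoi()`), and arrangements are compared
through the type-by-type matrix of ordered neighbor pairs within 100 px
(`neighbor_matrix()`, `pattern_set_distance()`).

## The synthetic study fixtures

All tests run on generated data with known structure; the generators are
exported, first-class code:

* `synth_csr_pattern()` / `synth_hardcore_pattern()` — no-interaction
  ground truths.
* `segregated_model()` — three types, cross-type inhibition only
  (log-deltas $-1.5$ within 50 px, $-0.3$ within 50-100 px), equal
  abundances calibrated so a 1500 px window holds about 2,000 cells at
  equilibrium. All multipliers are $\le 1$, so the density is integrable
  and the sampler verifiably equilibrates; the realized patterns are
  mosaics of single-type domains. Used for the self-prediction wmAUC
  study and the multirange-vs-single-range comparison (where each
  single-range model is exactly nested in the multirange one).
* `clustered_territory_model()` — five types at unequal abundances
  (35/25/20/12/8%) with first-range self-attraction $+1.0$ and cross-type
  inhibition $(-2, -0.5)$ over ranges 60/120 px and a 4 px hardcore, at
  confluent-tissue density (about 2,000 cells in 600 px squared; at
  CODEX pixel size that is one cell per $\sim 13\,\mu m$ pitch). Sampled
  canonically (see above) for $2 \times 10^6$ shift proposals. This is
  the strongly non-random fixture for the shuffle test: same-type
  clusters of unequal abundance aggregated into territories, the kind of
  arrangement (follicles, crypts) that makes real tissues non-random.
  Repulsion-only mosaics at equal abundances proved too weak for the
  shuffle test to separate *every* replicate at desk scale — the test's
  power comes from shuffle-fitted models being forced to extrapolate to
  extreme type compositions, which requires clustering plus abundance
  asymmetry.
* `recovery_model()` / `synth_recovery_pattern()` — the
  coefficient-recovery ground truth: two types, log-deltas $-1.0$ (A|A,
  first range), $-1.5 / -0.5$ (A|B, both ranges) and 0 elsewhere over
  ranges 30/60 px with a 10 px hardcore, about 2,000 cells in a 3500 px
  window. The generator simulates on a window enlarged by the outermost
  range and returns the core pattern with its halo, so recovery fits see
  edge-complete counts. Interaction pressure is kept low enough that the
  mixed phase is stable — at higher density or longer ranges the same
  coefficients drive segregation or type extinction, where the
  generating coefficients are no longer identifiable from one
  realization. Attraction is excluded here for the stability reason
  above; its magnitudes match the repulsive ones so the study still
  exercises coefficients of size 1-1.5.

Problem sizes throughout (about 2,000-3,000 cells per pattern, 10-20
replicates per property) were chosen as the smallest at which the
asymptotic behavior of the pseudolikelihood machinery is clearly visible;
the same code runs unchanged on full-size images.

What passing these studies does *not* show about real data: generated
patterns are homogeneous (no lumens, vessels, or cell-free regions), type
counts are balanced enough that every pair-range is observed, and cell
centers obey the generating hardcore exactly. Real segmented images
violate all three, which is why the fitting path reports — rather than
hides — forbidden points, dropped columns, and divergence.

## Known limitations

* The piecewise-constant interaction jumps at each breakpoint; smooth
  families (soft-core and relatives) are out of scope.
* Pseudolikelihood, not likelihood: the normalizing constant is never
  computed, so absolute model probabilities are unavailable and
  comparisons rest on deviance differences on a shared quadrature.
* Wald intervals use the quasi-GLM covariance; for strongly interacting
  patterns this is an approximation to the true pseudolikelihood
  sampling variance (empirically near-nominal in the recovery study).
* The exported interaction graphs presume positive node totals for the
  size mapping; nonpositive self-interaction totals are drawn at a floor
  radius in a hatched style.
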