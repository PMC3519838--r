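---
title: "Metric-matrix k-means: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-matrix k-means: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MMkmeans)
```

# The procedure

Given an `n × d` matrix `X` of points (rows) and a cluster count `k`,
all four algorithms in this package are Lloyd-style iterations: assign
every point to its nearest centroid, then move each centroid to the mean
of its members, until no point moves. They differ only in which
distance evaluations they skip:

* **Traditional** (`runTraditional`) skips nothing: `n·k` evaluations
  per iteration.
* **Enhanced / Overlapped** (`runEnhanced`, `runOverlapped`) keep
  per-point caches (`Clusterid`, `Pointdis`). Each iteration a point is
  probed once against its own cluster's updated centroid; if that
  distance does not exceed the cached one the point stays, otherwise it
  is reassigned against all `k` centroids. Enhanced refreshes the cache
  of a kept point; Overlapped leaves it anchored at the last full
  reassignment. The distinction between the two published variants is
  under-documented, so this cache-refresh policy is this package's
  explicit reading; everything else is shared code.
* **MMk-means** (`runMMKmeans`) freezes *whole clusters*. Once the run
  is judged near its optimum, every iteration ends by building the
  metric matrix `MM[i, j] = r(pm_i, m_j)` — the Pearson correlation
  between centroid `i` of the previous iteration and centroid `j` of the
  current one — and comparing its sorted eigenvalues with those of the
  previous iteration. Clusters whose relative eigenvalue change sits
  within the stability band are frozen, and their members skip
  reassignment at zero cost. Frozen clusters still receive centroid
  updates, may gain points from unfrozen clusters, and unfreeze again if
  their eigenvalue later shifts (the flags are recomputed every
  iteration, which is the conservative reading of the per-iteration
  stability check).

The per-iteration objective recorded in every run's trace is the mean
squared Euclidean distance of points to their assigned centroids,
measured **after the assignment step** — so `MSE_1` is available after a
single pass, and for squared-Euclidean assignment the sequence is
provably non-increasing (a property test asserts this). The MSE is
always squared-Euclidean even when assignment uses another distance
kind, so objective curves are comparable across distance kinds.

## Switch-on iteration (MMI)

Monitoring stability from iteration 1 would be both wasteful and wrong —
early centroids move a lot. The monitor is switched on at the
*MMk-means iteration* (MMI), estimated from the PCA–k-means relation:
the optimal k-means objective is bounded below by

    SSE_opt ≥ ‖X‖²_F − Σ_{j≤k} σ²_j

with `σ_j` the j-th largest singular value of `X`. Dividing by the
first-iteration objective gives a dimensionless multiplier
`m = bound / SSE_1` (clamped to `[0, 1]`; singular values beyond the
rank count as zero), and the prediction `MSE_l ≈ m · MSE_1`. Because a
convergent MSE sequence is Cauchy, the first iteration whose MSE comes
within `ε` of this prediction is taken as MMI, capped at the theoretical
bound `⌈MSE_1 · k / MSE_l⌉`. If the band is never entered the run
simply completes as Traditional k-means and the result flags
`mmIteration(run) = NA`; `mmiOverride` lets the caller force (or with
`Inf`, disable) the onset, and disabling reproduces Lloyd bit-for-bit —
a test asserts identity of labels and traces.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | — | cluster count |
| `seed` | 1 | RNG seed for Forgy initialization (k distinct rows) |
| `maxIter` | 300 | iteration cap |
| `distance` | `sq_euclidean` | assignment distance; also `euclidean`, `pearson_dissimilarity` (`1 − r`) |
| `L0`, `H1` | 0.005, 0.015 | stability band on relative eigenvalue change (dimensionless fractions, i.e. 0.5 %–1.5 %) |
| `epsilon` | 0.007 | MMI band half-width |
| `epsilonMode` | `relative` | band is `ε·MSE_1` (scale-free); `absolute` uses `ε` directly, appropriate for normalized expression data of unit scale |
| `stabilityMode` | `threshold` | stable when change `≤ H1`; `strict_interval` requires it in `[L0, H1]` |
| `mmiOverride` | `NA` | force the onset iteration; `Inf` disables the mechanism |

Two of these deserve justification, because the published description
leaves them open:

* **Band semantics.** The eigenvalue change is compared *relatively*
  (scaled by `|pe_j|`), since the band's endpoints are stated as
  percentages. The default test is one-sided (`≤ H1`): a fully
  converged cluster has change ≈ 0, below `L0`, and must count as
  stable. The literal two-sided interval is available as
  `strict_interval` for users who want the published reading; with it,
  two identical consecutive centroid sets freeze *nothing* (change 0 is
  below `L0`) — both behaviors are pinned by tests.
* **ε semantics.** Whether the published `ε = 0.007` was absolute or
  relative is not stated. The default here is relative to `MSE_1`, so
  the criterion does not depend on the measurement scale of the data;
  absolute mode reproduces the normalized-microarray setting.

Other numerical choices: nearest-centroid ties break to the lowest
cluster index (runs are bit-reproducible and deterministic given the
seed); an emptied cluster keeps its previous mean with size 0 rather
than being re-seeded (empty clusters are an expected outcome when
`k > d`, and are reported, not repaired); `MM` is generally slightly
non-symmetric because `(i, j)` and `(j, i)` pair different vectors, so
eigenvalues are taken of `(MM + MMᵀ)/2` — exact whenever `MM` is
symmetric, which is the converged regime where the mechanism operates —
and eigenvalue index maps to cluster by descending sort order (the
eigenvalues decrease along the diagonal by construction). A
zero-variance vector has no defined correlation; `pearsonR` returns 0
with a warning rather than propagating `NaN` into the eigenproblem.
The first stability call is a bootstrap: it records eigenvalues but
freezes nothing, since no previous eigenvalues exist. Inputs with
negative values trigger a warning — the correlation-based stability
condition is not designed for negative expression values, although the
algorithm still runs and in practice tracks Traditional k-means closely.

# Synthetic data

`generateMixture` draws from `kTrue` spherical Gaussian components with
deterministic mean placement: scaled canonical basis vectors when
`kTrue ≤ d` (every pair of means exactly `separation` apart), otherwise
an integer lattice. Class sizes follow the weights by largest
remainder, so only the noise consumes random numbers and identical
seeds give bit-identical data. `generatePeriodicProfiles` emulates
periodic time-course expression (one sinusoidal period over `d`
timepoints, `kTrue` phase classes, per-row phase jitter, additive
noise) — the shape of intraerythrocytic-cycle microarray profiles —
without any claim to microarray noise physics (no dye bias, spot
artifacts, or missingness structure). Both generators restore the
caller's RNG state.

**What passing tests on these generators do and do not show.** They
show algorithmic correctness: monotone objectives, exact reduction to
Lloyd when disabled, sound shortcut decisions, conservative freezing.
They do not certify behavior on real microarray data, for one structural
reason worth stating plainly: on *isotropic* Gaussian noise the spectral
bound is loose — the residual beyond the top-k singular directions is
about `(d − k)/d` of the achievable objective, far outside a 0.7 %
band — so on such data MMI is typically never detected and MMk-means
runs as Traditional k-means (their agreement is then exact, which is
what the headline ARI checks measure under those conditions). The bound
tightens, and the mechanism engages on its own, when the data's spectrum
is concentrated: the test suite includes a fixture with cluster means in
the leading coordinates and noise confined to the orthogonal complement,
on which MMI fires naturally, every cluster freezes, and the run
terminates on all-stable. Real time-course expression matrices, with
strongly correlated timepoints, sit between these extremes.

# Problem sizes

The agreement checks use five paired runs at `n = 5000, d = 50, k = 10`
and `n = 4000, d = 16, k = 15` (separation 8× the within-component
standard deviation), matching the two dimensionality regimes of
interest: k far from d and k near d. Property tests run at
`n ≤ 2000`; the brute-force ARI oracle enumerates all pairs at
`n ≤ 12`; the multiplier's Gram-matrix oracle runs on `8 × 5` matrices.
These sizes were chosen as the smallest at which the regimes'
qualitative behavior is stable across seeds.

# Known limitations

* The freezing rule is a heuristic: a frozen cluster's members skip
  reassignment, so if the band fires early (e.g. a forced low
  `mmiOverride` on marginally separated data) the final partition can
  differ from Lloyd's — the membership audit in the test suite bounds
  this at under 1 % of frozen-cluster members on well-separated
  mixtures, but no such guarantee exists for arbitrary data.
* The spectral estimate assumes the top-k singular values are a good
  proxy for the cluster structure; for isotropic high-dimensional noise
  it underestimates the optimum (see above) and the mechanism stays
  off — a safe failure mode, but no speedup.
* The metric matrix needs `d ≥ 2` (correlation is undefined in one
  dimension) and is unreliable for negative-valued expression data.
* Wall-clock time is not a target; cost is measured in distance
  evaluations, which is hardware-independent and is what the
  per-iteration traces record.
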