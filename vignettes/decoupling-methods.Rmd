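---
title: "Testing evolutionary decoupling of two trait complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing evolutionary decoupling of two trait complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodecouple)
```

# The question

A recurring idea in evolutionary morphology is that two functional units —
here the oral jaw (food capture) and the lower pharyngeal jaw (food
processing) of cichlid fishes — can evolve *decoupled*: divergence, trait
combinations, and evolutionary rates in one unit are unpredictable from the
other. Decoupling expands the reachable morphospace and is a candidate
mechanism behind adaptive radiations. `evodecouple` implements three
complementary phylogenetic comparative approaches to test it, plus the
geometric-morphometric plumbing they need and a synthetic-data generator so
the whole pipeline can be validated end to end without any particular
empirical dataset.

Interpretation rule used throughout: an evolutionary correlation *outside*
the Brownian-motion null band indicates morphological integration; one
*inside* the band is consistent with decoupling. For evolutionary rates only
the *absence* of a correlation is interpretable (a positive rate correlation
can arise under either coupled or decoupled directional change).

# Approach 1 — divergence matrices

Divergence within each jaw is the matrix of pairwise Procrustes distances
between species mean shapes ([`pairwise_shape_distances()`]). The two
matrices are compared with a partial Mantel test
([`partial_mantel()`]) controlling for patristic distance, with the
first-order partial Pearson correlation over lower-triangle entries,
permutations applied jointly to rows and columns of the first matrix, a
one-tailed test for positive association, and the add-one p-value rule.
Defaults: 999 permutations. The control matrix is the patristic distance on
the time tree — "phylogenetic distance" between species pairs is not uniquely
defined, and the patristic metric is the standard tree-derived species-pair
distance. A constant control matrix is bypassed (with a warning), degrading
to the simple Mantel statistic rather than dividing by zero.

# Approach 2 — evolutionary correlations of shape axes

Each jaw's aligned species mean shapes are reduced by PCA
([`shape_pca()`]; axis signs fixed by the largest-loading-positive rule so
orientations are reproducible). The first three axes of one jaw are
correlated with the first three of the other using phylogenetically
independent contrasts ([`pic_contrasts()`]): Felsenstein's pruning
recursion with contrast signs fixed by a deterministic child ordering
(lexicographically smallest descendant tip first), and correlations computed
*through the origin* with df = n_contrasts − 1. On a bifurcating tree of 234
species this gives 233 contrasts and df = 232 — the standard PIC convention.

Observed correlations are judged against an empirical null: 1000 independent
*pairs* of unit-rate Brownian traits simulated on the same tree
([`null_correlations()`]), each pair reduced to its through-origin PIC
correlation. The band is reported both as the min/max (the extreme range)
and as central 95% bounds. The pairing scheme (1000 disjoint pairs rather
than all pairwise combinations of 1000 traits) was an open design choice; we
use disjoint pairs because the resulting band width matches what ~1000
independent draws with ~233 degrees of freedom produce. A useful property
(and a test in the suite): the PIC null is tree-free — standardized
contrasts of independent BM traits are iid normal regardless of topology, so
the null band depends only on the number of contrasts.

Because PCA axes are constrained orthogonal within each block, the package
also extracts metric traits directly from landmarks
([`metric_traits()`]: angles, length ratios, lengths relative to centroid
size, polygon-area ratios such as a tooth-field fraction) whose definitions
are dataset-level configuration, and it fits a phylogenetic two-block PLS
([`phylo_pls()`]): GLS-center each block on the tree, SVD of the
evolutionary cross-covariance `X1c' C^-1 X2c / (n-1)`, correlation of the
phylogenetically transformed scores (`C^-1/2` via eigen-decomposition with
an eigenvalue floor of 1e-12), significance by permuting species rows of the
transformed second block (999 permutations, add-one rule). On a star
phylogeny this reduces exactly to ordinary two-block PLS.

# Approach 3 — branch-specific evolutionary rates

[`run_mcmc()`] fits a multivariate variable-rates Brownian model by
reversible-jump MCMC: per trait an ancestral state α (uniform prior, default
−1..1) and a base rate σ² (uniform prior; defaults 0–1e-4 for the oral
block and 0–1e-3 for the pharyngeal block, reflecting their different shape
variances), plus a set of rate scalars shared across traits, each scoped to
a single branch or to a whole clade (both scopes supported; a flag disables
clade scalars). A branch's relative rate is the product of all scalars
covering it, 1 by default. The likelihood multiplies each branch length by
its relative rate and evaluates the Brownian likelihood by pruning; the
contrast structure is cached so α/σ² updates cost O(1) and the chain is
cheap enough to run millions of iterations in seconds. The implementation is
contract-tested against a dense multivariate-normal oracle (agreement to
1e-8 on trees up to 12 tips across random parameter draws).

Priors with no canonical convention are explicit, configurable
stand-ins: shift magnitudes are log-normal(0, 1.5²) truncated to
(1e-3, 1e3); the number of shifts is Poisson(λ = 1) truncated at the slot
count, with slot arrangements uniform given the count. With that convention
the birth/death acceptance ratios reduce to λ/(k+1) and k/λ, and a
likelihood-free chain reproduces the Poisson count prior exactly — a
prior-recovery check in the test suite. Moves: uniform sliding windows with
reflection at the prior bounds for α and σ², a multiplicative log-normal
walk for existing scalars, and uniform birth/death over free slots. Chains
are exactly reproducible given (config, seed).

Desk-scale defaults are 2×10⁶ iterations, burn-in 2×10⁵, thinning 200
(9000 retained samples) — enough for all parameter ESS to clear the
conventional 200 threshold on trees of ~50–250 tips; [`ess()`] implements
the initial-positive-sequence truncated autocorrelation estimator and is
checked against iid, AR(1) closed-form, and coda. Production-scale runs
(~10⁹ iterations) are a configuration change, not a code change. Bimodal
rate posteriors are handled by [`split_posterior()`], which divides the
sample at per-trait σ² thresholds into two optima with posterior
probabilities, after which [`summarize_rates()`] gives per-branch mean
relative rates (or absolute rates, σ² × relative, which should agree
between optima when the bimodality is a σ²-scalar trade-off).

Rates of the two jaws are then compared overall
([`overall_rate_correlation()`], plain Pearson over branches, with an
optional high-leverage branch exclusion) and through time
([`window_rate_correlation()`]): 0.15-My windows anchored at the present,
all branches older than 8 My pooled into one first window (few lineages
exist near the root; this keeps every window at ≥ 7 branches on radiation-
sized trees). A branch enters every window its age interval overlaps;
intervals are half-open, (parent age, child age] against (start, end], so a
branch aligned with a boundary is counted once — the overlap convention is
declared, not inferred. Branches enter windows unweighted, and window
p-values are reported raw (flagged at 0.05), without multiple-testing
correction. Windows with fewer than 3 branches yield no correlation;
windows under `min_branches` (default 7) are flagged `low_n`.

# Geometric morphometrics

Alignment removes size, position and orientation by generalized Procrustes
analysis ([`gpa()`]): centering, optional scaling to unit centroid size,
iterative rotation to the consensus (convergence 1e-10 on the consensus
update, max 100 iterations — standard and cheap), and a final canonical
orientation (consensus on its principal axes) so results are invariant to
any common rigid motion of the inputs. Procrustes distance is the
post-superimposition Euclidean norm (partial Procrustes distance).

Two dataset-specific steps mirror how a two-jaw landmark dataset is built:

* **Bilateral mirroring** ([`mirror_landmarks()`]): half-configurations
  digitized on one side are completed by reflecting the paired landmarks
  across the least-squares plane through the midline landmarks (midline
  points are projected onto that plane). A 27-landmark half with 12 midline
  and 15 paired landmarks becomes the standard 42-landmark configuration.
  Which landmarks are midline vs paired is dataset configuration — only the
  27 → 42 count is fixed by the design.
* **Subset extraction without re-superimposition**
  ([`extract_recentered_subset()`]): the four premaxilla landmarks are taken
  verbatim from the whole-skeleton alignment and only re-centered — no
  re-rotation, no re-scaling — so the oral-jaw data retain relative size and
  orientation with respect to the body axes, not just shape.

# The synthetic radiation

[`simulate_dataset()`] emulates the statistical structure the analyses
assume, not cichlid anatomy: a pure-birth ultrametric tree (default 234
tips, root age 10 My, matching a large lacustrine radiation), joint Brownian
evolution of two 3-axis trait blocks whose *increments* are correlated ρ
between matched axes (coupling acts at the process level, since that is
what "evolutionary correlation" means), and landmark datasets built by
deforming templates (a 4-landmark 2-D quadrilateral for the premaxilla; a
21-landmark 3-D half-configuration, 9 midline + 12 paired, for the LPJ —
smaller than the real 27 for speed, configurable) along orthonormal shape
axes, with per-specimen Gaussian noise and random rigid motions plus scale
so superimposition is genuinely exercised. Defaults: 10 and 5 specimens per
species (typical 2-D X-ray vs micro-CT sampling), specimen noise sd 0.005
on unit-size templates (about a quarter of the species-level shape signal —
a realistic within/between ratio for skeletal landmarks). Block base rates
default to 5e-5 and 2.5e-4 per My, sitting inside the rate model's default
priors. The deformation bases are projected orthogonal to the similarity
directions (translation, rotation, scaling) at the template, so trait
signal is pure shape change.

Scenarios: `coupled` (ρ = 0.9), `decoupled` (ρ = 0), `late_decoupled`
(ρ = 0.8 on branch segments older than 2 My, 0 on younger; branches
crossing the change age are split there), and `shifted_clade` (a planted
rate scalar, default 10×, on all branches of a clade). Two caveats on what
passing tests show: the generator's noise is iid Gaussian with no
digitization artifacts, no allometry, and no missing landmarks, so success
here does not certify behavior on real data with those features. And in
`late_decoupled` the epochs differ in the *directional coupling* of trait
increments, not in rate magnitudes — so Approach 3 is not expected to
detect it on these data; the windowed-rate machinery is instead validated
with [`simulate_branch_rates()`], which plants epoch-dependent rate
coupling directly.

# Numerical choices and edge cases

* GPA: degenerate (single-point) configurations are rejected by specimen
  name; convergence 1e-10 / 100 iterations.
* PCA and PLS signs: largest-loading-positive; PLS score correlation
  reported non-negative (the singular-vector sign is folded in).
* Matrix inverse square roots: symmetric eigen-decomposition, eigenvalue
  floor 1e-12; a computationally singular phylogenetic covariance is an
  error, not a silent regularization.
* Permutation p-values: add-one rule everywhere (never exactly 0); the
  exhaustive Mantel variant enumerates all n! relabelings and returns the
  exact fraction.
* Mirroring: collinear midline landmarks (no unique plane) are an error.
* Polytomies: accepted by tree I/O and covariance computations, rejected by
  PIC and the rate model (which require bifurcation) with a clear error.
* Window grids: anchored at the present; the merged pre-8-My window fixes
  the old end. The oldest grid window may overlap the merged window — the
  union covers the whole depth and no branch is double-counted within the
  grid.
* Master seeding: the pipeline derives one seed per stage from the master
  seed by a fixed affine scheme, so stages are reproducible independently
  of execution order; all derived seeds stay below 2^31.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
statistical claims are sharp but a laptop-class machine completes them in
minutes: the null band on the full 234-tip tree with 1000 pairs; rate-model
recovery on 50-tip trees with 2×10⁶-iteration chains across 20 replicates;
calibration of the three permutation tests at 600–1000 replicates each; and
a 60-tip end-to-end fixture for byte-level reproducibility. A production-scale
MCMC budget (~10⁹ iterations) is expressed in configuration only.

# Known limitations

* Traits are modeled as independent given the tree and the shared rate
  scalars (PC axes are orthogonal); cross-trait covariance inside a block
  is not estimated.
* No Ornstein–Uhlenbeck or early-burst nulls; the null model is Brownian
  throughout.
* Branch rates from the posterior are shrinkage estimates sharing tree
  structure; windowed correlations of *inferred* rates can show systematic
  patterns that raw generating rates do not. Only the absence of
  correlation is interpreted, matching the method's logic.
* Semilandmark sliding, missing-landmark estimation and asymmetry
  decomposition beyond mirroring are out of scope.

# Interface note

This package is organized as an analysis workflow: the numbered scripts
under `analysis/` (simulate → align → divergence → evolutionary
correlations → rates → rate correlations) are thin drivers over the
exported functions and write their tables under `results/`. The exported
functions plus these scripts are the intended interface; there is no
separate shell tool.
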