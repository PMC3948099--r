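---
title: "The bitstring idiotypic-network model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bitstring idiotypic-network model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idionet)
```

## The model

A node of the network is a clone of B-lymphocytes whose idiotype — the
binding specificity of its antibodies — is caricatured as a bitstring
b_d b_{d−1} … b_1 of length d. Two clones can stimulate each other when
their receptors are (nearly) complementary, so the **base graph** G_d(m)
links every pair of nodes whose bitstrings are complementary allowing for
up to m *mismatches*, a mismatch being a position where the two bits are
equal rather than complementary (mismatches = d − Hamming distance). Every
node then has exactly κ = Σ_{k=0..m} C(d, k) neighbors. We fix the bit
convention once: b_1 is the least significant bit of the integer node
index, and component i of the position vector used below refers to bit b_i.

The **dynamics** is a probabilistic cellular automaton on the 0/1
occupations n(v):

1. *Influx*: every empty node becomes occupied with probability p,
   modeling random idiotype production in the bone marrow.
2. *Window rule*: the occupied-neighbor counts n(∂v) of all nodes are
   computed simultaneously from the post-influx configuration; every
   occupied node with n(∂v) outside [t_L, t_U] is emptied. The window
   caricatures log-bell-shaped B-cell activation: unstimulated clones die,
   overstimulated clones are suppressed.
3. Iterate.

Newly influxed nodes are subject to the same step's window rule; this
ordering (influx first, then selection) is what makes singletons viable:
after the influx a singleton typically has a freshly influxed neighbor that
supplies its stimulation and then dies itself. **Self nodes** model
permanently present self antigen: they are occupied at all times, counted
in the neighbor sums of others, exempt from the window rule, and receive no
influx (they are never empty).

## Emergent architectures and their combinatorics

For suitable parameters the automaton self-organizes into modular
architectures described by d_M ≤ d *determinant* bit positions. Group S_1
holds the nodes with a fixed reference assignment of the determinant bits;
group S_g holds the nodes differing in exactly g − 1 determinant positions.
This yields d_M + 1 groups of size |S_g| = 2^(d−d_M) C(d_M, g−1), summing
to 2^d and symmetric under g ↔ d_M + 2 − g. Each node of S_i has a fixed
number L_ij of neighbors in S_j; `linkMatrix()` evaluates the closed-form
double binomial sum with the convention C(a, b) = 0 for b < 0 or b > a,
which is required for the correct boundary rows. The matrix is
centrosymmetric, its rows sum to κ, and |S_i| L_ij = |S_j| L_ji.
`linkMatrixBruteforce()` recounts all entries on the materialized graph and
is used throughout the tests as an independent oracle.

On G_12(2) with window [1, 10] the relevant architecture has d_M = 11:
three singleton groups (high occupation, linked only to holes), two
periphery groups (high occupation, linked to core and holes), two core
groups (the only groups with intra-group links, weakly occupied), and five
groups of stable holes (kept empty by overstimulation). `roleLabels()`
classifies a group-occupation profile into these roles; because observed
profiles are strongly bimodal (≈ 0.68 against ≤ 0.01 per node) the
"occupied" and "hole" thresholds (defaults 0.1 and 0.05) are
uncritical, and anything between them is reported as `unclassified` rather
than guessed.

## Real-time pattern identification

The center-of-mass vector R with R_i = Σ_v n(v) (2 b_i(v) − 1) / n(G)
compresses the 2^d occupations to d numbers per step. In a stationary
pattern the components fluctuate around +level, −level (≈ ±0.4 at the
parameters above) at determinant positions or around 0 at non-determinant
ones. `inferPattern()` averages a window of steps (default 500) and
classifies each position against a band threshold θ; the default θ = 0.2
sits midway between the empirical levels 0 and 0.4, and positions within
two standard errors of ±θ are flagged ambiguous instead of silently
assigned. The level itself is p-dependent and has no closed form, which is
why θ is a parameter rather than a constant. `detectTransitions()` applies
the same banding per window and reports any band change — the signature of
a reorganization. R is undefined on an empty graph and returned as `NA`,
never as zero.

Two orientation conventions matter. A pattern and its all-bits-flipped
mirror describe the same architecture with group indices reversed;
`orientPattern()` fixes the convention that the occupied side carries the
high indices, which places the self group of a reorganized with-self run
among the high groups, matching the layout of with-self occupation tables.

## Mean-field theory

Replacing fluctuating neighbor occupations by group means gives the
modular mean-field map: with ñ_l = n_l + p(1 − n_l) the post-influx
occupations, the occupied-neighbor count of a group-g node is a sum of
independent binomials k_l ~ B(L_gl, ñ_l) and

n′_g = ñ_g · P(t_L ≤ Σ_l k_l ≤ t_U).

`survivalProbability()` evaluates the probability by sequential binomial
convolution truncated at t_U + 1 bins — once a partial count exceeds t_U it
can never re-enter the window, so the truncation is exact and the cost
polynomial instead of the exponential literal micro-configuration sum. The
tests verify the equivalence against exhaustive enumeration.

`solveFixedPoint()` iterates the map plainly (no damping, matching how the
map is normally used) until the max-norm change is below `tol`
(default 1e−12) or `maxIter` (1e5) is reached; non-convergence is flagged
and warned about, never silently accepted. Several fixed points coexist;
initializing at 0.7 on the groups expected occupied (the "pattern
profile") selects the fixed point seen in simulations. Because the
autonomous link matrix is centrosymmetric, the map commutes with vector
reversal and every fixed point has a mirrored partner; the symmetry is
broken by self.

**Self modifications.** With a fully occupied group s, every group-g node
deterministically sees L_gs occupied self neighbors: group s leaves the
stochastic product and both thresholds drop by L_gs (survival is zero if
t_U − L_gs < 0), and n_s ≡ 1. The index orientation — the count a group-g
node sees is row g, column s — is fixed here because only it reproduces the
with-self neighbor fields. With a single self node in group s, only the
L_sg nodes per group that see it are affected; they use L_gs − 1 trials for
group s and thresholds shifted by one. The affected sub-populations are
iterated separately and, by default, blended back into the group averages
with weight L_sg/|S_g| (`feedback = TRUE`); a purely perturbative variant
that leaves the group averages autonomous is available behind the flag,
since the two readings are equally defensible and differ only at the small
group sizes where sub-populations are a sizable fraction. Mean-field theory
for an intermediate number of self nodes (more than one, fewer than the
whole group) is not implemented; the automaton handles arbitrary self sets.

## Synthetic states and protocols

`idealState()` draws an occupation with prescribed per-group probabilities
— a stand-in for a long burn-in that matches the group occupations but not
the higher-order spatial correlations of a genuinely evolved state; a short
burn-in (500 steps by default) after seeding restores those before any
measurement. `protocolInsertSelf()` runs the insertion experiment
(established pattern → permanently occupy nodes of one group → follow the
reorganization), `protocolEvolveWithSelf()` the from-scratch variant. Both
infer the final pattern post hoc from the late center-of-mass window,
classify roles, and report whether the self placement is tolerant: every
group containing self nodes must link only to groups with mean occupation
below the hole threshold, except for the weakly occupied core.

A practical finding that shaped the analysis pipeline: when a whole hole
group is permanently occupied in an established pattern, the reorganized
architecture usually settles on a *different* set of determinant positions
(the exact mirror, which keeps the original grouping valid, occurred in
only about one of seven runs at p = 0.074). Group statistics after a
reorganization are therefore always computed in the inferred
post-reorganization grouping, not the seeded one. With that convention the
simulated occupations and neighbor fields agree with the with-self
mean-field fixed point within a few percent once self members are excluded
from the group means.

## Numerical and measurement choices

- Statistics are sampled after the window step of each iteration; the
  with-self neighbor fields computed this way match the mean-field
  link-weighted sums.
- Trajectories store bit-packed occupation snapshots (2^d/8 bytes per
  step), so group statistics and life times can be recomputed afterwards
  for any grouping; a 200 MB guard protects against accidental huge runs.
- Influx draws are consumed in node-index order from a single seeded
  stream, making trajectories bit-for-bit reproducible from (parameters,
  seed).
- Mean life times average maximal occupation runs per node within a step
  range; runs touching the range boundaries are discarded rather than
  truncated (unbiased for geometric-like run lengths), and self nodes are
  excluded since their runs never end.
- Problem sizes used in the shipped tests and the acceptance script:
  exhaustive structural checks up to d = 8 (pairwise oracles) and d = 12
  (group censuses), stationary runs of 3000 steps, and with-self
  reorganization runs of 20000 steps on G_12(2) averaged over their last
  ≥ 5000 post-transition steps.

## Known limitations

- Evolution from scratch in the presence of self does not reliably end in
  a tolerant architecture in our simulations: the pattern forms within a
  few hundred steps and, for ten scattered self nodes, regularly places
  some of them in core groups; at influx rates well below the stability
  threshold such non-tolerant patterns are frozen (no reorganization
  pressure), while close to the threshold repeated reorganizations occur
  but need not terminate in a tolerant placement within 6 × 10^4 steps.
  The insertion of a *whole* hole group, by contrast, reproducibly
  reorganizes into a tolerant architecture. The tolerance summary reports
  the placement honestly in either case.
- A single self node can also sit in an established pattern without
  triggering any reorganization (its mean-field fixed point is stable);
  "tolerance by reorganization" is a near-threshold phenomenon.
- Bands in the center-of-mass series are data-driven (θ); there is no
  closed-form criterion for which d_M is dynamically selected at a given
  p, so the architecture modules describe a *given* pattern.
- Weighted links graded by mismatch count, continuous (ODE) concentration
  dynamics, asynchronous updates, and large-d (≈ 22) performance work are
  out of scope.
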