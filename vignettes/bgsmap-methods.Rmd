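---
title: "Predicting background-selection B-maps: models and numerical choices"
author: "bgsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting background-selection B-maps: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgsmap)
```

## The problem

Purifying selection at constrained sites (exons, regulatory elements)
reduces genetic diversity at linked neutral sites: lineages sampled near a
selected locus share part of their history with it, and the recurrent
elimination of deleterious variants shortens neutral coalescence times.
The per-site summary is the B-value, B = E[pi]/E[pi0], the expected
pairwise diversity relative to what it would be without linked selection.
`bgsmap` predicts B at a focal neutral site for arbitrary selection
strength s, recombination distance r, deleterious mutation rate u and a
piecewise-constant population-size history, and composes those pure
two-locus predictions into chromosome-scale B-maps.

Two models cover complementary regimes and are joined at a configurable
handoff (default |s| = 0.005):

* a **two-locus moment system** (weak to moderate selection, including the
  interference regime near 2Ns ~ -1 where classical theory is least
  accurate), and
* a **structured coalescent** with deleterious allelic classes (strong
  selection), extended to size changes with phase-type machinery.

## The moment system

### State and closure

Write p and q for derived-allele frequencies at the selected (left) and
neutral (right) locus, D for linkage disequilibrium, and y = 1-2p,
z = 1-2q.  Under neutrality, pairwise diversity obeys the closed pair of
recursions Delta E[pi] = 2u and Delta E[pi] = -E[pi]/2N.  Selection at a
linked site couples E[pi_R] to E[D(1-2q)] (Delta_s E[pi_R] =
2s E[D(1-2q)]), whose own dynamics pull in further moments.  The hierarchy
organizes into the classical two-locus families augmented by powers of
(1-2p): E[D^2 (1-2p)^j], E[D (1-2p)^j (1-2q)],
E[p(1-p)(1-2p)^j q(1-q)], E[pi_L (1-2p)^j].  Each order j couples only to
neighbors (j +/- 1 or 2), so the system is sparse, and naive truncation --
setting terms above a maximum order j_max to zero -- is accurate once
j_max is large enough.

Internally the package computes on the equivalent monomial families
y^a, y^a z^2, y^a z D, y^a D^2 (a = 0..j_max+2), with y^0 = 1 as the
constant coordinate that carries affine terms such as the neutral
mutational influx.  This representation is exactly closed under every
operator below; the reported moment basis (`build_basis`) is an exact
linear projection of it.  One subtlety motivates a modeling choice: under
*one-way* recurrent mutation at the selected locus the images of the
pi_L-type moments contain odd pure-y components that no finite combination
of the four families can represent, so that model cannot close.  Symmetric
recurrent mutation at rate u (y' = (1-2u) y, D' = (1-2u) D, z' = z)
closes the system exactly and shifts the mutation-selection balance only
from u/|s| to u/(|s|+2u), a relative O(p) change that is negligible for
every regime the package targets (p <= 1e-3).  `bgsmap` therefore uses
symmetric recurrent mutation in the operator, the forward simulator and
the exact-chain oracle alike.

### Operators

One generation is the product M = S R U D of per-force matrices acting on
the expectation vector (drift applied first in the cycle, selection last;
the multiplicative composition retains cross-terms down to O(u r s / 2N),
and reordering the factors moves predictions by less than 1e-3 of 1-B).

* **Selection** (genic, fitness 1+s on haplotypes carrying the derived
  deleterious allele) is linearized to first order in s:
  dy = -s(1-y^2)/2, dz = -2sD, dD = syD.  Validation against the exact
  Wright-Fisher chain shows the expected quadratic error decay in s.
* **Recombination** is exact and diagonal: D-carrying monomials scale by
  (1-r)^c.
* **Mutation** is exact and diagonal in the monomial basis (factor
  (1-2u)^(a+c)), plus the infinite-sites influx 2 u_right E[y^a] into
  E[pi_R y^a].
* **Drift** is the *exact* expectation under multinomial resampling of 2N
  haplotypes.  Rather than Stirling-number expansions (whose coefficients
  explode combinatorially and cancel catastrophically beyond j ~ 20), the
  package evaluates derivatives of the sampling generating function
  (sum_i x_i e^(theta_i))^(2N) with a two-operator recursion whose
  weights -- (2N - d - j)/2N, k/2N -- all lie in [0, 1].  Expectations of
  every monomial channel are produced in a single O(j_max^2) sweep, stably
  up to j_max of several hundred.  At 2N = 8 the operator matches the
  enumerated Wright-Fisher chain to ~1e-15.

### Solving, truncation and conditioning

The equilibrium is the fixed point v = Mv with the constant pinned to 1, a
sparse linear solve; time-dependence is plain sparse iteration with
per-epoch operators (epochs are piecewise constant, matching the model's
discrete generations).  With no deleterious input (u_left = 0) the pure-y
block is exactly conserved and the solver pins it to the no-deleterious
boundary y^a = 1.

The truncation order needed for convergence grows supra-linearly with
|2Ns|; empirically j_max ~ 2.5-3 x |2Ns| suffices, and `auto_truncation`
increases j_max in steps of 5 until B moves by less than 1e-6.  A
1-norm condition estimate of (I - M) guards the solve: beyond 1e12 the
package raises an error suggesting a lower j_max or the mutation-rescaling
option (solving with rates scaled by k and reading B on the
per-unit-mutation log scale, log(B)/k, which is invariant to k up to
O(k(1-B)^2)).  The moment path is used for |s| <= 0.005; beyond that the
structured coalescent takes over, and the two routes agree within ~1% of
(1-B) at the handoff (tested at s = -0.005, N = 1e4).

## Strong selection: structured coalescent and phase-type demography

At mutation-selection balance the deleterious-class frequency is
p = u/|s|, and a sampled pair occupies classes (2,0), (1,1), (0,2) by its
number of deleterious carriers, with per-generation transition
coefficients b12 = p r and b21 = (1-p)(|s|+r) and within-class pair
coalescence at rate 1/(2N f) for class frequency f.  The total
coalescence-rate multiplier is lambda = [b21^2/(1-p) + b12^2/p] /
(b12+b21)^2 >= 1, giving the classical equilibrium reduction
B = 1 - (u/|s|)/(1 + r/|s|)^2 independent of N.

For piecewise-constant histories, the B computation summarizes the class
structure by the total rate: within an epoch of size N the selected pair
coalesces as an exponential with rate lambda/(2N), so P(coal within
epoch) = P(no coal before) x (1 - exp(-lambda t / 2N)), the conditional
coalescence time within an epoch of length t is
t0 + 2N/lambda - ((1-P)/P) t, and the unbounded ancestral epoch
contributes t0 + 2N/lambda.  B is the ratio of the selected to the
neutral expected TMRCA for the same history.  A single unbounded epoch
then gives E[T] = 2N/lambda exactly (equilibrium B = 1/lambda, the
classical closed form up to O(p^2)); the neutral limit lambda -> 1 is
exact; B < 1 always; and the transient and equilibrium predictions are
mutually consistent, so demography-aware and equilibrium-assumed maps
re-converge once a new steady state is reached.  This matches the
mechanism the theory describes: linked selection acts as a uniform
increase of the pair-coalescence rate, so the linked process relaxes to
new demographic equilibria faster than the neutral one.

Two further design points.  First, the class order of the stationary
occupancy vector is [(1-p)^2, 2p(1-p), p^2] against transient states
[(2,0), (1,1), (0,2)], the only pairing consistent with
P(both free) = (1-p)^2.  Second, one could instead propagate the raw
phase-type survival of the 3x3 sub-intensity matrix (matrix exponential
per epoch; `epoch_coalescence_probabilities` exposes exactly this as the
class-occupancy diagnostic).  That survival carries O(p) class-structure
terms — the background-discordant state (1,1) is a coalescence refuge,
and the fast (0,2) channel is suppressed whenever 4Npr is small — which
the lambda description deliberately averages away and which the
lambda-based equilibrium anchor does not contain.  Mixing the two
descriptions leaves transient errors of order p in B, larger than 1 - B
itself wherever 1 - B < p (moderate selection at r >> |s|), and can push
the ratio above 1.  The all-lambda route avoids this class of artifact
entirely; the price is that genuine O(p) class-occupancy transients are
outside the model's resolution, which is acceptable because the regime
where they would matter is exactly where the moment system, not the
structured coalescent, is the intended engine.

## Discrete vs continuous time

The moment system is discrete (per-generation decay 1 - 1/2N) while the
coalescent formulas are exponential (exp(-t/2N)); the two differ by
O(t/N^2), about 2.6e-4 relative on a 10-fold decline sampled after 5,000
generations.  `neutral_pi0` therefore offers both conventions: the
discrete geometric form (default) matches the neutral moment iteration to
machine precision and defines Ne(t) = pi0(t)/4u for the equilibrium-map
comparisons; the exponential form underlies `coalescence_profile` and the
phase-type model, keeping each comparison like-for-like.

## Multi-locus B-maps

Chromosome-scale prediction composes pure two-locus effects
multiplicatively.  A lookup table stores B on an (s, r) grid for a given
demography: by default 35 selection coefficients from 0 to -0.001 (the
moment system) extended log-spaced to -1 (structured coalescent), and 72
recombination fractions from 0 to 0.5, with a reference mutation rate
u_ref = 1e-8.  Along each s-gridline B(r) is interpolated with a monotone
cubic Hermite spline in log-shifted r (the shift is half the smallest
positive grid value); monotone Hermite rather than an unconstrained cubic
spline because interpolated values must stay bracketed by the neighboring
nodes of the monotone data.  Off-grid s interpolates linearly in log|s|
between gridlines (linearly in |s| below the weakest nonzero gridline);
extrapolation in s is refused.

Constrained elements are split into chunks of at most 1,000 bp; each chunk
contributes B^(w_i n_sel) per DFE grid point, evaluated at the genetic
distance from the focal site to the chunk midpoint (cumulative
recombination map, capped at 0.5 without a mapping-function transform).
Within-chunk interference is neglected, which is accurate at this chunk
size.  Gamma DFE mass is assigned to grid points by integrating over cells
with edges at geometric midpoints of |s| (open-ended tail to the strongest
point); element-specific mutation rates enter on the log-B scale,
B = B_ref^(u_site/u_ref), the exponent form being consistent with
multiplicative composition and equal to linear (1-B) scaling to first
order.

## Interference correction

Dense constrained regions violate the independence assumption: elements
reduce each other's local Ne.  Since the dynamics depend on the compound
parameters Ne mu, Ne r, Ne s, the correction rescales every chunk's mu, r
and s by that chunk's own current B (computed from all *other* chunks,
its self-effect excluded) and re-predicts, iterating to a fixed point.
Convergence is measured as the largest change in any element B (stricter
at the drivers of the fixed point than a site-wise criterion) with
tolerance 1e-4; on the fully constrained 100 kb benchmark (N = 1e4,
u = r = 1e-8, s = -1e-3) it converges in about 4 iterations.  Rescaled s
below the strongest gridline is clamped to the grid edge.  Under
non-equilibrium demography no single rescaling represents the history of
linked selection, so the correction is refused for time-resolved tables
unless forced.

## DFE inference and the equilibrium-assumption bias

`fit_dfe` minimizes the mean squared difference between a predicted
equilibrium B-map and a target map over focal sites (the squared-log-B
objective is available; near B = 1 the two are equivalent), using
Nelder-Mead in log-parameter space with seeded jittered restarts.  The
fit is a best-case, noise-free self-consistency exercise: no genealogical
noise is simulated.  A least-squares objective is used throughout; no
likelihood is defined for this distance, so none is invented.

`bias_experiment` reproduces the equilibrium-assumption bias design: a
two-epoch history is followed after the size change; at each sampling time
the demography-aware map (moment iteration recording all times in one
pass per grid cell; phase-type for strong s) is contrasted with the
steady-state map predicted at the drift-effective size Ne(t) = pi0(t)/4u,
and optionally the Gamma DFE is re-fit under the equilibrium assumption.
On the 10 Mb fixture with a 10-fold bottleneck the mean |Delta B|
discrepancy peaks ~4,000-5,000 generations after the size change (when
most of the change in pi0 has occurred and Ne has fallen to ~2,000);
under a 10-fold expansion it grows throughout the 25,000-generation
window.  The handoff for these runs is lowered so
that the largest |2Ns| the moment system must resolve stays near 20,
keeping truncation orders (and runtimes) modest; the strong-selection side
is N-independent at equilibrium, which is what makes the experiment
tractable.

Two regime boundaries shape the reduced grids these experiments use.
Structured-coalescent gridlines start where selection is strong in the
*ancestral* epoch (|2 N_anc s| >= 20): the model's mutation-selection
class initialization is set there, and rows initialized at ancestral
Nes ~ -1 develop transient B marginally above 1 (an artifact of the
conditional-time approximation outside its regime) that the B <= 1 bound
would freeze into spurious steps.  Moment-system gridlines, conversely,
should not sit where a post-change epoch has Nes ~ -1 for long spans:
with recurrent mutation the true stationary state there includes
fixed-deleterious boundary mass approached on 1/u timescales, so an
"equilibrium" solve and a finite iteration legitimately differ.  Any band
between the two boundaries carries no gridline; its Gamma-DFE mass is
absorbed by the flanking geometric-midpoint cells.

## The synthetic layouts and what the tests do (and do not) show

`make_fixture` provides the three study layouts: a 10 Mb chromosome with
20 evenly spaced 1 kb elements (u = r = 1e-8 per bp,
nonsynonymous:synonymous 2.31:1 so constrained_fraction = 2.31/3.31), the
fully constrained 100 kb benchmark segment, and a seeded random layout for
property tests.  The default DFE in the worked examples is
Gamma(shape 0.215, scale 0.028105) on |s|, a human-exome-like
parameterization.  These fixtures emulate the *structure* of real
annotations (element density, uniform maps) but not their heterogeneity:
no real exon clustering, no empirical recombination-map hotspots, no
mutation-rate variation.  Passing tests therefore demonstrate internal
consistency of the models and their numerics under controlled conditions,
not predictive accuracy on any particular genome.

## Simulation oracles

Two independent oracles validate the operator machinery.  The exact
Wright-Fisher chain enumerates all haplotype-count states at 2N <= 12 and
applies the same deterministic maps followed by exact multinomial
transitions; drift, recombination and mutation operators agree with it to
machine precision, selection to O(s^2).  The forward simulator applies
deterministic selection/recombination/mutation to haplotype frequencies
and multinomial drift (a vectorized binomial chain across replicates),
with symmetric recurrent mutation at both loci.  Because pi_R's
genealogical coefficient of variation is large at small 4Nu, a useful
comparison needs the signal 1-B well above the Monte-Carlo error: the
suite runs the *matched* finite-alleles model (the operator's
`right_recurrent` variant, so simulator and moment system share the exact
same mutation model) at N = 300 with rescaled parameters 2Ns = -12,
4Nu_left = 1.2, giving 1-B ~ 1.8%, and estimates pi_R by per-replicate
time averages over 5,000 independent replicates (honest standard errors
~0.3%, since replicates are independent while consecutive snapshots are
not).  The simulated B agrees with the moment prediction within the
Monte-Carlo error, the residual being consistent with the first-order
selection linearization at s = -0.02.

## Problem sizes and determinism

All randomness (simulator, optimizer restarts, random layouts) flows from
explicit seeds, and identical seeds give bitwise-identical outputs.  The
shipped analyses use reduced grids chosen for numerical adequacy: the
dense-benchmark and fit examples use ~8-17 selection gridlines and 20-25
recombination gridlines (interpolation error well below the assertion
tolerances), focal-site strides of 10-50 kb on the 10 Mb layout, and the
bias experiments sample every 500 generations over 25,000.  Grid
refinement changes the reported quantities by less than the tolerances
asserted in the test suite.

## Known limitations

* Selection acts genically at the left locus; dominance is not modeled.
* The focal site itself is assumed neutral in the pure two-locus model;
  multi-locus reciprocal effects enter only through the heuristic
  interference rescaling, which is restricted to equilibrium demographies.
* Single population only: no structure, migration or admixture.
* u, s and r are constant within an epoch; piecewise changes in them
  (which the phase-type machinery could accommodate) are not implemented.
* LD statistics (E[D^2] and relatives) are computed internally but are
  not part of the product surface.
* The moment path is limited to |s| <= 0.005 and practically to
  |2Ns| of a few hundred by truncation-order growth; beyond, the
  structured coalescent is the intended tool.
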