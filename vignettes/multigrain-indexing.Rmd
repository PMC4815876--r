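---
title: "Multigrain indexing of multiphase diffraction data: model, parameters and design"
author: "mgindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigrain indexing of multiphase diffraction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mgindex)
```

## The problem

A rotating polycrystalline sample in a monochromatic beam produces, after
spot harvesting, a pool of scattering vectors $\mathbf{g}_i$ (units
$\mathrm{\AA^{-1}}$, crystallographic $1/d$ convention, no $2\pi$) in a
Cartesian frame fixed to the sample. Each grain $g$ of the polycrystal
contributes the reciprocal-lattice points of its own lattice,
$\mathbf{g} = \mathbf{h}^\mathsf{T} B_g$ for integer $\mathbf{h}$, within
the observable shell $q_\min \le |\mathbf{g}| \le q_\max$; measurement
error enters as additive Gaussian noise with standard deviation $\sigma$
per Cartesian component. `mgindex` inverts this map: from the pooled,
unlabeled $\{\mathbf{g}_i\}$ it recovers, grain by grain, a direct basis
$A_g$ (rows = lattice vectors, $A_g B_g^\mathsf{T} = I$) and the set of
reflections belonging to the grain — with no prior knowledge of unit
cells, symmetries, or even how many phases are present. Intensities are
never used.

## The comb filter

The detector primitive is a one-dimensional lattice test. Projecting the
pool on a unit direction $\hat{u}$ gives $x_i = \mathbf{g}_i \cdot \hat{u}$.
If $\hat{u}$ is parallel to a direct-lattice vector $\mathbf{a}$ of some
grain, that grain's projections are integer multiples of
$d^* = 1/|\mathbf{a}|$. Membership in the comb of half-width $\varepsilon$
and spacing $d^*$ requires the nearest nonzero node $n d^*$
($|n| d^* \le q_\max$) to lie within $\varepsilon$ of $x_i$; since
$d^* > 2\varepsilon$, at most one node qualifies. The score subtracts the
count expected if all reflections were placed uniformly at random in the
shell $[q_\min, q_\max]$, using the exact marginal density of a projected
shell point,
$$p(x) = \frac{3\left[(q_\max^2 - x^2)_+ - (q_\min^2 - x^2)_+\right]}
             {4\,(q_\max^3 - q_\min^3)},$$
integrated over the boxes in closed form. The comb deliberately has **no
origin node**: every direction receives the central bulge of the projection
histogram, so counting it would reward arbitrary directions. (Where the
comb is used to *compare lattice directions on a fixed subset* — basis
determination, below — the central plane is counted, because a zero
projection is fully consistent with the direct vector and short vectors
hold a sizable share of their subset in that plane; ignoring it would bias
the comparison toward long vectors.)

The spacing is scanned from $d^*_\min$ to $d^*_\max = q_\max/2$ on an
adaptive grid with step $\varepsilon / \lfloor q_\max / d^* \rfloor$, so
the comb node furthest from the origin moves by at most $\varepsilon$ per
step and no 1-D lattice can be skipped. The scan over thousands of
directions is evaluated by interval accumulation (each reflection-harmonic
pair contributes one contiguous spacing interval on the grid), implemented
in C++.

## Direction refinement: the least-squares snap

With $N_{u1}$ random directions on the hemisphere, the best sampled
direction is typically a few tenths of a degree off a lattice direction —
close enough to catch reflections near the inner comb nodes, far too coarse
to catch the outer ones (the projection error of reflection $i$ is
$|\mathbf{g}_{i\perp}| \theta$). A grid search fine enough to close that
gap would need sub-$0.05°$ resolution over degrees. Instead, the comb's own
membership supplies node numbers $n_i = \mathrm{round}(x_i / d^*)$, and
$$\min_{\mathbf{y}} \sum_i (\mathbf{g}_i \cdot \mathbf{y} - n_i)^2,
\qquad \hat{u} = \mathbf{y}/|\mathbf{y}|,\; d^* = 1/|\mathbf{y}|,$$
solved in closed form, snaps the pair onto the 1-D lattice; membership is
re-collected and the fit iterated while the score improves. Because the
assignments $n_i$ stay correct as long as projection errors are below
$d^*/2$, the snap converges from far outside the comb tolerance. It is
applied to **every** scanned direction before the ten best candidates are
kept (a raw-score ranking would be dominated by harmonic locks — combs at a
multiple of the spacing of a long direct vector — which snap to nothing
better), and the conventional local grid search (9×9×9 over two tilt axes
and the spacing) runs on the kept candidates as a final polish.

Candidate member sets are extracted *with* the central plane
($|x_i| \le \varepsilon$), so a first-pass candidate of a single grain holds
essentially all of that grain's reflections. A second pass per candidate
(fresh directions at more than `minAngleDeg` from the first, boxes widened
by `epsilon2Factor`) re-runs the machinery on the subset alone and keeps
only the members of its best comb, shedding reflections of other grains
that fell into the first comb by chance.

## Basis determination and validation

For each cleaned subset, candidate plane normals are the normals of planes
through triples of the 50 reflections closest to the origin (near-collinear
triples discarded at a relative cross-product threshold of 0.01; directions
merged within 1°, then re-polished by the least-squares snap — a single
noisy triple fixes a direction only to $\sim 0.1°$, which is enough to
scramble comb counts at $\varepsilon = 5\times10^{-4}$). Along each
direction the possible spacings are the projected values themselves
(clusters within $\varepsilon/2$ collapsed to their median); the chosen
spacing is the **largest** whose count is within 80% of the per-direction
maximum (sub-multiples index the same reflections), and directions whose
count falls below 80% of the global maximum are dropped. Survivors map to
direct vectors $\hat{u}/d^*$.

The basis is the independent trio of **minimal cell volume** among the
shortest candidates (independence: triple product above 0.01 times the
product of lengths). The three shortest independent vectors alone can span
a doubled cell whenever one short lattice vector escaped detection; the
minimal-volume trio is the primitive cell of whatever lattice the
candidates support. The basis is validated against the *full* active pool:
all reciprocal-lattice points with $|\mathbf{g}| \le q_\max + 5\varepsilon$
are enumerated and each is assigned its nearest active reflection if closer
than $5\varepsilon$, conflicts resolved greedily by distance so assignments
are one-to-one. Among the $N_j$ candidates the hypothesis matching the most
reflections wins — with counts within 5% of the best treated as ties
resolved toward the smaller cell volume, because a multiple-volume cell
(denser reciprocal lattice) matches everything the true cell does plus a
few chance coincidences and must not win by that margin.

## Cell correction, refinement, peeling

The minimal-cell heuristic can still land on a sub-cell (a fraction of the
true volume, indexing only a fraction of the grain). The supercell check
re-indexes against every distinct volume enlargement by factors 2 and 3 —
the 7 + 13 Hermite-normal-form sublattice transforms, which exhaust the
distinct lattices reachable by integer combinations with those
determinants — and accepts the best iff it matches >20% more reflections,
repeating at most twice (volume factors up to 9). Shrinking corrections are
not attempted; the volume tie-break above prevents the over-large case
upstream. The accepted basis is refined by linear least squares on its
assignments ($\min_B \sum_i |\mathbf{h}_i^\mathsf{T} B - \mathbf{g}_i|^2$),
re-indexed, and refined once more so late-joining reflections inform the
final basis. Accepted grains (at least `minReflections` = 20 matches) have
their reflections marked inactive; the outer loop repeats until $N_t = 20$
consecutive failures or fewer than `minReflections` active reflections
remain. The recovered basis is a primitive cell of the grain's lattice in
an arbitrary setting; standard (Niggli-style) cell reduction is out of
scope, and all reported quantities (volume, assignments) are
setting-independent.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `epsilon` | 5e-4 | 1/Å | comb box half-width; slightly above the positional noise |
| `qMax` | 0.6 | 1/Å | outer data radius |
| `dstarMin` | 0.1 | 1/Å | smallest scanned spacing (below `qMin`); bounds detectable direct vectors at 1/`dstarMin` |
| `dstarMax` | `qMax/2` | 1/Å | largest useful spacing (two nodes in range) |
| `nU1`, `nU2` | 10000, 5000 | — | random directions per pass |
| `nJ` | 5 | — | candidate subsets carried to basis determination |
| `epsilon2Factor` | 2 | — | second-pass box widening |
| `minAngleDeg` | 10 | deg | second-pass exclusion cone |
| `minReflections` | 20 | — | acceptance threshold per grain |
| `nT` | 20 | — | consecutive-failure stopping rule |
| `sigma` | 1e-4 | 1/Å | simulator noise per Cartesian component |

Defaults reproduce the cementite study parameterization; the granite
studies use `qMax = 0.5`, `dstarMin = 0.05`.

## The simulator, and what passing tests do not show

`simulatePool()` draws Haar-uniform orientations, enumerates every
reciprocal-lattice point in the shell (both Friedel mates; per-axis bound
$|h_i| \le q_\max |\mathbf{a}_i|$), and adds i.i.d. Gaussian noise per
component. It deliberately models **no** diffraction geometry: no Ewald
construction, rotation range, detector blind regions, spot overlap, or
intensity thresholds, and reflection conditions default to none (the
indexing is symmetry-agnostic; a centering predicate is provided for
robustness experiments). Consequently per-grain reflection counts differ
from instrument-realistic simulations, grains of one phase all contribute
equally, and success on these scenes does not demonstrate robustness to
partially harvested or overlapping spots — only the paper-level claims
about the indexing mathematics: recovery of cells and assignments from
pooled positions, independence from phase count, and the noise/volume
accuracy relation. Grain-size distributions and intensity effects are
likewise out of scope.

## Numerical choices and degenerate inputs

Spacing-scan ties break toward larger $d^*$ (a sub-multiple indexes the
same members against more background). The background uses the shell, not
the ball; with $q_\min = 0$ the two coincide. All randomness flows through
R's RNG: simulation scenes seed from `SimulationConfig@seed`, indexing runs
from `IndexingConfig@seed` (the replication harness offsets the two so the
streams are unrelated), making every run byte-reproducible. Degenerate
inputs are handled explicitly: empty pools index to empty results; subsets
under 4 reflections are rejected in cleaning; fewer than 3 candidate
normals, or no 3 independent direct vectors, abort a candidate (the loop
simply retries with fresh directions); rank-deficient assignment sets raise
an error in `refineBasis()`; structureless (uniform-random) pools fall
below `minReflections` and produce no grains.

## Problem sizes used in the checks

The full-scale studies (500 cementite grains at $N_{u1} = 10^4$; 200
mineral grains) are multi-day computations; the package's replication
harness (`simulationStudy()`) runs 25 cementite grains and a
4-phase × 5-grain granite scene at $N_{u1} = 3000$, $N_{u2} = 1500$, three
seeded replicates each — a few minutes per replicate on one CPU — and
computes the same four figures of merit: fraction of grains successfully
identified (volume within 1% of nominal *and* strictly more than 90% of the
grain's reflections recovered), mean relative volume deviation over
successes, mean per-grain completeness, and mean per-grain
false-attribution fraction. Completeness and false-attribution averages are
computed over all indexed grains (spurious, unmatched grains enter with
completeness 0), with the same means over successful grains only reported
alongside.

## Known limitations

Detectable direct vectors are bounded by $1/d^*_\min$; lattices whose three
shortest independent vectors all exceed that length cannot be indexed at
the given scan range. Very small grains (fewer than `minReflections`
reflections in the shell) are invisible. Severely overlapping pools (many
thousands of grains) raise the chance-coincidence floor of the validation
step, which the 5% volume tie-break only partially mitigates. The recovered
setting is primitive but not reduced; downstream symmetry analysis should
reduce the cell first.
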