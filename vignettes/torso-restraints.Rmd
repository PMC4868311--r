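---
title: "Knowledge-based dihedral restraints for the HCDR3 torso: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based dihedral restraints for the HCDR3 torso: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3torso)
```

## The problem

The heavy-chain CDR3 (HCDR3) is the most sequence- and length-diverse loop
of the antibody paratope and the one that de novo loop modeling handles
worst. Its base, however, is far more regular than its apex: the first
three (T1--T3) and last four (T4--T7) residues -- the *torso* -- adopt one
of two canonical conformations, *bulged* (the common form, in which a
side-chain interaction, typically Arg/Lys at T2 with Asp at T6, pushes the
C-terminal strand out of regular beta pairing) or *non-bulged* (beta
pairing intact). Generic loop samplers rarely visit the bulged geometry on
their own. This package turns the observed regularity into backbone
dihedral restraints that an external modeling engine (Rosetta) can consume,
and provides the metrics needed to judge the resulting models.

## Circular statistics of torso dihedrals

Backbone phi/psi angles live on the circle, so per-position summaries use
the circular mean

$$\bar\alpha = \mathrm{atan2}\!\left(\sum_n \sin\alpha_n,\; \sum_n \cos\alpha_n\right)$$

and the approximate circular standard deviation
$\sigma \approx \sqrt{2\,(1 - R)}$ (radians), where
$R = \lVert \frac1n \sum_n (\cos\alpha_n, \sin\alpha_n) \rVert$ is the mean
resultant length. This is the standard small-dispersion approximation; the
exact directional-statistics form $\sqrt{-2\ln R}$ is available through the
`variant` argument of `circ_std_approx()` and agrees with the default to
first order for the concentrated samples ($\sigma \lesssim 60^\circ$) seen
in torso classes. The mean is undefined when $R$ is numerically zero
(guard: $R < 10^{-9}$ raises an error rather than returning an arbitrary
direction).

Two mathematical points that shaped the tests: the circular mean equals the
arithmetic mean only for two-point or symmetric samples (the discrepancy is
second order in the arc width), and a torsion angle is *invariant* under
reversal of its four-atom order -- its sign flips under mirror reflection,
not reversal.

## Reference profiles and the psi(T4) exclusion

`reference_torso_profile()` ships the per-position circular summaries for
the bulged (n = 218) and non-bulged (n = 38) classes obtained from human
and mouse antibody crystal structures clustered at a 2 A radius. The two
classes are separated almost entirely by psi(T6): about $-30^\circ \pm 26$
bulged versus $+129^\circ \pm 24$ non-bulged. psi(T4) is bimodal *within*
both classes, with modes roughly 180 degrees apart; its class mean is an
artifact of mode mixing, so it is excluded from restraint derivation and
classification (`excluded = "T4:psi"`). A bulged derivation therefore
always yields 13 restraints: 7 phi + 6 psi.

## Restraints

`derive_restraints()` maps T1--T3 to the first three and T4--T7 to the last
four HCDR3 residues of the caller's numbering, and emits one
circular-harmonic restraint per non-excluded measurement:
penalty $= (\Delta/\sigma)^2$ with $\Delta$ the circular difference to the
class mean. The serialization is the Rosetta constraint dialect, one line
per restraint, radians at six decimals:

```
Dihedral C 99 N 100 CA 100 C 100 CIRCULARHARMONIC -2.530727 0.157080
```

Tunable parameters:

* `min_sigma` (degrees, default 1): floor on the restraint width. A
  single-member or degenerate class would otherwise emit zero-width
  restraints with infinite penalty gradients.
* `start`, `length`: target numbering. Pose numbering differs between
  engines, so the offset is always explicit.

Non-bulged profiles run through the same machinery, but only bulged
restraints have been validated against benchmark modeling; deriving
non-bulged restraints is supported and flagged as such in the
documentation.

## Classification

Class assignment of a *single* new torso is an extension beyond the
clustering route used to build the profiles: `classify_torso()` computes,
per class, the root-mean-square of circular deviations standardized by the
class standard deviation over all measured non-excluded angles, assigns the
nearer class, and *gates* the call on psi(T6) -- the measurement that
actually discriminates -- lying within `sigma_mult` (default 3) class
standard deviations of that class's mean. Failing the gate yields
`indeterminate` with a reason, never a guess. The statistic is invariant to
relabeling angles by multiples of 360 degrees, and flipping the bimodal
psi(T4) by 180 degrees cannot change the label because the measurement is
excluded.

The torso-base pseudo-angles alpha101 (pseudodihedral over the C-alpha
atoms of T5, T6, T7 and the first framework-4 residue) and tau101 (planar
angle at the same base) are provided for window checks against externally
published bulged-geometry means. The tau101 atom triple (CA of T6, T7,
FR4) is this package's choice, anchored at the torso base consistently with
the alpha101 quadruple; the literature defining these angles does not print
an atom-level definition here, and the reference window means/sigmas are
therefore mandatory configuration for `in_bulged_window()` -- the package
deliberately ships no defaults for them.

## Clustering

Both use cases -- separating bulged from non-bulged fragments and grouping
decoy loop conformations -- use one greedy most-neighbors algorithm
(`greedy_cluster()`): compute all pairwise superposition RMSDs (Kabsch,
proper rotations only), repeatedly promote the item with the most
neighbors within the radius (ties: lowest input index, for
reproducibility), remove it and its neighbors, and iterate. This is the
shared semantics of the center-based clustering tools common in structure
prediction; their pruning heuristics are performance devices, not part of
the model, and are out of scope. Fragment clustering operates on the
concatenated T1--T3 + T4--T7 backbone (N, CA, C; carbonyl O included only
when present in all seven residues), decoy clustering on loop C-alpha
coordinates.

`cluster_decoys()` drops clusters holding less than `min_fraction`
(default 1 percent) of the models. The boundary is inclusive -- size
exactly `ceiling(min_fraction * N)` survives, i.e. 10-or-more for 1000
models -- which is the consistent reading of the two phrasings of the rule
("more than 1 percent (10 or more)" versus "less than 1 percent omitted").
For model counts that are not multiples of 100 the `ceiling()` reading is
the stricter and is documented here as the package's convention.

## Decoy evaluation

Loop accuracy is the C-alpha RMSD of the loop after superposing model onto
native on the *framework* C-alpha atoms (all residues outside the loop),
without re-fitting on the loop -- the standard convention in antibody
modeling, which charges rigid-body displacement of the loop to the loop.
Loop-local superposition would measure internal geometry only; it can be
obtained by calling `superpose_rmsd()` on the loop coordinates directly.

Lengths are made comparable with RMSD16, the logarithmic length
normalization rescaled to a 16-residue reference:
$\mathrm{RMSD16} = \mathrm{RMSD} / (1 + \ln\sqrt{L/16})$. The source
benchmark never prints its normalization formula; this package adopts the
Carugo--Pongor correction (the standard published RMSD length
normalization) because it has the required fixed point at L = 16 and
inflates short-loop RMSDs as the metric's usage implies. It is exposed as
a plain function so an alternative normalizer can be substituted upstream
of every metric.

Metric conventions, following each source caption verbatim where they
differ: counts of native-like models use strictly `RMSD16 < 2` A; funnel
labels use `RMSD16 <= 2` A. Blue = top 10 percent by score
(`ceiling(0.10 N)`, ties at the cut broken by model id) *and* native-like;
red = neither; gray otherwise. Labels are rank-based and therefore
invariant under monotone transforms of the score. The "correct" cluster is
the surviving cluster with the lowest average score -- the choice a blind
prediction would make -- reported with dense ranks of size (1 = largest)
and average RMSD16 (1 = best), a `1*` flag when only one cluster survives,
and an explicit not-available state when none does.

## Synthetic fixtures: what they do and do not show

`build_backbone()` places N/CA/C atoms by torsion-driven chain extension
(NeRF) with ideal Engh--Huber-style internal coordinates (N-CA 1.458 A,
CA-C 1.525 A, C-N 1.329 A; N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7
degrees), so measured torsions reproduce the specification to better than
1e-6 degrees -- the round-trip oracle behind every angle measurement test.

`sample_class_torsos()` draws each non-excluded angle independently from a
wrapped normal at the profile's (mean, sd) -- adequate for sd up to about
60 degrees -- and realizes fragments as 3D chains with nine extended head
residues (an HCDR3 of 16 residues, the repertoire-typical length); the
excluded psi(T4) is drawn from an equal mixture of modes 180 degrees
apart. `make_decoy_set()` perturbs loop torsions with wrapped-normal noise
and assigns scores `a * RMSD16 + b + N(0, noise)`, recording ground truth.

These generators emulate the *statistical* structure of the study
conditions (class-conditional dihedral dispersion, bimodal psi(T4), a
score--accuracy funnel), not crystallographic reality: no side chains, no
correlated neighbor deviations, ideal geometry, and decoy loops are not
re-closed onto the framework. Passing tests therefore demonstrate that the
statistics, restraints and metrics behave correctly under known ground
truth -- not that any particular real antibody will be modeled accurately.
One practical consequence surfaced by the generator: independent
wrapped-normal draws at the full class dispersions (sds up to 49 degrees,
plus T4 flips) scatter fragments beyond a 2 A cluster radius, unlike real
structures whose deviations are correlated; the end-to-end clustering test
therefore draws tightly around the class means and leaves
dispersion-robustness to the classifier and penalty tests, which use the
full dispersions.

## Numerical choices

* Angles are degrees at every API boundary, radians internally and in the
  Rosetta serialization; wrapping convention (-180, 180].
* Coincidence tolerance 1e-6 A (far below the 1e-3 A precision of PDB
  coordinates); collinear central triplets raise errors rather than
  returning 0.
* Kabsch superposition via SVD with the determinant correction, so
  reflections are never returned; clustering ties break toward the lowest
  input index.
* Altloc resolution keeps the highest occupancy (ties: first encountered);
  residues missing any of N/CA/C are dropped at read time with a warning,
  while individual unmeasurable angles are dropped at measurement time --
  reading imperfect files must not silently shift the numbering that
  definitions refer to.
* Problem sizes used by the test and acceptance runs: circular recovery at
  the class sample sizes (218/38), 200-fragment classifier recovery,
  decoy sets of 40--200 models, clustering oracles on up to 10 items.
  These sizes make every check self-contained and fast while keeping the
  statistical assertions (recovery within a few degrees, 95 percent label
  recovery) meaningful.

## Known limitations

* HCDR3 auto-location (`locate_hcdr3_imgt()`) is anchor-motif based (last
  Cys before a Trp-Gly-x-Gly) and returns an explicit no-call on
  ambiguity; it is not a full IMGT numbering engine. The curated
  definitions table is the authoritative path, and structures with
  multiple Fv copies per asymmetric unit must be disambiguated there.
* The closed-form classifier is this package's construction; the reference
  classes themselves were defined by clustering.
* The package emits restraints for and evaluates the output of an external
  modeling engine; it does not sample loop conformations itself, and
  headline modeling-improvement numbers that require running that engine
  over a 28-antibody benchmark are out of its scope.
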