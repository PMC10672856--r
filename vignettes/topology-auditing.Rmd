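---
title: "Auditing the backbone topology of predicted protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the backbone topology of predicted protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

About 2% of solved protein structures carry a knot on their polypeptide
chain, and each knotted family reproducibly forms one specific knot type —
mostly the trefoil (3_1), occasionally 4_1, 5_2 or the Stevedore knot 6_1.
Deep-learning structure predictors, however, assemble their models by
moving residues freely in space (a "residue gas") and only restore
stereochemistry at the end. Nothing in that procedure respects the mutual
impermeability of chain segments, so a predictor can emit geometries whose
topology no folding process could reach — for example a tandem repeat of a
small trefoil-knotted domain predicted to fold into ten consecutive
knots, or two sequence copies of a domain placed on top of each other.
Per-residue confidence scores do not catch this: each knotted core looks
locally native, so pLDDT stays high while the global topology is
impossible.

`knotscope` takes a model (PDB/mmCIF, or a bare Calpha polyline), works
out its knot content, decomposes composite knots into consecutive prime
factors, and asks a concrete question: *could the known mechanisms of
protein knot formation produce this arrangement?* Anything that fails is
red-flagged for the modeller.

## Knot type of an open chain

A linear chain has no knot type until its ends are joined. We close the
chain through a point drawn uniformly on a sphere of radius 12x the
chain's bounding-box diagonal (effectively "at infinity"; anything at or
above 10x behaves identically), do this `n_closures = 100` times, and
report the majority label with its vote fraction as a confidence. Direct
end-to-end closure is available but misleads whenever an endpoint is
buried inside the globule, which is exactly the situation in knotted
cores; the stochastic consensus is the default for that reason.

Each closed loop is simplified by KMT reduction — a vertex is deleted
whenever the triangle it spans with its neighbours is crossed by no other
segment of the chain, which preserves ambient isotopy — and then
projected along a random direction to build a crossing diagram
(projections with coincident or grazing crossings are rejected and
redrawn; crossings closer than 1e-9 in projected arc position force a new
direction). From the diagram we form the Alexander crossing-relation
matrix and evaluate the Alexander polynomial:

* `|Delta(-1)|` (the knot determinant) is computed as a single modular
  determinant for every closure;
* the full polynomial — determinant of the matrix minor over Z[t],
  computed by evaluation and interpolation modulo the Mersenne prime
  2^31 - 1, with the trailing power of t stripped and the sign fixed by
  Delta(1) = +/-1 — is extracted only when the determinant alone is
  ambiguous (4_1 vs 5_1 at 5, 5_2 vs 7_1 at 7, 6_1 vs 3_1#3_1 at 9, ...),
  and is then evaluated at t = -2.

The pair `(|Delta(-1)|, |Delta(-2)|)` is looked up in a table covering
the primes 0_1, 3_1, 4_1, 5_1, 5_2, 6_1, 6_2, 6_3, 7_1, all their
pairwise connected sums, trefoil sums up to 12 factors, and mixed sums of
up to two trefoils with one other prime. Within this scope the pair is
unique (a unit test asserts it). Both invariants are multiplicative over
connected sums, which is what makes composite tandem-repeat labels such
as `3_1#3_1#3_1` directly readable. Two caveats are inherent to the
choice of invariant: the Alexander polynomial is blind to chirality (all
labels are achiral), and knots outside the table — or with
Alexander polynomial 1, like untwisted doubles — report as `unknown`
rather than being guessed.

Why Alexander and not Jones/HOMFLY: determinant evaluation is polynomial
in the crossing number, exact in modular arithmetic, and separates every
knot the package claims to handle; the skein-based polynomials would add
exponential cost for no added discriminating power at this scope.

## Fingerprint, cores, slipknots, depth

`knot_fingerprint()` classifies every subchain whose endpoints lie on a
stride-5 index grid (plus the exact chain ends). The default stride keeps
the subchain count quadratic-but-tractable; cores are consequently
located to within one stride of their true boundaries, which is ample for
depth calls against a 20-residue threshold. `find_cores()` then scans
left to right, repeatedly taking the shortest prime-labelled interval
(ties leftmost, consensus probability at least `core_prob_min = 0.5`)
whose removal lowers the factor count of the remaining right part by
exactly one, then refining by a one-stride local search to the most
confident qualifying neighbour (a minimal interval can clip the core
boundary and dilute the closure consensus). Published tools differ by
+/-1 residue in their core
boundary convention; ours is "first/last residue of the minimal knotted
grid interval", and boundary positions should be read with the stride in
mind.

A factor's depth is its distance to the chain end (terminal factors) or
to the neighbouring core boundary (internal factors); knots deeper than
20 residues on both sides are *deep* — the conventional cutoff between
knots formable by a terminal threading event and knots that require long
segments to be pushed through a loop. The threshold is exposed as
`deep_threshold`.

A *slipknot* — knotted subchain inside an unknotted chain — is what a
correctly folded tandem repeat of a shallowly knotted domain should
produce instead of a string of complete knots. `detect_slipknots()`
reports maximal knotted subchains of chains whose full-length label is
0_1, and `find_cores()` flags them rather than counting them as factors.

## The feasibility rules

The known routes to a protein knot are: threading of a terminal tail
(one knot per terminus, almost always shallow), co-translational folding
with a twisted loop held at the ribosome exit tunnel (one deep knot; two
such loops cannot coexist at one tunnel), and domain swapping (one knot).
Combining them bounds what a real chain can do, which we encode as hard
rules: more than three consecutive factors (R1), more than one deep
factor (R2), three factors without a central deep knot (R3), or more
than one factor buried away from both termini (R4) each make a geometry
`implausible`. Exactly three factors arranged shallow-deep-shallow pass
but carry an `at_mechanism_limit` flag (S1). The rules are deliberately
hard rather than probabilistic: the tool's job is red-flagging, and every
threshold is a visible, documented parameter.

"Terminal" is operationalised as a core boundary within `terminal_margin
= 40` residues of a chain end. This is the rule set's main free
parameter: no number is stated for it in the mechanism argument, and 40
residues is our choice of a tail length that a terminus can plausibly
drag through a loop; users auditing unusually large domains should widen
it.

## Red-flag detectors

**Loop occlusion.** For a knot to form, a chain segment must physically
pass through the twisted loop. We fit a plane to the loop's Calpha ring,
find the thread segment piercing the ring polygon, and measure the
clearance: the smallest (distance from the threading axis to a loop
heavy atom) minus that atom's van der Waals radius (C 1.70, N 1.55,
O 1.52, S 1.80 angstrom). Verdicts: `open` above 2.8 angstrom (a water
diameter — the loop could hydrate while threading), `tight` down to 1.0
angstrom, `blocked` below (hard-clash scale). A static structure cannot
prove threading impossible, but a blocked loop in a *predicted* model
means the predictor drew a knot whose formation path it cannot defend;
the thresholds are anchored to those two physical scales rather than
fitted to anything.

**Domain overlap.** For each pair of domain spans we report the centroid
distance divided by the sum of the radii of gyration, and the number of
inter-domain Calpha pairs closer than 4.0 angstrom. A pair is `overlaid`
when the score drops below 0.5 with clashes above 10% of the smaller
domain's length — the signature of two sequence copies placed in one
spatial location.

**Confidence masking.** `confidence_profile()` summarises pLDDT with the
standard bands (>= 90 high, >= 70 good). The flag worth watching is
`masking`: global mean >= 70 *and* an implausible topology verdict.
B-factor columns are treated as pLDDT only when every value lies in
[0, 100]; crystallographic B-factors never masquerade as confidence.

## Synthetic fixtures: what they emulate and what they do not

Every topology operation is testable without a predictor run or a
download. `generate_knot()` samples closed curves of known type — torus
parametrisations T(2,3), T(2,5), T(2,7) for 3_1/5_1/7_1 (whose Alexander
values have closed forms: q at t = -1, 2^q - 1 at t = -2), the standard
figure-eight space curve for 4_1, and Lissajous curves for 5_2
(frequencies (2,3,7), phases (0.3, 1.5, 0)) and 6_1 ((2,3,5), phases
(0.9, 0.9, 0)). The two Lissajous identifications are rigorous: each
admits a 6-crossing diagram, and among knots of crossing number <= 6 the
invariant pairs (7,16) and (9,20) occur exactly once — which also rules
out Alexander coincidences such as 9_46. 6_3 has no convenient
low-harmonic parametrisation; it stays in the classification table but
has no generator.

The curve is cut open at a seeded location. Because the knot type of an
open chain genuinely depends on where the closed curve is cut (cutting
inside a clasp region unties part of the knot), the generator verifies
each candidate cut — cut, grow straight escape tails along
maximal-clearance directions, resample to `n_points` at 3.8 angstrom
mean spacing — and rejects cuts that fail to reproduce the requested
type, taking the next seeded candidate. Gaussian coordinate noise is
added last. Defaults (`open_fraction = 0.05`, noise up to 0.5 angstrom,
~3.8 angstrom spacing) were fixed once to mimic Calpha geometry at the
fidelity the reduction and closure machinery sees in real traces.

`concat_knots()` emulates the tandem-repeat constructs used to probe
predictors — trefoil units joined by 9-point straight linkers, by
default, matching the nine-glycine linkers of the corresponding wet-lab
style constructs (linker lengths 1–17 are the tested range in
`construct_spec()`). Units are laid out along an axis with disjoint
bounding boxes, so the ground-truth factor list is exact by
construction.

What passing these tests shows: the invariant machinery, decomposition
and rules behave correctly on chains with Calpha-like geometry and known
topology, including noisy ones. What it does not show: robustness to
real-model pathologies such as low-confidence spaghetti regions, chain
breaks (those are refused, not classified), or sub-angstrom clashes;
and verdicts concern mechanism-compatibility of a geometry, never
whether a real protein folds.

## Numerical choices and degenerate inputs

* Projection degeneracy (near-parallel segments, crossings within 1e-9
  of a vertex or of each other, depth ties below 1e-7 of the z-range)
  forces a new seeded direction; 64 retries per closure before erroring.
  Exact 3D incidences — a vertex lying on another segment, as perfectly
  straight linkers produce — defeat every projection, so after each 16
  degenerate projections the loop is nudged by a deterministic jitter of
  1e-6 of its diameter, far below any topological clearance of
  angstrom-scale chains.
* Modular arithmetic uses p = 2^31 - 1; polynomial coefficients are
  centred lifts, exact while |coefficient| < p/2 — satisfied by orders
  of magnitude across the table's scope (a 12-fold trefoil sum's largest
  coefficient is ~7e4).
* Chains that reduce to two points are straight segments; every closure
  of them is the unknot, and the closure loop is skipped.
* (Near-)collinear input chains classify as 0_1 without projection.
* Broken traces (unbridged gaps, consecutive Calpha distances outside
  2.0–4.5 angstrom) are refused by topology operations; gap bridging
  interpolates at most `max_bridge = 3` missing residues, because longer
  interpolation can silently change the very topology being audited.
* Ties in the consensus vote break toward the smaller determinant
  (hence the simpler knot); ties in core selection break shortest, then
  leftmost. Both make reports reproducible bit for bit under a fixed
  seed.
* Voting stops early once the first `min(30, n_closures)` closures agree
  unanimously (`early_stop = TRUE`); the reported probability then
  refers to the closures actually evaluated. Disable it to force the
  full closure budget.

## Problem sizes

The test-suite and acceptance runs use tandem constructs of ~100-residue
trefoil units for k = 3, 5, 10 repeats (up to ~1100 residues), stride-5
fingerprints with 100 closures, and 50 noisy recipes per knot type for
the accuracy sweep; a full k = 10 audit takes about two minutes on one
core. These sizes are the package's chosen study conditions, matching
the repeat counts of the constructs it reproduces.

## Known limitations

* Chirality is not resolved (Alexander invariants cannot see it).
* Labels outside the table scope report `unknown`; factor counting stops
  with an `unresolved` row and the verdict becomes `ambiguous` rather
  than guessing.
* Core boundaries are grid-resolution (one stride).
* The occlusion metric uses a single piercing segment as the threading
  axis; strongly curved threads through wide loops are summarised
  conservatively.
* A slipknot adjacent to a deep factor is reported as a flag, not
  counted against R2 — only complete factors enter the rules.
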