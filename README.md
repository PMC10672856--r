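# knotscope

Topology auditing for predicted protein structures.

Deep-learning structure predictors move residues freely during assembly
("residue gas") and only repair stereochemistry afterwards, so nothing
stops them from emitting backbones whose topology no folding process can
reach: tandem repeats of a small knotted domain predicted to form ten
consecutive knots, sterically blocked threading loops, or two sequence
copies of a domain stacked in one place — all while per-residue
confidence (pLDDT) stays comfortably above 70, because each knotted core
looks locally native. `knotscope` detects knots on open backbones,
decomposes composite knots, and checks the result against the known
mechanisms of protein knot formation, flagging what they cannot produce.

## The method in brief

An open chain gets a knot type by consensus over stochastic closures:
both endpoints are joined through a random point on a far sphere
(radius 12x the bounding-box diagonal), the loop is simplified by KMT
vertex deletion, projected to a crossing diagram, and classified by
Alexander invariants — the knot determinant |Δ(−1)| for every closure,
plus |Δ(−2)| extracted from the full Alexander polynomial (determinant
of the crossing-relation minor over Z[t], computed modulo 2³¹−1) when
the determinant alone is ambiguous (4₁/5₁, 5₂/7₁, 6₁/3₁#3₁, ...). Both
invariants are multiplicative over connected sums, so tandem-repeat
composites read off directly as e.g. `3_1#3_1#3_1`. Labels are achiral
(Alexander invariants cannot see chirality).

Subchain classification on a stride grid (`knot_fingerprint`) localises
knotted cores (`find_cores`), separates slipknots (`detect_slipknots`),
and classifies depth (shallow vs deep at 20 residues from the nearest
terminus). The rule engine (`assess_feasibility`) encodes the mechanism
bound — tail threading, one ribosome-held deep knot, domain swapping;
at most three consecutive knots, deep one central — and returns
plausible / implausible / ambiguous with the triggered rules.
Loop-occlusion, domain-overlap and pLDDT-masking detectors cover the
other failure modes.

## Worked example

Build a synthetic analogue of a 3x tandem repeat of a trefoil-knotted
domain (nine-point linkers standing in for nine-glycine linkers) and
audit it:

```r
library(knotscope)

units <- lapply(1:3, function(i)
  knot_recipe("3_1", n_points = 100, noise_sigma = 0.2, seed = i))
tr <- concat_knots(units, linker_points = 9)

fp <- knot_fingerprint(tr, step = 5, n_closures = 100, seed = 1)
fc <- find_cores(fp)
as.data.frame(fc)
#>   label probability core_start core_end depth_n depth_c depth_class
#> 1   3_1           1         21       86      20      40     shallow
#> 2   3_1           1        126      196      40      50        deep
#> 3   3_1           1        246      311      50      10     shallow

assess_feasibility(fc)
#> <plausibility_verdict> plausible (3 factors)
#>   flags: at_mechanism_limit
```

Three consecutive trefoils with the deep one central is exactly the
limit of what threading plus one ribosome-held loop could make, so the
verdict is plausible but flagged. The same audit of a 10-repeat
construct finds ten factors and rules the geometry implausible (rule R1:
more than three consecutive knots; R2: more than one deep knot):

```r
units10 <- lapply(1:10, function(i)
  knot_recipe("3_1", n_points = 100, noise_sigma = 0.2, seed = i))
tr10 <- concat_knots(units10)
fc10 <- find_cores(knot_fingerprint(tr10, step = 5, n_closures = 100, seed = 10))
nrow(fc10)
#> [1] 10
assess_feasibility(fc10)$verdict
#> [1] "implausible"
```

Real models go through the same pipeline from a file:

```r
audit <- audit_structure("model.pdb", chain = "A", seed = 42)
write_audit_json(audit, "model.audit.json")
```

A command-line front end (`inst/cli/knotscope.R`) wraps classify /
build / synth / fingerprint / occlusion / overlap subcommands and exits
3 when any input is implausible, so it can gate model-selection
pipelines. Sequence-side, `construct_spec()` + `build_tandem()` emit
tandem-repeat FASTA constructs (poly-Gly / GGGGS / Pro-rich linkers,
lengths 1–17) ready for any predictor.

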