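Package: knotscope
Title: Topology Auditing of Predicted Protein Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates the backbone topology of protein structure models,
    in particular deep-learning predictions whose structure modules do not
    enforce chain impermeability. Detects knots on open polypeptide chains
    by stochastic chain closure, KMT reduction and Alexander-invariant
    classification; maps knotted cores and slipknots from subchain
    fingerprints; decomposes composite knots into consecutive prime
    factors; and audits models against the known mechanisms of protein
    knot formation (tail threading, on-ribosome folding, domain swapping),
    flagging structures whose topology those mechanisms cannot produce.
    Includes loop-occlusion, domain-overlap and per-residue confidence
    (pLDDT) red-flag detectors, a tandem-repeat construct builder, and
    parametric generators of Calpha-like polylines with known topology for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
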