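Package: funvar
Title: Functional Impact Events from Tumor Missense Mutations via Functional Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects functional impact events (FIEs) in somatic missense mutations by
    aggregating paralog mutations through functional-family alignments onto a single
    representative protein domain structure. Provides permutation-tested 3D mutation
    clustering and recurrence hotspots, proximity filtering against known and
    conservation-predicted functional sites ("tunable sites"), a component-wise FIE
    score built on the Grantham substitution matrix, classification of mutation timing
    relative to gene duplication from allele-specific and mutation copy numbers, and
    Hill-Shannon diversity of FIE genes and families with exact rarefaction,
    extrapolation, sample-coverage estimation and bootstrap confidence intervals.
    Includes a synthetic-fixture generator with planted clusters, hotspots and timing
    truth so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
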