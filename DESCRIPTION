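Package: rampseq
Title: Ramp Sequence Detection in Coding Sequences from Codon Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ramp sequences, the stretches of slowly-translated codons
    at the 5' end of coding sequences that space ribosomes during translation
    initiation. Per-codon translation efficiencies (tRNA adaptation index
    values supplied by the user, or relative codon adaptiveness computed from
    codon usage) are smoothed with a ribosome-footprint sliding window; the
    windowed minimum locates each gene's translational bottleneck, outlier
    regions of bottleneck positions across the gene set delimit where a ramp
    may start, and the ramp is extended until local efficiency exceeds the
    whole-gene level. Includes goodness-of-fit and mark-recapture overlap
    statistics for downstream validation, a seeded generator of codon-biased
    sequence sets with planted ramps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
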