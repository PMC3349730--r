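Package: repkin
Title: Replication Timing Inference from Density-Transfer Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring DNA replication timing from Meselson-Stahl
    density-transfer experiments in budding yeast. Implements the locus-level
    inference chain (gradient-fraction pooling, percent replication, kinetic
    curves, time of half-maximal replication T_rep, and replication indices
    against early/late timing standards), a genome-wide microarray-style
    profile layer (per-probe percent replication, window smoothing, Z-score
    normalization, origin peak calling, and persistent timing-difference
    detection between strains), and a stochastic forward simulator of S-phase
    origin firing with a phenomenological centromere-proximity effect on
    origin activation time. Ships fully parameterized synthetic scenarios of
    a chromosome XIV centromere relocation experiment so that every stage of
    the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
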