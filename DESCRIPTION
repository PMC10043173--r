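Package: epimem
Title: Persistence of Stimulus-Induced Histone Modifications Through Cell Division
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-course analysis of whether stimulus-induced histone
    post-translational modification (PTM) changes persist through cell
    division, or decay according to passive two-fold dilution at each round
    of DNA replication. Provides a negative-binomial simulator of peak and
    gene count matrices with division-indexed effect trajectories
    (non-persistent, retained, induced) and peak-gene coupling; TMM
    normalization and per-timepoint linear-model differential testing with
    empirical-Bayes variance moderation; retention curves of T0-significant
    features compared against the 50 percent-loss-per-division null by
    Kolmogorov-Smirnov test; trajectory classification with nearest-gene
    concordance testing; PC1xPC2 epigenome-transcriptome coupling; and
    priming analysis of secondary-stimulation responses with adaptive
    shrinkage and local false sign rates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
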