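Package: aflpscan
Title: Genome Scans for Divergent Selection on Dominant AFLP Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting loci under divergent selection from dominant
    amplified fragment length polymorphism (AFLP) presence/absence data in
    structured populations. Implements peak-height threshold scoring with
    replicate-based error optimisation, Bayesian null-allele frequency
    estimation for dominant markers, variance-component FST with permutation
    tests, island-model neutral simulation calibrated to the trimmed mean FST
    with heterozygosity-conditional outlier envelopes, a repeated-outlier
    framework that separates selection associated with phenotype from
    selection associated with geography, and a synthetic-data generator for
    hierarchically structured dominant-marker datasets with planted selected
    loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
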