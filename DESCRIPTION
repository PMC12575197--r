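Package: sweepscan
Title: Selective-Sweep Scans Contrasting Two Populations from Whole-Genome SNP Data
Version: 0.1.0
Authors@R: person("sweepscan", "maintainers", email = "maintainers@sweepscan.dev", role = c("aut", "cre"))
Description: Detects selective sweeps between two diverged populations
    (e.g. a trait-selected group versus a reference group) from a joint
    multi-sample VCF. Implements sliding-window Weir-Cockerham FST and
    nucleotide diversity with joint outlier calling, a cross-population
    composite-likelihood-ratio (XP-CLR style) sweep scan, PLINK-style
    runs-of-homozygosity calling with ROH-island segmentation, interval
    mapping of outlier regions to genes with three-method consensus, and
    exact hypergeometric term over-representation testing. Ships a forward
    Wright-Fisher two-population simulator with planted hard sweeps so the
    whole pipeline is testable without external data, plus a command-line
    driver orchestrating simulate, filter, scan, consensus and enrichment
    stages reproducibly from a config file.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
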