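Package: nucleodiff
Title: Differential Nucleosome Positioning from MNase-Seq Read Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide comparison of nucleosome positioning between strains
    from mapped mono-nucleosome sequencing reads. Converts strand-specific
    read 5' ends to fragment centers, builds per-base occupancy and
    Gaussian-smoothed nucleosome-score tracks, calls nucleosome centers as
    suppressed score peaks, and classifies between-strain differences into
    position shifts, occupancy changes and losses/gains with strand-split
    confirmation. Downstream statistics include nucleosome fuzziness, shift
    directionality and propagation to neighbors, inter-nucleosome linker
    distributions, TSS-aligned profiles, covariate-stratified shift means and
    a mixture decomposition separating real shifts from positioning error. A
    synthetic MNase-seq generator with injectable perturbations provides
    ground truth for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    IRanges,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
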