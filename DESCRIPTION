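Package: riboswitchEP
Title: Riboswitch Expression Platform Annotation, Mutagenesis and Kinetic-Barrier Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcriptional riboswitch expression
    platforms that switch through internal strand displacement, modelled on
    the ZTP (pfl) riboswitch. Annotates terminator invader/substrate duplexes
    and their noncomplementary elements (wobbles, mismatches, bulges), indexes
    kinetic barriers by distance from the strand-displacement nucleation site,
    generates mismatch/deletion/wobble/bulge mutant libraries with a compact
    naming grammar, curates and chimerises candidate expression platforms,
    designs flipped-logic OFF-switches, and fits the quantitative models used
    for reporter assays: blank/OD normalization, Welch t-tests with Bonferroni
    correction, sigmoidal dose-response (EC50) fits and the inverse-square
    kinetic-barrier model for ON-state shifts. A synthetic fluorescence-assay
    generator with known ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    minpack.lm,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
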