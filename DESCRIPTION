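Package: sfsdemog
Title: Joint-SFS Demographic Model Selection and Coalescent Introgression
    Analysis for Three-Population Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Demographic inference tools for three-population systems built
    around a structured-coalescent simulation engine: construction, folding,
    projection and serialisation of the 3D joint site frequency spectrum; a
    ten-model registry of divergence, secondary-contact (refugia) and
    riverine-barrier scenarios fitted by multinomial composite likelihood
    with staged Nelder-Mead optimisation; Akaike-weight model ranking,
    confidence sets and Godambe-adjusted likelihood-ratio tests; simulation
    under the multispecies coalescent with bidirectional introgression
    pulses (MSci), label-swap transforms, minimum-divergence moment
    estimators, ignored-gene-flow bias and admixed-sample sensitivity
    experiments; divergence-time and effective-population-size calibration;
    and genotype-environment association outlier-filtering rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
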