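Package: famnorm
Title: Reference-Free Pre-Processing and Evaluation of Familial Infinium
    Methylation Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pre-processing Infinium 450k-style DNA methylation
    array data from family studies, where no matched reference group exists.
    Implements probe- and sample-level quality control (detection p-value,
    bead-count and sex-chromosome filters), eight normalisation algorithms
    (global and stratified quantile normalisation, SWAN-style subset quantile
    normalisation, beta-mixture quantile dilation, normal-exponential
    out-of-band background correction, dasen-style type-wise normalisation
    and control-probe functional normalisation) together with empirical-Bayes
    location/scale batch correction, and an eight-metric evaluation battery
    (density and probe-type alignment, multidimensional scaling, principal
    component ANOVA, replicate median absolute differences, the imprinted
    region standard error DMRSE, batch-cluster agreement, kinship-adjusted
    meQTL association and an age-EWAS inflation lambda). A synthetic-data
    generator emulates the familial, batch, probe-chemistry, imprinting,
    meQTL and age structure these metrics assume, and an end-to-end pipeline
    compares methods on a common dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    data.table,
    jsonlite,
    mclust,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    optparse,
    withr
Config/testthat/edition: 3
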