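Package: pseudopace
Title: Pseudotime Trajectories and Epigenetic Pacemaker Models for DNA
    Methylation Aging
Version: 0.1.0
Authors@R:
    person("Pseudopace", "Developers", email = "pseudopace@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the aging trajectory of DNA methylation
    without assuming a functional form of age.  The package generates
    synthetic 450k-style methylation cohorts, selects age-associated CpG
    sites by Pearson correlation, quantile-normalizes beta values by probe
    design type against a training reference, embeds samples with principal
    components, clusters them with Gaussian mixture models selected by BIC,
    infers a single-lineage trajectory (minimum spanning tree over cluster
    centers followed by a principal curve) and assigns arc-length pseudotime.
    It also fits the Epigenetic Pacemaker model by conditional
    expectation-maximization, and compares five functional forms of age
    (quadratic, logarithmic, square root, exponential and a sum of two
    exponentials) by AIC, RMSE and R-squared, including Gompertz-style
    mortality doubling times for exponential rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
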