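Package: mireflow
Title: Demographic History and Gene Flow Inference from Haploid SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of polarized haploid SNP matrices
    from short unlinked loci (RAD-seq style data), built around the
    workflow used to study divergence and gene flow in haploid-dominant
    plants such as peatmosses: unfolded joint site frequency spectra with
    hypergeometric projection over missing data, nucleotide diversity,
    Hudson's Fst, Dxy and site-class counts with delete-one jackknife
    uncertainty, ABBA/BABA introgression statistics (Patterson's D and
    f4-ratio with block-jackknife significance), a structured-coalescent
    simulator of expected and sampled spectra under isolation-with-migration
    models with time-windowed gene flow, composite-likelihood model fitting
    with conditional-maximization cycles and AIC ranking, parametric
    bootstrap confidence intervals, and a synthetic-data generator with
    known demographic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
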