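Package: karyopoly
Title: Karyotype Polymorphism and Aneuploidy Analysis for Macrostomum Flatworms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing karyotype polymorphism from chromosome
    morphometry to population genetics. Computes per-chromosome metrics
    (absolute and relative length, arm ratio, centromeric index) from arm-length
    measurements, classifies centromere position under Levan nomenclature,
    calls specimen karyotypes from replicate metaphase plates with mosaicism
    detection, tests karyotype-class frequencies against independent-assortment
    (Hardy-Weinberg style) expectations with Pearson chi-squared and Fisher's
    combined probability, tests Mendelian cross expectations for aneuploid
    parents, estimates viability selection against the euploid class by maximum
    likelihood, and forward-simulates karyotype-class dynamics in finite
    obligately outcrossing hermaphrodite populations under viability selection
    and meiotic drive. A synthetic-data generator emulates morphometric
    measurement tables so that every pipeline stage is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
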