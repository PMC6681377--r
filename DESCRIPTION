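Package: poolqtl
Title: Pooled-Sequencing QTL Discovery by Replicated CMH Scans and
    Bulked-Segregant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for pool-based QTL discovery in
    backcross populations, modelled on the design used to map a dominant
    high-ascorbate supergene in kiwifruit (Actinidia chinensis x A. eriantha)
    hybrids. Generates cohorts with a bimodal major-gene trait, an orthogonal
    2x2 pooling design, and Popoolation2 "sync" pooled allele counts; applies
    site filters and coverage resampling; runs replicated
    Cochran-Mantel-Haenszel association scans with Mantel-Haenszel common odds
    ratios and Benjamini-Hochberg correction; performs QTL-seq windowed
    delta-SNP-index bulked-segregant analysis with simulation-based null
    thresholds, including a tetraploid backcross (BC4x) population model with
    expected bulk allele frequencies 0:0.25; fingerprints recombination-
    suppressed introgressions from homeo-SNP allele-of-origin expression
    counts; and provides marker-validation ANOVA and metabolite group-contrast
    statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
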