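Package: rarebands
Title: Repeated Rarefaction for Library-Size Normalization of Amplicon
    Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Library-size normalization of amplicon (ASV/OTU) count tables
    by repeated rarefaction: each sample is randomly subsampled to a common
    depth many times, with or without replacement, and the resulting
    ensemble of rarefied libraries is propagated through alpha-diversity
    (Shannon index, Hill numbers) and beta-diversity (Hellinger-transformed
    Bray-Curtis, Jaccard, principal-coordinate ordination) analyses.
    Instead of a single diversity value or a single ordination point per
    sample, the package produces bands of values and patches of points that
    characterize the random variation introduced by rarefying, together
    with rarefaction curves and their exact analytic expectation to guide
    the choice of normalized library size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    parallel,
    vegan,
    ggplot2,
    jsonlite,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
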