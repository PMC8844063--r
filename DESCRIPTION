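Package: callspace
Title: Null-Model Tests of Acoustic Niche Partitioning in Anuran Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures six standard call parameters (5% / 95% / dominant
    frequency on the log10 scale; 90% energy duration, relative peak time,
    note rate) from single-call audio, computes five pairwise
    acoustic-similarity measures (Euclidean distance in the first three
    principal components of all, spectral-only, or temporal-only parameters;
    90% bandwidth spectral overlap; dominant-frequency distance), and tests
    assemblages of co-calling species for acoustic niche partitioning
    against geographically constrained null models: each observed assemblage
    is compared with random assemblages of matching richness drawn from the
    species pool within a 50 km radius, summarised as standardized effect
    sizes with bias-corrected and accelerated (BCa) bootstrap confidence
    intervals and linear mixed-effects covariate checks. A synthetic-data
    module generates call audio and full assemblage datasets with known
    partitioning structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    boot,
    geosphere,
    withr
Config/testthat/edition: 3
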