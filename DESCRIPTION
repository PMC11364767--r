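Package: chronospread
Title: Diurnal Activity Archetypes and the Spread of Potentially Disinformative Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how diurnal posting rhythms on social media
    relate to the spread of potentially disinformative content. Builds 96-bin
    diurnal activity curves from timestamped post streams, clusters users into
    behavioural archetypes (morning, intermediate, evening, infrequent),
    smooths curves by circular Gaussian averaging and truncated Fourier
    series, infers heightened-activity windows and prolonged wakefulness,
    computes source-reliability content ratios under a nine-category Harm
    Score scheme, and compares day against night under clock, daylight and
    inferred-waking definitions with nonparametric statistics (Mann-Whitney U
    with exact small-sample enumeration, Spearman rank correlation, Pearson
    chi-squared, Hartigan's dip test). Includes a synthetic post-stream
    generator with planted archetype structure so the full pipeline is
    testable without restricted platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
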