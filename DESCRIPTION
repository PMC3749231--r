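Package: itraq4
Title: Quantitative Analysis of iTRAQ 4-Plex Proteomics Experiments
Version: 0.1.0
Authors@R:
    person("p2r", "maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for isobaric-tag (iTRAQ 4-plex) quantitative
    proteomics at the peptide-spectrum-match (PSM) level: peptide
    qualification by labeling, identification confidence, uniqueness and
    reporter-ion dynamic range; per-channel normalization (equal-sum,
    median log-ratio centering, trend-line and protein-level variants);
    sum-of-intensity rollup to protein abundance ratios; selection of
    differentially expressed proteins via the R and S log-ratio
    statistics with cut-offs at the median of R plus or minus z times
    the standard deviation of S; decomposition of the S-value variance
    into technical and biological components; and human/mouse protein
    inference for xenograft tumor samples.  Includes a synthetic PSM
    generator with known ground truth for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
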