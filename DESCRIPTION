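Package: panelutility
Title: Aggregate Net Utility of Multi-Gene Germline Screening Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic evaluation of which genes add or subtract net
    utility on a multi-gene, multi-disease germline screening panel. Computes
    closed-form net utilities from carrier prevalence, lifetime penetrance and
    user-specified disutilities for discordant test/disease outcomes; derives
    the disutility-ratio threshold at which testing breaks even; models
    uncertainty in penetrance estimates as Beta distributions and propagates it
    into credible intervals, probabilities of positive utility and
    fifth-percentile worst-case summaries; and provides grid sweeps over
    disutility ratios and two-way disutility heatmaps. Ships a five-gene
    female breast cancer panel (ATM, BRCA1, BRCA2, CHEK2, PALB2) as a built-in
    fixture, JSON/TSV panel file formats and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
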