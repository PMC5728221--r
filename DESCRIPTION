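Package: opiwatch
Title: Social-Media Surveillance of Illicit Opioid Marketing with Biterm Topic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable detection funnel for illicit direct-to-consumer drug
    marketing on microblogging platforms: keyword-filtered tweet ingestion,
    short-text topic modeling with a Biterm Topic Model fitted by collapsed
    Gibbs sampling, theme-based isolation of news content, selling-argument
    lexicon filtering, duplicate/retweet collapsing, hyperlink extraction,
    website-category triage, and inter-annotator agreement (Cohen's kappa).
    Includes a synthetic tweet-corpus generator with planted ground truth so
    every pipeline stage can be validated without access to raw platform data,
    and an exhaustive-enumeration posterior oracle for testing the sampler on
    small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
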