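Package: mexsets
Title: Collections of Mutually Exclusive Somatic Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies collections of mutually exclusive genomic alterations
    in cancer cohorts. Implements an exact conditional test of exclusivity on
    2^k contingency tables with fixed margins, computed by a tail-enumeration
    algorithm with binomial and permutation approximations; a
    Metropolis-Hastings sampler over collections of disjoint alteration sets
    weighted by their exclusivity score; a permutation-based significance
    threshold on margin-preserving shuffles of the alteration matrix; and a
    marginal-probability-graph summarization that extracts output modules as
    connected components. Ships an implanted-pathway simulation benchmark with
    F-measure and adjusted Rand index evaluation, and supports simultaneous
    analysis of alterations and cancer subtypes via subtype indicator rows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
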