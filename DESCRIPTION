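Package: drugpulse
Title: Mining Drug Discourse from Short-Text Social-Media Corpora
Version: 0.1.0
Authors@R:
    person("drugpulse", "developers", email = "drugpulse@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for pharmacovigilance-oriented text
    mining of short social-media posts (tweets): corpus ingestion and URL
    filtering, lexicon-based drug/symptom entity extraction with
    normalization of colloquial variants, targeted three-class sentiment
    aggregation into weekly series, latent Dirichlet allocation by
    collapsed Gibbs sampling with perplexity- and coherence-based model
    selection, and cosine-similarity co-occurrence networks (drug-drug and
    drug-symptom) with Louvain community detection, ATC annotation and
    Gephi-loadable exports. A seeded synthetic-corpus generator with full
    ground truth makes every stage testable without access to platform
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
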