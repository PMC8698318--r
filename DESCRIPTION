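Package: osteostage
Title: Metabolic Phase Detection and Regulon Inference for Osteogenic
    Differentiation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-omic staging analysis of mesenchymal stromal cell (MSC)
    osteogenic differentiation. Detects metabolic phases from extracellular
    metabolite uptake/secretion rates via multivariate E-divisive
    energy-statistic change-point analysis with permutation testing;
    corrects 13C isotopologue intensity distributions for natural abundance
    and computes mean label enrichment; filters differential-expression
    tables to a response gene set; infers transcription-factor regulons by
    consensus-k agglomerative clustering and hypergeometric enrichment with
    a correlation gate, classifies switch-like activity patterns, and
    builds directed TF-TF influence networks. Includes seeded synthetic
    data generators with known ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    mgcv,
    pracma,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
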