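Package: gradRT
Title: Gradual-Template Transcriptome Selection and Preclinical Endpoints
    for Combined Radiotherapy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for preclinical studies combining external
    beam radiotherapy (photon or carbon ion) with tumor-targeting
    endoradiotherapy. Implements microarray-style transcript filtering and
    control-group normalization, selection of gradually regulated genes by
    Pavlidis Template Matching against a 3-step treatment-intensity
    template (UpCor/DownCor), hypergeometric gene-set enrichment with
    population maps, direct protein-protein interaction subnetwork
    extraction with permutation-based largest-component significance, and
    the quantitative preclinical endpoints: caliper tumor volume, growth
    inhibition, relative biological effectiveness, radiotracer
    biodistribution (percent injected dose per gram, tumor-to-muscle
    ratio), time-to-progression survival with Kaplan-Meier and log-rank
    analysis, microvessel density and Ki-67 index. Ships a synthetic-data
    generator with planted ground truth so the full pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    fgsea,
    igraph,
    jsonlite,
    stats,
    survival,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
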