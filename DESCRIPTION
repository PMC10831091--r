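Package: ffpesieve
Title: Classification of FFPE-Induced Artifacts in Somatic Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of MuTect2 somatic variant calls from
    formalin-fixed, paraffin-embedded (FFPE) tumour specimens. Matched
    fresh-frozen (FF) call sets provide ground-truth labels (calls private
    to the FFPE sample are treated as fixation artifacts), 41 numeric
    predictors are derived per called allele -- including a strand
    orientation bias (SOB) score on F1R2/F2R1 read counts and a ref-vs-alt
    orientation cosine similarity -- and a small feed-forward neural
    classifier scores each call with a probability of being a true
    variant. Includes exact confusion-matrix metrics, an F1-maximising
    decision-threshold sweep, stratified benchmark reports, a synthetic
    matched FF/FFPE pair generator for end-to-end testing without
    sequencing data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Rsamtools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
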