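Package: bemux
Title: Base-Editor Multiplex Guide Design and Safety Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design machinery for one-step multiplexed base editing of tumor
    models: cytosine and adenine base-editor (CBE/ABE) sgRNA design across
    Cas9 PAM variants (SpCas9, SpCas9-NG, SpRY, SaCas9, SaKKH), bystander
    outcome enumeration with protein-consequence annotation, CRISPR-stop
    nonsense-codon scanning, cross-editor sgRNA interference auditing,
    variant-catalog targetability aggregation, and the whole-genome
    safety statistics used to assess off-target burden (exact Mann-Whitney
    load comparison, 96-channel mutational-signature refitting, gene-body
    depletion tests, rainfall/kataegis detection, mismatch-tolerant
    off-target site search). Includes seeded synthetic-data generators
    with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
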