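Package: dppscreen
Title: N-Terminal Processing Prediction and Proteome Screening for
    DPP8/9 Substrates
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts which proteins are candidate substrates of the
    cytosolic dipeptidyl peptidases DPP8 and DPP9 from their N-terminal
    sequence, models the two-step N-terminal maturation (initiator
    methionine excision followed by post-proline dipeptide release),
    derives the resulting neo-N-terminus and its N-end-rule (N-degron)
    class, screens annotated proteomes (e.g. a MitoCarta-style
    mitochondrial inventory) for candidates with hypergeometric
    subcompartment and pathway enrichment, and quantifies cross-species
    conservation of cleavage sites from pre-computed ortholog alignments
    via per-column frequency profiles, information content and sequence
    logo matrices.  A synthetic-data generator produces planted-motif
    proteomes and substitution-model ortholog sets so that every stage of
    the pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
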