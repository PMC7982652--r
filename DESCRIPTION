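Package: pgdbprop
Title: Ortholog-Based Propagation of Curated Annotations Between Genome Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Propagates curated knowledge (gene and product names, GO term
    assignments, reaction assignments, and heteromultimeric complex membership)
    from a well-curated annotated genome database to databases for closely
    related strains. Orthologs are detected as best bidirectional hits with
    ties retained, ambiguous mappings are resolved by local synteny and then
    by gene name, and a set of conservative quality filters (evidence codes on
    both sides, similarity P-value, sequence length difference, complex
    completeness) gates every transfer. All changes carry provenance records,
    and each run emits a three-part report. A synthetic strain-pair generator
    with known ortholog ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
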