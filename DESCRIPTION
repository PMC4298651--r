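Package: pepspace
Title: Tryptic Search-Space Analysis of Protein Sequence Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise and compare the tryptic search space of
    protein sequence collections. Provides in-silico proteolytic digestion
    with configurable cleavage rules and peptide filters, monoisotopic mass
    computation, expansion of collections with annotated single-amino-acid
    variants (optionally restricted to disease-associated ones), 100%-identity
    redundancy clustering with accounting of the tryptic peptides lost by
    clustering, pairwise three-compartment comparison of digested collections,
    peptide-unicity evaluation at sequence and entry level, matching against
    mass-spectrometry repository peptide evidence, and a synthetic proteome
    generator with a ground-truth manifest so that every stage can be tested
    without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
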