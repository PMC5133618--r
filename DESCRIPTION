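Package: ringfam
Title: Genome-Wide Annotation of RING-H2 (ATL) Ubiquitin-Ligase Gene Families
Version: 0.1.0
Authors@R:
    person("ringfam", "maintainers", email = "maintainers@ringfam.dev",
           role = c("aut", "cre"))
Description: Tools to identify and annotate plant ATL-type E3 ubiquitin
    ligases genome-wide: a configurable spacing-grammar scanner for the
    ATL RING-H2 zinc-finger motif with PxC/PC subtyping, Kyte-Doolittle
    hydropathy profiling with transmembrane and hydrophobic region calls,
    GLD-motif grading, isoelectric point and molecular weight, gene
    structure from GFF3, duplication-mode classification (segmental/WGD,
    tandem, proximal, dispersed) from all-vs-all homology with a
    collinearity chainer and Fisher retention-enrichment tests,
    phylogeny-guided nomenclature against a reference gene set,
    expression-atlas clustering with weighted Pearson co-expression and
    Mantel association, stress-responsiveness flagging from per-contrast
    differential-expression tables, and seeded synthetic-data generators
    with ground truth for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    optparse,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
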