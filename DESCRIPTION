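Package: pdselect
Title: Phylogenetic Diversity Scoring and Greedy Sequencing-Target Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores microbial taxa by their contribution to the total
    phylogenetic diversity (PD) of a reference tree and selects fixed-size
    primary and backup sequencing-target lists by greedy PD maximization,
    in the style of the GEBA/KMG type-strain genome-sequencing projects.
    Includes newick tree input/output with strict validation, rooted and
    unrooted PD for arbitrary taxon sets, an exhaustive small-instance
    selection oracle, per-phylum taxonomy summary tables (counts, percent
    homotypic synonyms, genome-sequencing coverage), a seeded Yule tree
    and taxon-record simulator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
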