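Package: mhcvar
Title: Sequence Variability, Anchor-Residue Conservation and Lineage
    Phylogenetics for MHC Class I Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes aligned amino-acid sequence families of MHC
    class I peptide-binding domains (alpha1/alpha2): per-site Shannon
    entropy variability with polymorphic-site calling, pairwise
    percent-difference matrices and summary statistics, conservation
    auditing of peptide-anchor residues against HLA-A2 reference
    numbering, Poisson-corrected neighbor-joining phylogenies with
    Felsenstein bootstrap support, and bootstrap-supported assignment
    of query sequences to teleost MHC-I lineages (U, Z, S, L, P, H).
    Includes a synthetic sequence-family simulator with known truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
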