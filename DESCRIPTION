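Package: cpdscan
Title: Compensated Pathogenic Deviations in Mitochondrial Complex I Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline that searches multi-species
    amino-acid alignments of the mitochondrially encoded NADH dehydrogenase
    (Complex I) subunits for human pathogenic variants occurring as wild-type
    alleles in other metazoans (compensated pathogenic deviations, CPDs), and
    nominates potential masking substitutions at structurally contacting
    residues. Includes rCRS nucleotide-to-protein coordinate mapping for the
    seven ND genes (including light-strand ND6), a configurable pathogenicity
    scoring rubric, Fitch parsimony ancestral-state reconstruction with
    substitution and reversion counting, residue contact maps from PDB
    structures (C-beta representative atoms, C-alpha for glycine, 8 Angstrom
    threshold), Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor
    correction, a hypergeometric conservation probability, Miyata (1979)
    physicochemical similarity ranking, and a fully deterministic
    synthetic-data generator producing alignment/tree/structure bundles with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
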