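Package: ifacevol
Title: Structure-Conditioned Molecular Evolution of Protein Complex Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to contrast evolutionary rates between structurally defined
    residue classes of a multi-subunit protein complex. Residues of designated
    chains are classified by inter-chain atomic contact (with the genome of
    origin of the partner chain), solvent exposure and interface burial;
    codon alignment columns are projected onto those classes through a
    reference taxon; and class-wise selective pressure is quantified by
    pairwise nonsynonymous divergence sums with codon-resampling empirical
    nulls, by fixed-sites codon-model omega estimates on a fixed phylogeny,
    by M1a/M2a likelihood-ratio tests for positive selection, and by
    per-branch expected nonsynonymous substitution counts. A synthetic-data
    generator with planted ground truth (toy complexes, random trees, codon
    alignments simulated under partition-specific omega, per-residue
    stability tables) supports end-to-end validation, and a pipeline driver
    orchestrates the full analysis from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
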