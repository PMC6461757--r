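Package: magpipe
Title: Phylogenomic Rank Normalisation, MAG Quality Scoring and
    Abundance-Environment Inference for Marine Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative genomics and ecology of
    metagenome-assembled genomes (MAGs): relative evolutionary divergence
    (RED) computed on rooted genome trees and used to normalise taxonomic
    ranks, with detection and splitting of polyphyletic clades;
    marker-based completeness and contamination estimation with
    lineage-specific marker refinement, MIMAG high-quality classification,
    quality-score ranking for type-material selection, and
    identity-threshold dereplication; spectral-tuning and proton-donor
    classification of proteorhodopsin sequences from protein alignments;
    and negative-binomial GLM/GAM association of clade abundances with
    environmental metadata, including median-of-ratios library scaling,
    AIC-driven dispersion and reference-level selection, Wald tests with
    Benjamini-Hochberg correction, and cubic-spline seasonal smooths.
    A synthetic-data module generates every input with known ground truth
    so the full pipeline is testable without raw metagenomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    MASS,
    jsonlite,
    splines,
    stats,
    utils,
    withr
Suggests:
    DESeq2,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
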