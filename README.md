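# magpipe

Phylogenomic rank normalisation, MAG quality scoring, proteorhodopsin
spectral typing, and abundance–environment inference for marine
metagenomes.

Uncultured marine lineages are studied almost entirely through
metagenome-assembled genomes (MAGs): draft genomes binned from shotgun
assemblies, placed on genome trees, and correlated with the environments
they were sampled from. magpipe implements that analytical core as a
tested, reproducible R pipeline for anyone delineating taxa on a genome
tree, ranking MAGs as candidate type material, typing light-harvesting
genes, or asking which environmental variables structure clade abundances.

## What it computes

**Relative evolutionary divergence (RED).** On a rooted genome tree, the
root is assigned RED 0, every extant leaf RED 1, and an internal node with
parent value *p*, branch length *d*, and mean parent-to-descendant-leaf
path length *u* is interpolated as

    red = p + (d / u) (1 − p)

RED is scale-invariant and rate-aware, which makes divergence comparable
across lineages and lets taxonomic ranks be drawn as RED windows
(median ± 0.1 per rank). Polyphyletic or over-deep taxa are split into
monophyletic children with numeric suffixes (`L1, L2, ...`) in ladder
order.

**MAG quality rules.** Marker-set refinement (markers absent from a whole
lineage are dropped before estimating), completeness / contamination from
single-copy marker counts, screening at ≥ 20% completeness and ≤ 10%
contamination, MIMAG high-quality classification (> 90% / < 5%, near
full-length rRNAs, ≥ 18 tRNAs), type-material ranking by the quality score
`completeness − 4 × contamination`, and greedy dereplication at 99.5%
identity.

**Proteorhodopsin spectral tuning.** A residue lookup on a protein
alignment: methionine at alignment position 315 predicts green light
absorption (525 nm, shallow-photic clade), glutamine predicts blue
(490 nm, deep-photic clade); position 318 separates proton pumps
(E or K) from photosensors (F or S). Includes the 30%-similarity /
termini-113–585 alignment filter with original coordinates kept
addressable, and depth-binned class summaries.

**Abundance–metadata inference.** Median-of-ratios library scaling,
per-clade negative-binomial GLMs (Var = μ + αμ², α chosen by AIC) against
one metadata variable at a time with treatment or sum-to-zero coding and
AIC-selected reference levels, Wald tests with Benjamini–Hochberg control
(variables at adjusted p ≤ 0.1, coefficients at ≤ 0.05), NB GAM seasonal
smooths (cubic splines, df 3–9 by AIC), grand-mean baseline contrasts, and
single-copy ribosomal gene normalisation.

**Synthetic data.** Every input above — trees with rate heterogeneity,
marker tables with planted completeness/contamination, NB counts with
known effects and seasonal cycles, alignments with planted tuning
residues — can be simulated with ground truth attached, so the entire
pipeline is testable offline.

## Worked example

```r
library(magpipe)

# RED on a small rooted tree with three cherry "genera"
tr  <- ape::read.tree(text =
  "((a1:1,a2:1)A:4,((b1:1,b2:1)B:4,(c1:1,c2:1)C:9)W:7.5)R;")
ann <- compute_red(tr)
subset(as.data.frame(ann), !is_leaf)
#>    node label is_leaf  red   p   d  u
#> 7     7     R   FALSE 0.00  NA  NA NA
#> 8     8     A   FALSE 0.80 0.0 4.0  5
#> 9     9     W   FALSE 0.50 0.0 7.5 15
#> 10   10     B   FALSE 0.90 0.5 4.0  5
#> 11   11     C   FALSE 0.95 0.5 9.0 10
```

Genus A diverged at RED 0.80, B at 0.90, C at 0.95; the root is 0 and all
leaves are 1. Fitting the genus window from these seed taxa gives the
median 0.90 with the ± 0.1 tolerance:

```r
tax <- setNames(c("g__A","g__A","g__B","g__B","g__C","g__C"), tr$tip.label)
fit_rank_windows(ann, tax, ranks = "genus")
#>    rank median_red half_width lower upper n_taxa
#> 1 genus        0.9        0.1   0.8     1      3
```

Spectral typing on a simulated alignment recovers the planted classes:

```r
sim <- simulate_pr_alignment(4, c("SP","DP","SP","DP"), seed = 1)
classify_spectral(sim$alignment)
#>      id residue_315 spectral_class absorption_max_nm
#> 1 pr001           M       green_SP               525
#> 2 pr002           Q        blue_DP               490
#> 3 pr003           M       green_SP               525
#> 4 pr004           Q        blue_DP               490
```

An NB GLM recovers a planted covariate effect (β = 0.5) from scaled
counts:

```r
ds <- simulate_counts(200, 20, coefficients = seq(-0.5, 0.5, length.out = 20),
                      dispersion_alpha = 0.5, seed = 42)
ds$size_factors <- scale_by_library_size(ds$counts)$size_factors
fit_nb_glm(ds, "clade020", "covariate")
#> NB GLM: clade clade020 ~ covariate (treatment coding)
#>   alpha = 0.4587, AIC = 1887.75, block Wald p = 1.44e-17, n = 200
#>          term estimate      se      z         p
#> 1 (Intercept)   3.7329 0.04918 75.896 0.000e+00
#> 2          .x   0.4353 0.05102  8.532 1.438e-17
```

The estimate 0.435 ± 0.051 recovers the planted 0.5 (mildly attenuated
because the size factors absorb part of the shared covariate signal), and
the fitted dispersion 0.46 recovers the planted α = 0.5. Screening all 20
clades with `significance_screen(fits)` keeps 17 of them at the BH
thresholds and reports each association's sign.

A complete simulated run — tree, taxonomy, quality, dereplication,
spectral calls, GLM screen, GAM smooth, with every table written as TSV
plus a JSON run manifest — is one call:

```r
run_pipeline("out/", seed = 1)
```

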