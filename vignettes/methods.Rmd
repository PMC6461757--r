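---
title: "Methods: rank normalisation, MAG quality rules, spectral tuning, and abundance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank normalisation, MAG quality rules, spectral tuning, and abundance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magpipe)
```

magpipe implements the computational core of a phylogenomic-ecology study of
an uncultured marine archaeal lineage: normalising taxonomic ranks on a
genome tree with relative evolutionary divergence (RED), scoring and
selecting metagenome-assembled genomes (MAGs) by marker-based quality rules,
classifying proteorhodopsin spectral tuning from alignment residues, and
associating clade abundances with environmental metadata through
negative-binomial regression. Every input the pipeline consumes can be
simulated with known ground truth, so the whole chain is testable without
raw metagenomes. This vignette records the models, the defaults and why they
are what they are, and the choices made where the methods literature leaves
room.

## Relative evolutionary divergence

RED maps a rooted tree onto $[0, 1]$: the root (the last common ancestor at
a fixed time in the past) is 0, every extant leaf is 1, and internal nodes
are linearly interpolated along their lineage. For a node with parent RED
$p$, branch length $d$ to its parent, and $u$ the mean path length from the
parent to all of the node's descendant leaves,

$$\mathrm{red} = p + \frac{d}{u}\,(1 - p).$$

The interpolation uses only ratios of path lengths, so RED is invariant to
globally rescaling branch lengths — the property that lets it normalise
ranks across lineages evolving at different rates. `compute_red()` verifies
rootedness and never guesses a root; an unrooted tree is an error, because
any silent midpoint rooting would move every RED value.

Numerical choices:

* Zero-length *internal* branches are collapsed to polytomies before the
  computation (`ape::di2multi`). A zero-length internal edge carries no
  divergence signal, and keeping it would interpolate two nodes onto the
  same point with a $0/0$ hazard. Polytomies themselves are handled
  natively; no binarisation is forced.
* Zero-length *terminal* branches are permitted; the leaf is pinned at
  RED 1, which is also the limit of the formula.
* The audit quantities $p$, $d$, $u$ are retained per node so any value can
  be reproduced by hand.

Rank windows are fitted by placing each named seed taxon at the RED of the
last common ancestor of its members and taking the per-rank median; the
window is the median $\pm$ a half-width of 0.1. The 0.1 is the tolerance
used for the genus rank in the source methodology; the widths of other
ranks are not published, so all ranks default to 0.1 and the parameter is
exposed.

`normalise_taxonomy()` first decomposes each taxon into its maximal
member-only subclades (a monophyletic taxon yields exactly one). Clades
whose RED falls below the window are too deep for their rank and are
replaced by their children, recursively — splitting always increases RED,
so the recursion terminates. Clades above the window cannot be repaired by
splitting (merging upward would engulf non-members) and are flagged rather
than forced. Split children are suffixed `X1, X2, ...` in ladder order:
descending clade size, ties broken by alphabetical first leaf. The ordering
criterion behind published split names is unstated, so a deterministic
convention was chosen and documented. Window medians are kept fixed while
clade REDs are recomputed during splitting; recomputing the medians after
every split would make the result depend on processing order.

## MAG quality rules

Completeness and contamination use the single-marker approximation:
completeness is the percentage of expected single-copy markers present at
least once, contamination the percentage of surplus copies,
$100 \sum_m \max(c_m - 1, 0) / |M|$. This deliberately does not reproduce
CheckM's collocated marker-*set* bookkeeping: the available substrate is a
flat marker-count table, and the refinement step — dropping markers absent
from every genome of the lineage, which otherwise deflate completeness —
operates identically either way.

The rule constants are taken as printed in the genome-quality literature
and are strict where the prose is strict:

* screening keeps a genome iff completeness $\ge 20\%$ and contamination
  $\le 10\%$ (exclusion is phrased as "< 20%" / "> 10%", so the boundary is
  on the keep side); the stricter per-site assembly screen is the same rule
  at 50% / 1%;
* MIMAG high-quality requires completeness $> 90$ (strictly), contamination
  $< 5$, 16S $\ge 1200$ bp, 23S $\ge 1900$ bp, 5S $\ge 100$ bp, and
  $\ge 18$ tRNAs;
* the type-material quality score is completeness $- 4\times$
  contamination, with no rounding before ranking (whether published
  "score integers" imply rounding is ambiguous; ranking the raw score is
  order-preserving for integer inputs and strictly more informative
  otherwise), ties broken lexicographically by genome id;
* dereplication clusters at $\ge 99.5\%$ identity. Only the threshold is
  published, not the algorithm; a greedy pass in descending quality-score
  order was chosen because it guarantees every representative out-scores
  its cluster and representatives stay pairwise below the threshold.

## Proteorhodopsin spectral tuning

The classifier is a residue lookup at two 1-based columns of the
*unfiltered* protein alignment: position 315 (spectral tuning — methionine
means green light, absorption maximum 525 nm; glutamine means blue light,
490 nm) and position 318 (proton donor — glutamic acid and lysine mark the
two pump clades; phenylalanine or serine marks photosensors). Anything
else, including gaps and the ambiguity code X, is `unknown`, never an
error: the classification is total.

The alignment filter removes columns outside termini 113–585 and columns
whose modal non-gap residue accounts for less than 30% of the non-gap
entries. "30% minimum similarity" has no published operational definition,
so the modal-residue reading was adopted and the threshold exposed. The
filter returns an index map instead of renumbering, so position 315 remains
addressable after filtering; whether published positions refer to the
filtered or unfiltered alignment is ambiguous, and the unfiltered reading
was chosen because a coordinate that survives filtering is then identical
under both readings.

## Abundance–metadata inference

Counts are scaled by the median-of-ratios method: each sample's size factor
is the median over clades of the ratio of its count to the clade's
geometric mean, clades with any zero excluded. One subtlety: multiplying a
single sample's counts by $c$ moves the geometric-mean pseudo-reference by
$c^{1/n}$, so size factors are equivariant only up to that single global
constant — the implementation matches the reference behaviour of the
DESeq-family estimators, which the test suite cross-checks directly.
Samples holding less than 5% of their uniform "fair share" $1/n$ of the
mapped reads are excluded; "accounted for less than 5% of the whole data"
is under-defined and this fair-share reading is flag-configurable.

Per clade and per variable (one variable per model, as the source analysis
fits each variable separately), a negative-binomial log-link GLM is fitted
with $\mathrm{Var} = \mu + \alpha\mu^2$. This is the single dispersion
parameterisation used everywhere, including the simulator. The model uses
raw counts with $\log(\text{size factor})$ offsets, the standard equivalent
of regressing scaled counts that keeps the likelihood a genuine count
likelihood. $\alpha$ is chosen by bounded one-dimensional AIC minimisation
on $\log \alpha \in [\log 10^{-6}, \log 10^{3}]$ (golden-section; robust,
derivative-free, deterministic), with $\mathrm{AIC} = 2k - 2\ell$ counting
$\alpha$ as one parameter. Standard errors use the fixed-$\alpha$
information (dispersion pinned at 1), not a re-estimated Pearson
dispersion. Categorical variables use treatment coding against a reference
level or sum-to-zero coding with an omitted level; the level is chosen by
exhaustively fitting every candidate and minimising AIC, ties to the first
sorted level. Rows with missing metadata are dropped before fitting.

Significance is assessed by Wald tests — a block chi-square for the whole
variable and per-coefficient z tests — with Benjamini–Hochberg correction:
variables kept at adjusted $p \le 0.1$, coefficients within kept variables
at adjusted $p \le 0.05$, signs reported from the coefficient estimates.
Rejection is at $\le$, the step-up definition (ties at exactly the
threshold are rejections). The BH family is adjusted across clades within
each variable by default; the published analysis does not state the family,
so a global option is provided.

Seasonal series are fitted by an NB GAM: a cubic B-spline basis of time
with degrees of freedom 3–9, df and $\alpha$ selected jointly by AIC.
Pointwise confidence bands are Wald-type on the linear predictor,
transformed through the log link (the published confidence procedure is
unstated). Groups are compared against the grand mean — the mean of group
means — and flagged when their interval excludes it. Flagellum-type trait
abundances are normalised by the mean of five single-copy ribosomal protein
genes (S4, S15, S24e, S27ae, L21).

## What the simulators emulate, and what they do not

* `simulate_tree()` draws a uniform random-join topology with exponential
  branch lengths scaled by per-edge gamma rate multipliers. It provides
  controllable rate heterogeneity — the property RED must be robust to —
  but makes no attempt to match any real tree's depth distribution.
* `simulate_marker_table()` plants per-genome completeness and
  contamination. The duplication probability is scaled by 1/completeness so
  the *expected duplicated-marker fraction* equals the requested
  contamination, making both estimators unbiased; empirical estimates
  converge to truth within 1% at $10^4$ markers.
* `simulate_counts()` draws NB counts around
  $\exp(\beta_0 + x\beta + A\sin(2\pi t/12))$ with known library-size
  multipliers; dispersion below $10^{-10}$ falls back to the Poisson limit.
* `simulate_pr_alignment()` plants M/Q at 315 and K/E at 318 over otherwise
  uniform random residues, with optional gap injection.

Passing tests on these inputs shows the *rules and estimators* are
implemented correctly and recover known truth; it does not show anything
about read mapping, binning, alignment quality, or confounding in real
ocean metadata, all of which are upstream of this package's scope.

Simulation sizes used by the test suite were chosen to give stable
Monte-Carlo checks at interactive runtimes: effect recovery over 100
replicates of $n = 500$ samples (mean bias below 0.02, 95% Wald coverage
within $[0.92, 0.97]$), and the null false-positive screen over 30
replicates of 40 clades $\times$ 60 samples. Seeds are fixed throughout;
all generators are bit-reproducible for a fixed seed.

## Known limitations

* Completeness/contamination ignore marker collocation, so contamination
  from a closely related genome sharing the same single-copy markers is
  under-detected relative to CheckM.
* The Wald block test is slightly liberal at small $n$ with estimated
  $\alpha$; the BH screen inherits this. The acceptance checks measure the
  realised type-I rate rather than assuming nominal calibration.
* `exclude_sparse_samples()` and the alignment-filter semantics implement
  one defensible reading of under-specified published procedures; both are
  parameterised so other readings can be expressed.
* Taxonomy normalisation verifies window logic only; placements that
  depend on taxa outside the focal lineage (class- and phylum-level
  reassignments) are out of scope.
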