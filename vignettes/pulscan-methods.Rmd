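---
title: "Methods: windowed PUL detection, dispersion analysis and the surrounding measurements"
author: "pulscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed PUL detection, dispersion analysis and the surrounding measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulscan)
```

# The scientific question

Marine Bacteroidota typically organise polysaccharide degradation in
polysaccharide utilization loci (PULs): a *susC/susD* transporter tandem
flanked by carbohydrate-active enzyme (CAZyme) genes. Some
particle-associated genera, however, degrade laminarin — the soluble
beta-1,3-glucan storage polysaccharide of algae — with the same functional
repertoire *dispersed* across the genome. Deciding between the two
organisations for a given genome requires an explicit, reproducible rule
for what counts as a PUL and what counts as dispersed, plus the supporting
measurements (consensus annotation, label-free proteomics statistics,
fluorescent-substrate uptake scoring, growth and enzyme quantifications)
that connect the genomic claim to physiology. `pulscan` implements that
whole chain as tested, seedable code.

# The gene model and the windowed PUL rule

All window logic runs on **ORF ranks**: genes are ordered along each contig
by ascending start (ties by end, then id) and numbered 0..n-1. Distances in
ranks, not base pairs, make the rule robust to intergenic-length variation.
Coordinates are 1-based inclusive everywhere; the only conversion (to
0-based half-open BED) is centralised in `coords_to_bed()`.

The PUL rule at an anchor gene is:

* take the window of `up = 7` ORFs left and `down = 7` ORFs right of the
  anchor (contig order, truncated at linear contig ends, wrapped on
  circular contigs);
* require a SusC/D tandem pair fully inside the window;
* require at least one consensus CAZyme within `reach = 8` ORF ranks of
  the *nearer* pair member. The anchor itself counts when it carries a
  consensus CAZyme call.

Two deliberately open choices are exposed as options:

* **Window orientation.** "Upstream/downstream" is counted in contig rank
  order, not in the anchor's reading direction, which makes the window
  symmetric under strand flips; the anchor's strand remains available for
  reading-direction analyses.
* **Reach reference.** "Within eight ORFs" is measured from the nearer
  SusC/D pair member by default (`mode = "pair"`), because the PUL concept
  is transporter-centred; `mode = "anchor"` measures from the anchor
  instead. Enlarging `up`, `down` or `reach` can only add evidence, so
  verdicts are monotone in all three parameters (a property the test suite
  checks).

`genome_pul_catalog()` applies the pair-centred rule once per detected
tandem plus once per declared anchor and deduplicates identical evidence
spans. `dispersion_summary()` operationalises "spread over the genome": a
gene set is *clustered* only if all members share a contig and their
minimal enclosing rank window is at most 15 ORFs — the full anchor window
(7 + 1 + 7); anything else, including any multi-contig set, is
*dispersed*.

# Consensus annotation

CAZyme calls follow the two-of-three vote over a declared tool set: a
protein is a CAZyme of family F when at least `min_tools = 2` distinct
tools report F. The vote is counted at family level (GH16), because
engines frequently disagree at subfamily level while agreeing on the
family; the subfamily label (GH16_3) is taken from the single
subfamily-capable tool. SusC proteins are split by evidence class:
a *specific* hit on the sugar-transporter motif TIGR04056 versus
superfamily-only hits (transporter annotation not established). SusC/D
tandems require consecutive ranks, a shared strand, and susD immediately
downstream of susC in the susC reading direction — the canonical
Bacteroidota arrangement; options allow intervening ORFs or strand-agnostic
pairing. Pairing is resolved greedily left-to-right so every gene joins at
most one pair, making results order-independent and deterministic.

The GH16_3 laminarinase classifier encodes the canonical large-enzyme
architecture: signal peptide, PKD beta-sandwich, laminarin-binding domain,
and a split GH16 catalytic domain (N part, inserted domain of unknown
function, C part) containing the WPA active site. A protein is
`canonical_large_laminarinase` iff all of these are present and the
catalytic split is ordered; a length outside the 687–705 AA window of known
full-domain homologues only raises a flag. Because the reference
architecture itself nests domains (the laminarin-binding region spans the
PKD; the WPA site lies inside the catalytic domain), the overlap validation
applies only to the core ordered chain. Motif evidence (the
beta-1,3-glucanase finger-three motif `GGTWPALWALGANFDEVGWP`, the
galactosidase finger-one motif `WKLCTYNNAWSQ`, and `WPA`) is located by
`scan_motif()`, an exact/bounded-mismatch scanner in which an unknown
residue `X` never matches.

# Label-free proteomics statistics

Detection ("expressed") requires a quantified intensity in at least 1 of 3
replicates, evaluated on the raw matrix before any imputation. For testing,
intensities are log2-transformed and missing values are imputed with the
constant 0 on the log2 scale. The moderated statistic is the SAM-type

$$t_{s_0} = \frac{\bar a - \bar b}{s_p \sqrt{1/n_a + 1/n_b} + s_0},$$

with pooled standard deviation $s_p$ and offset $s_0 = 0.15$; $s_0 = 0$
recovers the classical pooled two-sample t exactly (verified to 1e-10
against `t.test`). Significance is assigned by a symmetric volcano cut on
$|t_{s_0}|$ with a permutation FDR: at candidate cut $c$, the estimate is
the median over group-label permutations of the count of $|t| \ge c$,
divided by the observed count; the cut is the smallest $c$ with estimated
FDR at or below 0.05. A 3 vs 3 design has only $\binom{6}{3} = 20$ distinct
label assignments, so the requested 250 permutations fall back to the
exhaustive set (including the identity, which makes the estimator
conservative). Upregulated means significant *and* positive difference.

The generator plants log-normal base abundances (log2 ~ N(25, 2)),
replicate noise of 0.3 log2 units, and left-censors any log2 value below a
detection limit of 21 — intensity-dependent missingness, the mechanism that
motivates constant-0 imputation. One consequence is worth stating plainly:
a down-regulated protein whose shifted abundance straddles the detection
limit gets *partially* censored, and the 0-imputed replicates inflate its
within-group variance, costing sensitivity. That effect measures censoring,
not the test, so the sensitivity scenario in the acceptance checks plants
effects clear of the limit (`detection_limit = 0`, i.e. no missing values —
also the generator's documented no-censoring mode), where sensitivity is
complete; under default censoring it drops to roughly 0.91–0.96. The null
FDR scenario keeps default censoring and realises false-positive
proportions far below the nominal 0.05.

# Uptake scoring

Cells are detected on the DAPI channel (Otsu threshold by default, fixed
threshold for exact reproducibility), labelled with 8-connectivity, and
filtered at 20 px minimum area (0.3 um^2 at the default pixel scale).
Background is the mean substrate gray value outside all objects after a
2-px dilation, excluding halo bleed. An object is positive iff at least
30% of its area is covered by substrate signal (pixels at background + 10
or brighter) *and* its own mean gray value clears the same +10 margin —
the two criteria are evaluated independently, on the linear 0–255
acquisition scale. The image generator plants non-overlapping discs
(radius 3–5 px) with a deterministic count of positives at background + 40,
so the planted fraction is exact; the scorer recovers 0%, 10% and 90%
scenes within 5 percentage points. What these synthetic scenes do *not*
emulate: focus drift, uneven illumination, touching cells and autofluorescent
debris — passing tests show the scoring rule is implemented correctly, not
that segmentation is robust on difficult real slides.

# Growth and enzyme quantifications

The maximal specific growth rate is the steepest slope of log(OD) over a
sliding window of 4 points, restricted to windows with $r^2 \ge 0.98$ (the
exponential phase). The growth generator produces logistic curves
(defaults r = 0.09 h^-1, od0 = 0.01, od_max = 0.5, multiplicative noise sd
0.02, sampled every 2 h — the cadence of manual side-arm photometer
readings). On a pure logistic the instantaneous rate is strictly below r
(by about 2.5% at these defaults), and the max-over-windows estimator adds
a small upward noise bias; across 100 seeds the mean estimate stays within
5% of r (about 2–3% in practice). A capped-exponential model is available
for which the noiseless fit recovers r exactly.

Cell densities scale mean counting-grid counts to the filter area over the
filtered volume, flagging fewer than 30 grids or 280 or fewer total cells.
Enzyme activity converts a chromophore absorbance slope via Beer–Lambert
(default epsilon 7,500 M^-1 cm^-1, nitrophenol at 405 nm) into
nmol s^-1 (ug protein)^-1; calibration curves are ordinary least squares
with extrapolation flags, and consumption percentages are
`100 (initial - final) / initial`.

# Synthetic genomes and what passing means

`sim_genome()` places features on anchor slots 30 ranks apart so that no
planted element can interact with another through the 7/7/8 windows:
planted PULs (tandem + GH16_3 at two ranks' distance + GH3), decoy tandems
without CAZymes, lone superfamily-only susC genes, single-vote CAZyme
decoys, and consensus-grade dispersed pathway genes at pairwise distances
of at least 100 ranks. This yields exact ground truth (the PUL caller
recovers planted PULs with precision = recall = 1 and agrees with a
brute-force predicate scan on hundreds of random genomes), but it
deliberately avoids the hard cases of real genomes — overlapping PULs,
tandem arrays, fragmented assemblies splitting a locus across contigs —
where the rule's verdicts depend on assembly quality rather than biology.

# Numerical and degenerate-input choices

* Rank ties (identical starts) break by end, then gene id — determinism
  under record shuffling.
* A raw LFQ intensity of exactly 1 collides with the imputation constant
  after log2; it is kept but flagged, as is a quantified 0 (treated as
  missing).
* Zero within-group variance with $s_0 = 0$ yields an infinite statistic,
  reported as p -> 0 with a warning; any positive $s_0$ regularises it.
* `fdr = 0` accepts nothing by definition.
* A flat OD series has growth rate 0 (the zero-slope fit is exact).
* Objects covering an entire image leave the background undefined and
  raise an error rather than a silent 0.

# Problem sizes

The shipped checks use 200 random genomes of ~500–2,100 genes for oracle
equivalence, 20 x 2,000 proteins for null FDR, 100 seeds for growth
recovery and 150-cell scenes for imaging; the whole suite runs in well
under a minute per module on a single CPU.
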