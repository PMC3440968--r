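---
title: "Methods: two-colour miRNA arrays in a gender-by-stressor design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-colour miRNA arrays in a gender-by-stressor design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirray)
```

## The experiment this package models

mirray analyses two-channel (Cy3/Cy5) miRNA microarray experiments with a
crossed design: two genders times a set of stressor treatments (an
untreated control, feeding with an entomopathogenic bacterium, a sham
saline injection, peptidoglycan injection, mild heat shock and
starvation), as used to ask whether insects such as the red flour beetle
adjust miRNA expression in a gender- and stressor-specific way. Each
gender-by-treatment cell contributes two biological replicates (pooled
RNA samples); the two replicates of a cell are co-hybridized on one
chip, one labelled Cy3 and the other Cy5. The chip carries 455 mature
arthropod miRNA probes (386 experimentally confirmed, 69 computationally
predicted), each spotted as several repeating spots.

Because the raw per-chip data of such service-provider assays are
typically not public, the package ships a synthetic-data generator that
emulates the chip design and layout with planted, recoverable ground
truth. Every downstream stage is exercised and validated against that
truth; the package is equally usable on real spot-level TSV exports in
the documented dialect.

## Signal model of the generator

For probe $p$ with baseline $b_p \sim N(\mu_b, \sigma_b^2)$ (log2
intensity units, defaults $\mu_b = 10$, $\sigma_b = 1.5$), a spot on
channel $c$ of a chip hybridized with sample $s$ measures

$$\mathrm{raw} = 2^{\,b_p + \tau_{p,t(s)} + \gamma_{p,t(s)}\,[g(s)=F] +
\varepsilon + \beta_c(\ell)} + B,$$

where $\tau$ and $\gamma$ are the planted treatment and gender (female
minus male) log2 effects, $\varepsilon \sim N(0, \sigma_n^2)$ is
per-spot noise (default $\sigma_n = 0.1$), $B \sim N(\mu_B, \sigma_B^2)$
floored at zero is additive raw-scale background (defaults 100 and 30,
both recorded in the chip file), and $\beta_c$ is an
intensity-dependent dye bias applied to Cy5 only. Planted effects have
magnitude 1.5 log2 by default, on 10% of probes per treatment and 15%
of probes for gender; a gender-specific probe carries its effect in a
random subset of treatments so that per-treatment sets, their Venn
regions and the all-treatment core are all non-trivial.

Design choices worth stating explicitly:

* **Dye bias is linear in log2 intensity** ($\beta_c(\ell) \propto \ell -
  \mu_b$). Real two-colour bias curves are smooth but often curved; the
  linear choice makes the bias exactly removable by a local-linear
  smoother, which turns normalization correctness into a sharp test
  (residual M below $10^{-6}$) instead of an approximate one. The
  correction path is LOWESS removal, not dye-swap averaging: the layout
  has no dye swap.
* **Background is additive on the raw scale** under a log-normal
  signal. The detection rule only needs the per-chip background mean
  and s.d., which the file format carries; whether a provider subtracts
  local or global background is unknowable from such files, so the
  per-chip global statistic is used.
* **Replicate variability comes from spot-level noise.** With four
  repeating spots, per-sample integrated noise is roughly
  $\sigma_n / 2$; there is no separate biological-replicate variance
  component. Passing tests therefore demonstrate correctness of the
  statistical machinery under the stated model, not power under real
  biological replicate dispersion, which is typically larger.
* `n_bio_replicates` must be even (replicates are co-hybridized in
  pairs) and at least 2 (otherwise no t-test is defined).

The qPCR generator plants per gene-gender-treatment fold differences
(no change with probability 0.45, otherwise $2^{U(-1.5,3)}$), builds
Ct values as a gene reference Ct minus log2 relative expression plus a
per-sample RNA-loading offset and technical noise (s.d. 0.1 cycles,
three technical replicates), with a constant 18S normalizer. The
loading offset cancels in the delta-Ct step by construction.

## Preprocessing

Per chip and channel, repeating spots are integrated: background mean
subtracted with a floor at zero, then averaged. The repeat CV is the
sample s.d. over the floored spot values divided by their mean — the
only CV computable from spot-level data of this shape. A probe is
**detectable** when its integrated signal exceeds three times the chip
background s.d., its repeat CV is below 0.5, and at least 50% of its
repeating spots individually clear the same 3-s.d. level (the "above
detection level" threshold is deliberately reused per spot, since no
separate per-spot level is defined by the rule). Boundary semantics are
strict for the first two conditions and inclusive for the repeat
fraction; the monotonicity of the call in integrated signal is a tested
invariant.

Normalization is within-chip MA-LOWESS followed by across-chip median
centering. Only probes with positive integrated signal in both channels
enter the fit of M on A; the fitted trend is removed symmetrically
(half from each channel) so A is untouched. Log2 of a nonpositive
integrated signal is a missing value and stays missing throughout.
With fewer than 10 co-positive probes the LOWESS fit would be
meaningless, so the chip falls back (with a warning) to median-only
normalization. Median centering subtracts each sample's median over its
chip's co-positive probes, which therefore sits exactly at zero — the
operational reading of "normalize across all arrays" for a design in
which every chip is one condition.

The LOWESS implementation is the classic robust locally weighted
regression: for each point a weighted least-squares line over the
$\lceil \mathrm{span} \cdot n \rceil$ nearest x-neighbours (equidistant
ties resolved toward the lower index), tricube distance weights, and
bisquare robustifying reweighting of residuals against $6 \times$ the
median absolute residual. Defaults are span 0.3 and 3 robustifying
iterations, both configurable. On noise-free data whose M-A trend is
linear the smoother is exact and normalization is idempotent; with
noise a second pass shifts values on the order of the smoothed noise —
local regression is not a projection — so idempotence is only exact in
the noise-free case, which is how it is tested.

## Differential expression and summaries

Contrasts are pooled-variance two-sample t-tests on normalized log2
intensities, two-sided, $df = n_A + n_B - 2$. With two replicates per
group this is a 2-df test — low-powered by construction, matching the
study design it mirrors; no moderated-variance shrinkage is applied on
purpose. Degenerate cases are pinned by convention: zero pooled
variance with equal means gives $t = 0, p = 1$; with unequal means
$t = \pm\infty, p = 0$ (which makes zero-noise recovery tests exact);
groups under two values are untestable and reported as `undetected`
rather than given a silent p-value.

A probe enters a contrast only if detectable in at least half the
samples of at least one group — permissive enough to keep
presence/absence responders, strict enough to drop all-background
probes. Classes: `up` / `down` at $p < 0.05$ and at least twofold
(gender contrasts) or any fold (treatment-vs-control contrasts, where
the reporting convention names only $p < 0.05$); both thresholds and an
optional Benjamini-Hochberg correction are configurable, with
study-faithful defaults (no correction). Gender contrasts are female
minus male; treatment contrasts are computed within gender. Whether the
original analysis tested intensities or per-chip ratios is not
derivable from its description; intensities-with-design is the
implemented default.

`summarize_gender()` produces the per-treatment gender-specific sets
(female-biased and male-biased are disjoint by construction),
percentages of total probes both raw and display-rounded (the rounded
values reproduce printed-table arithmetic such as 245/455 → 54%), Venn
region counts by exact set algebra (regions partition the union), and
the core set common to all treatments.

## Clustering

Probes in the gender-specific union are clustered over their
per-treatment log2(F/M) profiles: Euclidean distances with
pairwise-complete dimensions rescaled by $\sqrt{D/D_{used}}$ (so probes
undetected in some treatments still cluster), then average-linkage
(UPGMA-style) agglomeration in which the cluster-cluster distance is
the arithmetic mean of member pairwise distances. Near-tied minima
(relative $10^{-8}$) are broken toward the lexicographically smallest
pair of cluster creation indices, which makes trees reproducible and
lets a brute-force agglomerator verify exact tree equality. Average
linkage is monotone, so merge heights never decrease. Trees serialize
to Newick with height-difference branch lengths (ultrametric), the
portable stand-in for interactive heatmap viewers; both probe and
sample axes can be clustered.

## Two-factor ANOVA

Per probe, a balanced fixed-effects gender-by-treatment decomposition
from cell means; under balance type-I and type-III sums of squares
coincide, and the SS identity (effects plus residual equal total) is
tested to $10^{-9}$ relative. Unbalanced or incomplete tables are
rejected rather than silently reweighted — the emulated design is
balanced, and probes with missing values are flagged untested. All
sums of squares zero is reported as $F = 0, p = 1$.

## qPCR relative quantification

Delta-delta-Ct with fixed efficiency 2 (configurable per call):
per-sample $\Delta Ct$ against the 18S normalizer over technical
replicates, $\Delta\Delta Ct$ against the mean $\Delta Ct$ of the
same-gender calibrator condition, per-replicate fold
$2^{-\Delta\Delta Ct}$, reported as mean ± s.d. across biological
replicates. The s.d. is taken across replicate folds, not propagated
from Ct error. Induction is strict: fold > 2, so exactly twofold does
not count. Calibrators are gender-matched because the gender comparison
happens after within-gender induction; a pooled-control variant would
change female/male fold ratios and is intentionally not the default.

## Problem sizes and reproducibility

The test suite runs the full 455-probe, 24-sample, 12-chip emulation
for end-to-end checks and smaller 40-probe configurations for unit
tests; statistical checks use 200 simulated null datasets of 455
probes for the t-test's type-I error, 500 probes for ANOVA p-value
uniformity, and 200 random instances up to 12 leaves for tree equality
against brute force. Every random draw descends from a single
configuration seed; identical configurations produce byte-identical
study files and pipeline outputs, recorded with MD5 digests in each
run's JSON manifest.

## Known limitations

* No biological-replicate variance component, no batch effects, no
  spatial or print-tip artifacts in the generator.
* No quantile or variance-stabilizing normalization, no empirical-Bayes
  variance moderation, no permutation tests — the pipeline is
  deliberately faithful to the simpler analysis it models.
* qPCR efficiency is fixed per run, not estimated from standard curves.
* The image-analysis layer (gridding, per-spot local background) is out
  of scope; analysis starts at spot-level signals.
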