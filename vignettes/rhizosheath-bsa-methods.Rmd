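---
title: "Mapping rhizosheath QTLs by bulked segregant analysis: models and methods"
author: "rhizobsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping rhizosheath QTLs by bulked segregant analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizobsa)
```

## The problem and the phenotype

The rhizosheath is the layer of soil that adheres to roots after gentle
shaking; its size influences water and nutrient acquisition and is a
candidate breeding target in dryland cereals such as pearl millet. The
working phenotype is RAS/RT: the dry mass of root-adhering soil divided by
the dry mass of root tissue, a dimensionless ratio computed by
`ras_rt_ratio()`. In the designs this package supports, an F2 population
from two inbred parents contrasted for RAS/RT is phenotyped in successive
greenhouse blocks, and DNA pools ("bulks") of the phenotypic extremes are
sequenced to detect allele-frequency divergence at loci controlling the
trait.

## Phenotype-side models

**Block ANOVA and bulk selection.** Ratios are strictly positive and
right-skewed, so `fit_block_model()` works on the natural log of the ratio
(the base cannot change the residual ranking, only the scale) and removes
fixed block effects by one-way ANOVA. Bulks are the `round(f * n)`
individuals with the smallest and largest residuals (`select_bulks()`,
default tail fraction `f = 0.10`; 547 F2 gives 55 per bulk). Ties are broken
by id order so the selection is reproducible. Selecting on residuals rather
than raw ratios prevents a strong block from monopolising a tail.

**Broad-sense heritability.** `heritability()` fits the one-way
random-effects model `y = mu + line + residual` and reports

$$H^2 = \frac{\widehat{\mathrm{Var}}(\mathrm{line})}
{\widehat{\mathrm{Var}}(\mathrm{line}) +
 \widehat{\mathrm{Var}}(\mathrm{res}) / \bar n_{\mathrm{plant/line}}}.$$

The default estimator is the ANOVA method of moments with the standard
effective replicate number for unbalanced designs and truncation of a
negative between-line component at zero; `method = "reml"` refits the
components with lme4 when an iterative estimate is preferred. The two agree
closely away from the boundary. $H^2$ is invariant to shifting or rescaling
the phenotype, which the test suite checks.

**Trait correlations and colonization scores.** `trait_correlations()`
reports pairwise coefficients, p-values and squared coefficients over
per-line trait means. Both Spearman (default, robust to monotone
transforms) and Pearson (for adjusted least-square means) are exposed,
because both conventions are common for this kind of trait panel.
Mycorrhizal colonization of root fragments scored 0–5 is summarised by
`mycorrhiza_scores()` as frequency $F = n/N \times 100$ and intensity
$I = (95 n_5 + 70 n_4 + 30 n_3 + 5 n_2 + n_1)/N$, both in percent.

## The synthetic-data generator

`simulate_bsa_dataset()` produces the full chain - genotypes, phenotypes,
bulks, pooled read counts - so every downstream stage can be validated
without any sequencing data.

* **Meiosis.** Gametes are simulated as a marker-to-marker Markov chain
  whose switch probability between adjacent markers is the Haldane
  recombination fraction $r = (1 - e^{-2d})/2$ for map distance $d$. With
  no crossover interference this chain is distributionally identical, at
  the markers, to dropping a Poisson number of uniformly placed crossovers
  per chromosome. Genotypes are sums of two independent gametes and
  segregate 1:2:1.
* **Genome defaults.** 7 chromosomes of 150 Mbp and 1.5 Morgan
  (about 1 cM/Mbp, a typical plant rate; pearl millet's genome-wide average
  is somewhat lower), physical and genetic positions related by a uniform
  rate per chromosome. All of this is configurable in `sim_config()`.
* **Phenotypes.** Log-ratio = grand mean + block effect + QTL effects
  ($a(g-1) + d\,\mathbf 1\{g=1\}$) + Gaussian residual, with the residual
  variance set so the genetic fraction of the non-block variance equals
  `heritability_target`. The default grand mean `log(22.3)` puts simulated
  ratios on the observed F2 scale (roughly 2-55).
* **Pooled reads.** Site depth is gamma-Poisson (mean 875 by default,
  matching deep target-capture pools; dispersion 0.2 gives the heavy depth
  tails that motivate percentile filters), alternate read counts are
  binomial in the true pooled frequency, and missing calls and multiallelic
  contamination are injected at 1% each so the filter cascade has real work.

What the generator does *not* emulate: genotyping or alignment error,
reference bias, indels, segregation distortion, non-uniform recombination
(hot/cold spots), and selective genotyping artefacts. Passing tests
therefore validate the statistical machinery, not robustness to those
data pathologies.

## SNP filtering

`filter_cascade()` applies, in order: multiallelic removal; a pooled
alternate-allele frequency floor of 0.25; total-depth percentile trimming
(below the 25th or above the 95th percentile, percentiles estimated on the
sites surviving the frequency step with the linear-interpolation definition,
boundary values kept); removal of sites missing in at least one of the two
bulks (the operative meaning of "more than 50% missing" with two samples);
and a 5% pooled minor-allele-frequency floor. Each removed site is
attributed to the first rule that rejects it, and the report records the
cascade. Two genuinely ambiguous readings are settled by switches:
`freq_symmetric` (whether the 0.25 floor also trims mirrored extremes - off
by default, since after polarization an F2 alternate allele should sit near
0.5 and the rule plainly targets artefactual low-frequency calls) and
frozen `depth_bounds` (to make re-runs strictly idempotent). Alleles are
polarized by `polarize()` so that the reference allele is the low-phenotype
parent's allele everywhere.

## The ED statistic, windows and significance

At each marker the bulk allele frequencies are read fractions
(`bulk_frequencies()`), and the per-marker signal is the Euclidean distance
between bulks,

$$ED_m = \sqrt{(f_{aL} - f_{aH})^2 + (f_{AL} - f_{AH})^2}
       = \sqrt 2\,\lvert f_{aL} - f_{aH}\rvert,$$

zero when the bulks agree and $\sqrt 2$ at opposite fixation. A variant that
contrasts the two alleles *within* each bulk
($\sqrt{(f_{aL}-f_{AL})^2 + (f_{aH}-f_{AH})^2}$) is retained behind
`formula = "within"` for comparison with sources that typeset the formula
that way; it cannot distinguish the direction of divergence, so the
between-bulk form is the default.

`window_statistic()` sums $ED_m$ over sliding windows of 100 consecutive
markers (step 1, never crossing a chromosome boundary) and raises the sum
to the fourth power - the "cumulative, then fourth power" reading; summing
per-marker fourth powers is available as `window_stat = "pow4sum"`. The
window value is assigned to the centre marker (the 50th of 100); markers
without a full window carry `NA`. The fourth power sharpens genuine
multi-marker divergence against isolated noisy markers.

**Significance.** BSA studies commonly draw a "95% confidence" line on the
ED profile without describing its construction, so the package makes the
null explicit:
under no-QTL segregation each bulk's frequency at a marker is a
Binomial$(2k, 1/2)/2k$ draw (bulks of $k$ F2 individuals), read counts are
binomial at the observed site depths, and the windowed statistic is computed
on each simulated genome. The default threshold is the $(1-\alpha)$ quantile
of the per-genome *maximum*, controlling the family-wise false-positive rate
across all markers; a pooled per-window quantile is available as a less
conservative option. The simulation seed and method are recorded in the
result. This null treats markers as independent: it calibrates read and
bulk-composition noise exactly, but linked drift along a real bulk genome is
positively correlated between overlapping windows, so genome-wide error
control on fully linked genomes is approximate (see Limitations).

## Regions and GWAS overlap

A significant marker's "support" is operationalized as the physical span of
its 100-marker window - the resolution of the statistic; overlapping or
abutting spans merge into regions (`call_regions()`), named
`RAS<chromosome>.<index>`, with the peak at the marker maximising the
windowed statistic, `length = end - start`, and the count of significant
markers inside. GWAS hits contribute ±50 kb windows, merged when they
overlap (`gwas_windows()`), and `overlap_report()` tabulates overlap
lengths, gaps and peak-to-hit distances per (region, hit) pair. Coordinates
are 1-based and closed everywhere inside the package; BED conversion
(0-based, half-open) happens only in `write_regions_bed()`.

## Numerical and design choices

* Percentiles use the linear-interpolation definition (R type 7);
  boundary-equal sites are kept, so constant-depth tables lose nothing.
* Bulk-size rounding is `round()`, so 547 F2 at 10% gives 55.
* The null threshold refuses fewer than 20 simulated genomes (quantile
  instability) and degenerates to zero at `alpha >= 1`.
* Window centre assignment uses the 50th marker of 100; start/peak
  alternatives were not retained because centre assignment keeps region
  spans symmetric around the evidence.
* All randomness flows through explicit seeds; a seeded configuration
  reproduces every table bit for bit, and the RNG state of the caller is
  restored afterwards.

## Validation scale and what the checks show

The test-suite studies run at desk scale, chosen to finish in minutes on
one CPU while keeping the design realistic: null calibration and QTL
recovery use 2 chromosomes × 2000 markers, bulks of 55 from 547 F2 and
200× depth; the threshold is calibrated on 500 simulated null genomes and
evaluated on 200 fresh ones; heritability recovery uses 200 replicates of
the 181-line × 1408-plant panel design with generating $H^2 = 0.72$,
recovered to within 0.02 in the mean by the plug-in estimator.

## Known limitations

* **Peak localization.** With bulks of 55, pooled allele-frequency drift is
  correlated along the chromosome (correlation $\approx 1-2r$), and the ED
  signal near a QTL is a cusp of slope $2\,\Delta p_0$ per Morgan. Balancing
  that slope against the drift increment gives a peak localization scale of
  a few centimorgans *regardless of sequencing depth*. At about 1 cM/Mbp
  this means peaks typically land within 1–4 Mbp of the true locus: region
  coverage of the truth is essentially certain, but sub-2-Mbp peak accuracy
  is reached in only about two thirds of simulated scans, and raising the
  QTL effect saturates that rate near 80% rather than curing it. Users
  should read peaks as region-scale, not gene-scale, evidence.
* **Threshold null.** The simulated null is marker-independent. On fully
  linked null genomes the realised family-wise error of the genome-max
  threshold can deviate from the nominal level; the package's calibration
  check is against the same independent-marker null it simulates.
* The ambiguous published readings (one- vs two-sided frequency floor,
  summed vs per-bulk depth percentiles, window semantics) are settled by
  documented defaults with switches, so exact third-party threshold values
  are not expected to be reproduced number for number.
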