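---
title: "Karyotype polymorphism analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype polymorphism analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyopoly)
```

## The problem

Laboratory lines of the free-living flatworm *Macrostomum lignano* segregate
a striking karyotype polymorphism: besides the 'normal' complement of
2n = 8 (one pair of large and three pairs of small metacentric chromosomes),
a majority of worms in some inbred lines carry one (2n = 9) or two (2n = 10)
additional copies of the large chromosome, with occasional 'abnormal'
variants. `karyopoly` implements the complete quantitative chain for such a
system:

1. **morphometry** — per-chromosome metrics from arm-length measurements and
   Levan centromere classification;
2. **karyotype calling** — specimen-level karyotypes from replicate metaphase
   plates, with mosaicism detection, and population tabulation;
3. **assortment model** — gamete-frequency estimation and a Hardy–Weinberg
   style test of independent assortment of the extra chromosome, with
   Fisher combination across lines;
4. **cross model** — Mendelian expectations for crosses among 2n = 8/9/10
   parents and a viability-selection estimator;
5. **population simulator** — a Wright–Fisher forward model with meiotic
   drive and zygotic selection, plus likelihood fitting;
6. **synthetic data** — a generator that emulates the measurement tables, so
   every stage is testable without microscopy data.

## Morphometry

For a chromosome with short-arm length $S$ and long-arm length $L$ (µm),
measured within one metaphase spread:

* absolute length $AL = S + L$;
* relative length $RL = 100 \cdot AL / (\tfrac12 \sum_{plate} AL)$, i.e.
  relative to the haploid complement length of its own plate, so plate-level
  condensation cancels and $\sum RL = 200\%$ per plate;
* arm ratio $R = L/S \ge 1$ and centromeric index $CI = S/(S+L) \le 0.5$,
  linked by $CI = 1/(1+R)$.

Centromere position follows the Levan convention: metacentric (m) for
$1 \le R \le 1.7$, submetacentric (sm) for $1.7 < R \le 3$, subtelocentric
(st) for $3 < R \le 7$, acrocentric/telocentric (t) beyond. Boundary values
belong to the lower class — the classification must be a deterministic step
function, and no observed chromosome sits exactly on a boundary, so the tie
rule is a pure convention.

**Size classes.** The bimodal karyotypes have a large chromosome more than
twice the length of the smallest, while uniform karyotypes (e.g.
*M. spirale*) vary only ~1.2-fold. Chromosomes of a plate are sorted by
decreasing $AL$ and the candidate split is placed at the largest adjacent
ratio; a split is accepted only if that ratio reaches `gap_ratio = 1.5`,
halfway between the two observed regimes. Because the rule uses only
within-plate ratios it is invariant to condensation stage. The threshold is
a tunable argument.

**Pair summaries.** Without hybridisation data there is no homology
information, so chromosomes are paired by consecutive ranks after sorting —
the convention used in the original morphometric tables. Rank-pairing
slightly overestimates differences between adjacent pairs (an order-statistics
bias the original authors also acknowledged); summaries therefore report
means of per-plate values, not ratios of means, and the two differ slightly
(e.g. mean RL of the largest pair is 41.2 when averaged per plate, versus
41.4 evaluated at the mean lengths). Standard deviations are taken across
plates *and* homologs, the only option that does not require homology
assignments.

## Karyotype calling

A specimen's karyotype is the modal (n_large, n_small, anomaly) combination
across its plates, requiring at least `min_plates = 10` plates — the study
design rule that makes within-individual mosaicism detectable at all. Two
conventions are needed where the source protocol is qualitative:

* `majority_fraction = 0.9`: a call is non-mosaic when the modal combination
  accounts for ≥ 90% of plates. One aberrant spread in ten is tolerated
  because broken or overlapping spreads are routine technical artifacts; a
  stricter rule would flag technical noise as biology.
* Modal ties break toward the smaller 2n (conservative against over-calling
  aneuploidy) and are always flagged mosaic.

Categories are profile-relative: `normal`, `plus_one_large`,
`plus_two_large` require the small complement intact; everything else —
structural anomalies, deviant small counts, or *fewer* large chromosomes
than normal — is `abnormal`, mirroring the published table structure, which
has no 'minus' column. Mosaic specimens are tabulated under `abnormal`
(none were observed in the study, but the bucket must exist). Percentages
are rounded to one decimal, matching the reporting convention.

## The assortment model

Let $p$ and $q = 1 - p$ be the population frequencies of gametes carrying
one (n = 4) versus two (n = 5) copies of the large chromosome. Under fair
meiosis, 2n = 8/9/10 parents produce n = 5 gametes with probability
0, ½, 1, so allele counting over specimens gives the maximum-likelihood
estimate

$$\hat p = \frac{2 c_8 + c_9}{2(c_8 + c_9 + c_{10})},$$

and random gamete union predicts class frequencies $(p^2, 2pq, q^2)$.
'Abnormal' karyotypes are excluded upstream by the caller. The Pearson
$\chi^2$ uses no continuity correction and **1 degree of freedom**
(3 classes − 1 − 1 estimated parameter); both choices are confirmed by exact
reproduction of the published statistics (6.43 and 2.17) from the published
counts.

**Fisher's combination.** The statistic is $-2\sum\ln p_i$. The standard
reference distribution is $\chi^2_{2k}$; the analysis this package
reproduces referred the two-test statistic to $\chi^2_2$ instead. Both
conventions are implemented (`"standard"`, `"fixed2"`) and reported side by
side; with a single p-value they coincide and return the input unchanged.
Whether the fixed-df convention was intentional cannot be determined from
the source, so neither is silently preferred — but only `"fixed2"`
reproduces the published combined probability of 0.0016.

## The cross model

Offspring-class probabilities are the convolution of the parental gamete
distributions. Classes with zero Mendelian probability are dropped before
the $\chi^2$ (df = classes − 1, confirmed by the published df), and a
nonzero observed count in an impossible class raises an error rather than a
statistic, since it signals a parental miscall or non-Mendelian event.

One published inconsistency is handled explicitly: the 9 × 10 cross is
printed with n = 25 offspring, but its percentages (61.5/38.5) and statistic
(1.38) are only consistent with counts (16, 10), n = 26. The packaged table
carries (16, 10).

**Viability selection.** The deficit of 2n = 8 offspring in 9 × 9 crosses is
modelled as zygote viability selection: class probabilities proportional to
$(m_8(1-s), m_9, m_{10})$. The MLE has the closed form
$\hat s = (N m_8 - c_8)/(m_8 (N - c_8))$, clamped to $[0,1]$; intervals come
from the likelihood-ratio profile at the $\chi^2_1$ 95% cutoff, with
boundary cases ($c_8 = 0 \Rightarrow \hat s = 1$) handled exactly. For the
observed 9 × 9 counts (8, 54, 25) this gives $\hat s = 0.696$
(95% CI 0.41–0.86). Gamete-level distortion is deliberately *not* fitted
here — from a single cross the two mechanisms are confounded; the simulator
module owns that distinction.

## The population simulator

Generations are discrete and non-overlapping (a Wright–Fisher
simplification; the cultured populations are continuous, but no demographic
parameters exist to justify anything richer). Each offspring draws two
*distinct* parents uniformly — the species is an obligately outcrossing
simultaneous hermaphrodite, so selfing is structurally impossible — one
gamete from each (a 2n = 9 parent transmits its extra chromosome with
probability $k$; $k = 0.5$ is fair meiosis), and the zygote survives with
probability $1 - s$ if 2n = 8, 1 otherwise; rejected zygotes are redrawn
until the population is replenished. Configurations where every producible
zygote is lethal are detected and refused before sampling. Trajectories are
bit-reproducible given `random_seed`.

The infinite-population limit is available as `deterministic_recursion()`:
gamete pool $g_5 = f_{10} + k f_9$, Hardy–Weinberg zygotes, viability
reweighting, renormalisation. Its fixed-point structure drives several
design decisions:

* With fair meiosis ($k = 0.5$) and any $s > 0$ the recursion has **no
  interior equilibrium**: $g_5' = g_5 / (1 - s(1-g_5)^2) > g_5$, so the
  extra chromosome sweeps to fixation. Selection against the euploid class
  alone cannot maintain the polymorphism.
* Interior equilibria exist exactly on the balance manifold
  $s(1 - g_5^*) = 1 - 2k$: drive *toward* the n = 4 gamete ($k < 0.5$)
  balanced by viability selection against 2n = 8. `equilibrium_freqs()`
  iterates the recursion to a fixed point (tolerance $10^{-10}$) and is the
  analytic oracle for the simulator tests.

**Fitting.** Because iterating to a fixed point degenerates for the
one-parameter models (the only equilibria off the manifold are boundaries),
`fit_karyotype_model()` instead models the observed census as **one
generation of the recursion applied to the parental class frequencies**.
With a known parental composition this is a proper multinomial likelihood;
without one, the parental frequencies default to the observed ones (a
stationarity assumption, flagged in the output as exploratory). The
`selection_only` model has a closed-form MLE; `distortion_only` is a 1-D
profile; the `joint` model is exactly identified (two parameters, two
degrees of freedom), so it fits any interior count vector perfectly — its
content is the estimates and their profile CIs, not goodness of fit — and
flat profiles (e.g. no 2n = 9 parents) are flagged as non-identifiable.
This is also the honest answer to a question the data cannot settle: a
single count vector cannot distinguish meiotic drive from zygotic selection,
and the joint CIs make that visible.

## The synthetic-data generator

The generator emulates the *statistical structure* of the study's tables,
not its images:

* **Arm lengths** are truncated normals per chromosome pair with the
  observed per-pair means; only means ± SD are reported for the real data,
  so no heavier-tailed form is justifiable.
* **Condensation**: observed chromosome length depends strongly on mitotic
  stage, which affects a whole plate at once. Each plate draws one
  multiplicative lognormal factor (sdlog 0.12, meanlog set for mean exactly
  1), and the chromosome-level arm SDs are set to *half* the observed total
  SDs, so the marginal spread approximately matches the observed tables
  while within-plate ratios — which drive size-splitting and centromere
  classes — stay realistically tight. Additive per-arm measurement noise
  (SD 0.05 µm) approximates digitising error; the longer measured arm is
  always recorded as the long arm, as a human measurer would.
* **Extra large chromosomes** reuse the pair-1 parameters: normal and
  additional large copies are indistinguishable by banding in the study
  system.
* **Abnormal variants** are drawn uniformly from the small observed
  repertoire (small-chromosome aneuploidies, combined aneuploidies, a
  doubled complement, structurally rearranged plates); no per-variant
  frequencies were reported, so a uniform draw is the only defensible
  choice.
* **Mosaics** alternate plates between the assigned karyotype and the one
  with an extra large chromosome (50:50), the simplest mixture that any
  reasonable majority rule must catch.
* Whether measurement error correlates at plate or chromosome level is
  unknowable from summary tables; one plate-level factor plus i.i.d. noise
  is assumed.

What passing tests on this generator do **not** show: robustness to
segmentation errors, overlapping chromosomes, partial spreads, or
non-normal length distributions in real micrographs. The generator's
defaults are fixed study conditions, not tuning knobs.

## Numerical and testing choices

* Tolerances: equilibrium iteration stops at $10^{-10}$ max frequency
  change; profile-CI roots are found to $10^{-8}$; probability conservation
  is asserted to $10^{-12}$.
* Degenerate inputs error early with typed conditions (schema errors carry
  offending line numbers; impossible offspring raise a dedicated class).
* Optimisation: the joint fit seeds box-constrained BFGS with the analytic
  saturated solution plus grid restarts, so the saturated optimum is found
  exactly when interior.
* Test problem sizes were chosen to make Monte-Carlo error a small fraction
  of each tolerance: 10⁴ null replicates at the observed census size for
  type-I calibration of the assortment test (rate 0.05 ± 0.01); 10³
  replicates for CI coverage of the selection and distortion estimators
  (≥ 93% nominal-95% coverage); five replicates of N = 10⁵ over ten
  generations for simulator–recursion agreement (< 2% relative error);
  10⁴ specimens × 10 plates for full-pipeline recovery of the gamete
  frequency (within 0.02). A naive trend test on the mean neutral
  trajectory would overreject (the mean of replicate random walks is itself
  autocorrelated), so neutrality is tested on per-replicate slopes, which
  are independent.

## Known limitations

* No homology assignment: pair statistics inherit the rank-pairing bias.
* The simulator has no mutation, no 'abnormal' class (no rates are
  reported), no overlapping generations, and no spatial structure.
* The assortment test relies on the $\chi^2$ approximation; at very small
  line sizes an exact multinomial test would be preferable, but the
  reproduced analyses are all comfortably in the approximation's range.
* `fit_karyotype_model()` without `parental_freqs` is exploratory by
  construction; treat its joint-model output as a reparameterisation of the
  data, not as evidence for a mechanism.
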