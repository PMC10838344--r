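---
title: "Methods: flip-signature mode-of-action analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flip-signature mode-of-action analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipmoa)
```

## The question the pipeline answers

A three-condition bulk RNA-seq design - control, perturbed (e.g. a
receptor overexpressed in chondrocytes), and perturbed plus a candidate
drug - asks a simple mode-of-action question: which genes does the
perturbation dysregulate, and which of those does the drug put back?
Genes that move up under the perturbation and back down once the drug is
added (or the mirror) are *flip* genes; they form a signature of the
drug's corrective activity that can then be projected onto pathways,
transcription-factor regulons, and a library of drug expression profiles
to find compounds with a similar corrective signature and their enriched
targets.

## Differential expression

Both contrasts are tested against the same control with a transparent
negative-binomial Wald test (`nb_wald_contrast()`):

1. **Normalization.** Median-of-ratios size factors: sample $j$ gets
   $s_j = \mathrm{median}_g\, K_{gj} / (\prod_j K_{gj})^{1/m}$ over
   genes expressed in every sample. A `pseudo_reference` flag switches
   the geometric means to positive counts only for very sparse data.
2. **Dispersion.** Per gene, a pooled method-of-moments estimate
   $\hat\alpha_g = \frac{(v_1 - \bar x_1) + (v_2 - \bar x_2)}
   {\bar x_1^2 + \bar x_2^2}$ on normalized counts, floored at $10^{-8}$.
   With 3-5 replicates this estimator has only $n_1+n_2-2$ degrees of
   freedom, and plugging it into a normal-reference Wald test makes the
   test anti-conservative (the statistic behaves like a $t$ with few
   df). We therefore shrink each estimate toward a fitted
   mean-dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ with a prior
   weight of `prior_df = 20` pseudo-degrees of freedom:
   $\tilde\alpha_g = (d_g\hat\alpha_g + d_0\hat\alpha_{\mathrm{trend}})
   /(d_g + d_0)$. This is the one place where we deliberately depart
   from a "no moderation anywhere" design: the package's own null
   simulations (see the acceptance test on calibration) put the raw-p
   rejection rate at 0.05 inside [0.03, 0.07] with shrinkage and near
   0.11 without it. Shrinkage can be disabled
   (`shrink_dispersion = FALSE`).
3. **Effect and test.** $\log_2\mathrm{FC} =
   \log_2\frac{\bar x_2 + c}{\bar x_1 + c}$ with pseudocount $c = 0.5$
   (bounds the fold change when a group is all zero); the standard
   error comes from the delta method under
   $\mathrm{Var}(K) = \mu + \alpha\mu^2$; $z$ is referred to a standard
   normal, two-sided; BH correction is applied across tested genes.
   Genes with mean normalized count below `min_base_mean = 1` are
   excluded from testing and from the BH family (independent
   filtering), carrying `NA` p-values.

This is intentionally not a clone of shrinkage-heavy DE packages (no
fold-change shrinkage, no outlier replacement, no likelihood-ratio
machinery); on real data its gene lists will differ in detail from such
tools, and all downstream guarantees in this package are established on
synthetic data with known truth.

## DEG rules and flip classification

The two contrasts use asymmetric rules reflecting that a drug usually
moves expression less than the perturbation that is being corrected:
the perturbation rule is $|\log_2\mathrm{FC}| > 1.5$ at FDR $< 0.05$;
the drug rule is a natural-scale fold change of 1.5
($|\log_2\mathrm{FC}| > \log_2 1.5 \approx 0.585$) at raw $p < 0.05$.
Both inequalities are strict. Whether the drug rule should act on pre-
or post-filter p-values is not a settled question; both the filter
threshold and the significance scale (`alpha_on`) are rule parameters
rather than hard-coded choices.

`classify_flip()` intersects the calls: `up_down` = up under the
perturbation rule and down under the drug rule (both contrasts against
the control), `down_up` the mirror. Flip membership requires passing
the drug-contrast rule, not merely a sign change, and no additional
reversion-magnitude condition is imposed. Perturbation DEGs that do not
flip are retained as `perturbed_only_*`, so each DEG sign class is
exactly partitioned - the flip fraction (`flip_fraction()`, reported as
an integer percentage) has a well-defined denominator. An alternative
reading of "reverted" (drug contrast taken against the perturbed
condition instead of the control) can be had by passing that contrast's
`de_result`; the default pipeline follows the against-control
convention for both.

## Pathway layer

`enrich_pathways()` scores a pathway $P$ against a flip list $F$ in a
universe $U$ by the enrichment factor
$\mathrm{EF} = \frac{|P\cap F|}{|P|\,|F|/|U|}$ (observed over expected
overlap) with hypergeometric upper-tail significance and BH correction
across pathways. The universe defaults to the genes actually tested in
the DE step - enrichment background should match the measurement space,
not the whole genome - and is overridable. The two flip classes are
scored separately (catabolic-style pathways against `up_down`,
anabolic-style against `down_up`).

`build_network()` connects significantly enriched pathways
(`fdr < 0.05`) whose *flip-restricted* memberships overlap more than
chance (hypergeometric $p < 0.05$ within the flip set) and whose
flip-restricted Jaccard reaches 0.1; the floor exists purely to avoid
hairball networks and both thresholds are arguments.
`cluster_pathways()` groups nodes by K-means on the L2-normalized
binary pathway x flip-gene incidence matrix; with `k = "auto"` the
cluster count maximizes the mean silhouette width over
$k \in [2, \min(10, \mathrm{nodes}-1)]$, falling back to a single
cluster when the silhouette degenerates (e.g. identical rows). K-means
runs from a fixed seed with 10 starts, so labels are reproducible.

## Regulon layer

Genes are ranked by the flip score
$s_g = -\mathrm{sign}(\beta^{\mathrm{pert}}_g)\,\beta^{\mathrm{drug}}_g$
when the two contrasts disagree in sign and 0 otherwise - a reversal
scores positive regardless of its direction. Each TF regulon gets the
standard weighted Kolmogorov-Smirnov enrichment score: walking down the
ranking the running sum gains $|s|^q$ (normalized over the regulon's
hits) at members and loses $1/(N - n_h)$ elsewhere; the ES is the
signed supremum. The null is gene-label permutation: `n_perm` random
same-size regulons; $\mathrm{NES} = \mathrm{ES} / \overline{|\mathrm{ES}_{\mathrm{null}}|}$
over null scores of matching sign, with an add-one permutation p-value
(never exactly zero). Nulls are cached per regulon size, which keeps a
fixed-seed run deterministic and fast.

Two numerical choices deserve a note. First, ties in the ranking are
broken lexicographically by gene id, making every downstream result
deterministic. Second, the *driver* `tf_enrichment()` defaults to
weight exponent $q = 0.5$ while the `enrichment_score()` primitive
keeps the classic $q = 1$: the flip score is heavy-tailed (near zero
for concordant genes, large for true flips), and at $q = 1$ a handful
of extreme weights dominates the normalized increments so that any
regulon containing a few top-ranked genes saturates near
$\mathrm{ES} = 1$; square-root damping restores discrimination between
flip-dense regulons and incidental overlaps while still using the
scores. With $q = 0$ the statistic reduces to the classical KS form.

This layer is a methodological reconstruction: preranked regulon
enrichment with permutation NES is the field-standard reading of an
"NES per TF" analysis, but regulon catalogues and enrichment engines
vary, so results on real data depend on the supplied GMT.

## Drug-library screen

Profiles failing the high-quality or FDA-approval flags are dropped
first. Each retained profile is reduced to its extreme flanks - the
`n_sig = 100` most up- and down-regulated genes, ties broken by gene id
with the two flanks taken from the head and tail of one total order (so
they can never overlap). In the default *directional* mode a profile's
score is $\frac{|\mathrm{sig.down}\cap F_{ud}| +
|\mathrm{sig.up}\cap F_{du}|}{|F \cup \mathrm{sig}|}$: only
direction-concordant genes count (a mimic must push the
induction-reversed flips down and the repression-reversed flips up),
with the plain pooled Jaccard available as a mode. The top decile of
retained profiles is flagged ($\lceil 0.1\,m\rceil$ profiles, extended
to ties at the threshold); a drug is a mimic if *any* of its profiles
is flagged - the most sensitive collapse over doses, times and cell
lines, chosen because profile-to-condition mappings are usually
many-to-one. `target_enrichment()` then scores each annotated target by
the enrichment factor of drug-target links among mimic drugs versus all
screened drugs, hypergeometric p, BH across targets. The screen selects
profiles, collapses to drugs, and tests targets at the drug level; this
profile-vs-drug bookkeeping is stated explicitly because the two levels
are easy to conflate.

## Synthetic data: what it emulates and what it does not

`sim_config()` fixes the study conditions; the generators are pure
functions of it (bit-reproducible per seed, each deriving its own
stream from the master seed).

* **Counts.** Per-gene baselines are log-normal (meanlog 4, sdlog 1.5,
  i.e. a median around 55 counts with a realistic dynamic range);
  counts are NB with dispersion 0.1
  ($\mathrm{Var} = \mu + 0.1\mu^2$); depth factors are Uniform(0.7,
  1.3). Five replicates per condition is the default, a typical size
  for primary-culture designs; the true replicate depth of the emulated
  experiment is not published, so this is a declared surrogate.
* **Planted classes.** 80 induction-reversed and 120
  repression-reversed flip genes plus 100 + 100 non-reverting DEGs, at
  a perturbation effect of 3 log2 units. In the drug condition flip
  genes reverse the full perturbation effect
  (`drug_revert_fraction = 1`) and overshoot baseline by
  `drug_overshoot = 1.5` log2 units. The overshoot is part of the
  generator's contract - planted flips must be genuine DEGs of the
  drug contrast - and 1.5 makes that hold across the expression range:
  at an overshoot of 1.0 the reversal is under-powered for
  low-expression genes at $n = 5$, which would make the planted truth
  internally inconsistent rather than the classifier wrong.
* **Pathways / regulons.** One planted pathway per flip class (size
  40, 60% of members from the class) among 200 uniform decoys; one
  planted TF regulon (size 30, 80% from flip genes) among 50 decoys.
* **Drug library.** 200 drugs x 2 profiles over the full gene space;
  decoy scores are standard normal; the 10 planted mimic drugs get 60
  of each 100-gene flank forced flip-concordant, beyond the noise
  range. 10% of decoy profiles are low-quality and 10% of decoy drugs
  non-FDA, exercising the filter. The planted target covers 8 of the
  10 mimic drugs and 5% of the rest; 29 decoy targets annotate at the
  5% background rate.

The generator does **not** emulate batch effects, library-composition
bias, dose-response structure, correlated co-expression modules,
ortholog ambiguity, or the heavy profile redundancy of a real signature
library. Passing the planted-recovery suite therefore demonstrates the
pipeline's internal correctness and statistical calibration, not
performance on any real dataset.

## Problem sizes used by the test and acceptance suites

The suites run the generator at its default size (2,000 genes, 15
samples) for single full runs, 100 seeded replicates for the pathway
layer, 20 seeded replicates with 200 permutations for the regulon and
drug-screen layers, and a 4,000-gene simulation for the NB moment
check. These sizes were chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo error well below the margins being
asserted.

## Known limitations

* The DE model is a simplified NB Wald pipeline; no fold-change
  shrinkage or outlier handling, so single-outlier genes can reach the
  DEG lists at small $n$.
* The flip definition is binary per contrast; partial reversions below
  the drug rule are invisible by construction.
* Ortholog handling keeps only 1:1 pairs; paralog families are dropped
  rather than collapsed.
* The mimicry screen uses overlap statistics on fixed-size flanks; it
  does not model signature strength beyond membership, and the
  direction of ortholog mapping between the flip genes and the library
  gene space is a configuration choice, not inferred.
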