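---
title: "Episignature discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episignature discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `episig`, the meaning
and defaults of its tunable parameters, what the synthetic cohort generator
does and does not emulate, and the design decisions taken where the
methodology left genuine freedom.

## The workflow at a glance

An episignature study asks whether a genetic disorder leaves a reproducible
DNA-methylation pattern in peripheral blood, and whether that pattern
classifies new samples. The pipeline proceeds:

1. **Probe filtering** — remove SNP-overlapping, cross-reactive and
   sex-chromosome probes, probes failing detection (p > 0.1 in any sample),
   and probes with missing values.
2. **Cell-composition estimation** — reference-based deconvolution of
   leukocyte fractions, used as model covariates (blood methylation is
   dominated by cell composition).
3. **Matched controls** — greedy nearest-neighbour selection, exact on sex,
   batch and array type, nearest on age, without replacement.
4. **Moderated differential methylation** — per-probe OLS of beta on the
   case indicator plus cell fractions; empirical-Bayes variance shrinkage;
   moderated t; Benjamini-Hochberg FDR.
5. **Signature selection** — sweep adjusted-p cutoffs, prune correlated
   probes, keep the set with the best case/control silhouette.
6. **Classification** — linear SVM with Platt-calibrated MVP scores,
   trained on cases vs matched controls plus 75% of all other samples.
7. **Annotation and comparison** — CGI/gene context, DMR calling, and
   cross-cohort overlap/relatedness analyses.

## The differential methylation model

Beta values (methylation fractions in [0, 1]) are the response:

$$\beta_{gs} = \alpha_g + \delta_g\,\mathrm{case}_s + \mathbf{c}_s'\boldsymbol\gamma_g + \varepsilon_{gs},
\qquad \varepsilon_{gs}\sim N(0, \sigma^2_g)$$

with one leukocyte-fraction column dropped to avoid the sum-to-one
singularity. Although beta values are bounded, OLS on the beta scale keeps
$\delta_g$ directly interpretable as a methylation difference, the
convention of the episignature literature; the moderated test is robust to
the mild heteroscedasticity this induces at the scale of whole-array FDR
control.

Residual variances are shrunk towards a scaled inverse-$\chi^2$ prior
$(d_0, s_0^2)$ estimated by moment matching on $z_g = \log s^2_g$: the
excess of $\mathrm{Var}(z)$ over $\psi'(d_g/2)$ estimates $\psi'(d_0/2)$,
inverted by Newton iteration on the trigamma function (tolerance $10^{-8}$);
the mean equation then gives $s_0^2$. Two boundary conventions matter:

* when the observed dispersion does not exceed $\chi^2$ sampling
  dispersion, $d_0 = \infty$ and the prior variance is the arithmetic mean
  of the $s^2_g$ (the same convention as the established empirical-Bayes
  implementation, against which the package is cross-checked in its tests);
* with $d_0 = \infty$ the moderated t is referred to the normal
  distribution; with $d_0 = 0$ it reduces exactly to the ordinary
  two-sample t-test.

## Signature selection

Candidates are ranked by adjusted p (ties by |Δβ| descending, then probe
id). Each entry of `cutoff_grid` below 1 is an adjusted-p threshold and each
entry ≥ 1 a top-n size; the default grid (`1e-8, 1e-6, 1e-4, 0.01, 0.05`)
sweeps p-value cutoffs, the quantity the original workflow varied. Probes
correlated above `r_max = 0.9` with a better-ranked retained probe are
pruned (greedy, deterministic). Sets are scored by the mean silhouette width
of the case/control labelling under Euclidean distance — a metric was not
prescribed, and silhouette was chosen because it is bounded, symmetric in
the two groups and directly measures the "best clustering" notion used to
pick probe sets; ties go to the smaller set. A best score below
`min_separation = 0.25` flags the selection as non-significant (a null
cohort yields an empty, flagged selection rather than an error).

## The MVP classifier

Label 1 is the cases; label 0 is their matched controls plus a seeded,
cohort-stratified 75% of every other available sample (pool controls and
other-disorder cohorts), so the classifier learns disorder specificity, not
merely case/control contrast. The SVM uses a linear kernel (the standard
choice for episignature classifiers; betas on a common scale, so inputs are
not rescaled) with inverse-class-frequency weights. Decision values are
mapped to [0, 1] by Platt scaling with regularised targets
$t_+ = (N_++1)/(N_++2)$, $t_- = 1/(N_-+2)$, fitted by the standard IRLS of
`glm`; the fractional targets keep the sigmoid finite on separable training
sets, and the slope is constrained nonnegative so scores are monotone in the
decision value. The 0.5 threshold defines classification in
cross-validation; 0.75 is reported separately as the descriptive "high
score" bound. Cross-validation re-runs the *entire* pipeline — matching,
differential methylation, selection, training — on each round's retained
samples, so held-out samples influence nothing.

## The synthetic cohort generator

Defaults mirror the study design the package models: 24 discovery and 5
validation cases, 200 pool controls, two other-disorder cohorts of 20
samples with their own disjoint 200-probe signatures, 10,000 probes on 8
autosomes plus sex chromosomes, a planted case signature of 296 probes
(98.6% hypomethylated) with mean beta shift 0.10, logit-scale technical
noise sd 0.15, 6 leukocyte types with Dirichlet(6, 3, 2, 1.5, 1, 0.8)
composition acting through reference profiles on 20% of probes, two batches
with probe-wise logit shifts (sd 0.05), detection failures at rate 1e-4 per
entry, and 2% SNP-overlap, 2% cross-reactive and 3% sex-chromosome probes.
Pool sizes, batch structure and rates are generator choices at realistic
magnitudes — the source study reports its cohort sizes but not its database
composition. The array size (10,000 probes rather than ~850,000) keeps the
default study tractable on a laptop while preserving every statistical
feature the pipeline exercises; tests and the acceptance script state the
sizes they use.

Two generative constraints deserve emphasis because they were *decisions*,
not givens:

* **Effects are planted where they are biologically possible.**
  Hypomethylation is planted on probes with methylated baselines
  (beta in [0.55, 0.92]) and hypermethylation on unmethylated ones
  ([0.08, 0.45]). Planting a −0.10 shift on a probe whose baseline is
  already 0.10 clips at the boundary and produces a probe that is an
  almost deterministic indicator of case status; a set of such probes is
  mutually correlated near 1 and collapses under correlation pruning.
  Real differentially methylated CpGs lose methylation they have.
* **Effect sizes vary between individuals.** Each affected sample's shift
  at each signature probe is the probe effect times a nonnegative
  $N(1, 0.3)$ factor, emulating the inter-individual spread of episignature
  strength visible in real MVP scores.

Effects and noise are applied on the logit (M-value-like) scale except the
planted delta itself, which is specified directly in beta units so that
`delta_beta` remains a directly interpretable knob; betas are clipped to
[0.001, 0.999] before the logit to avoid boundary pathologies. One seed
drives everything through per-stage derived sub-seeds, so adding a stage
never shifts the draws of an earlier one and identical configurations
reproduce byte-identical artifacts.

What the generator does **not** emulate: realistic EPIC probe-level
annotation and probe-type chemistry, genotype-driven (SNP) methylation
effects, age-associated drift, correlated probe blocks beyond the planted
signature, and array normalisation artifacts (normalisation and background
correction sit upstream of this package's entry point). Passing tests
therefore demonstrate the correctness and internal consistency of the
statistical machinery under a controlled truth — not clinical performance
on real cohorts.

## Numerical and procedural choices

* Detection-p filtering uses the *any-sample* reading of "p > 0.1"
  (strictest; configurable to a mean-based rule would be a one-line
  change in `filter_probes`).
* PCA outlier screening reports (median ± 3 × 1.4826 MAD on each of the
  top 3 axes) but never drops samples: exclusion is an analyst decision.
* Cell deconvolution solves the simplex-constrained least-squares problem
  exactly by support enumeration — with ≤ ~12 cell types this is fast,
  deterministic, and free of solver tolerances; rank-deficient references are
  rejected naming the collinear cell types.
* Matching processes cases in sample-id order and breaks age ties by
  control id: deterministic, and insufficiency is an error, never a silent
  relaxation. The default ratio of 4 controls per case is a package
  default, configurable.
* Hierarchical clustering uses complete linkage (the common heatmap
  default; configurable) with the tie-breaking of `hclust`; trees serialise
  to newick with branch lengths from merge heights.
* "Consecutive" in the DMR definition means adjacent in the
  position-sorted table of tested probes with no intervening
  non-significant probe, and "within 1 kb" bounds the window's positional
  span; overlapping qualifying windows merge into maximal regions.
* Gene-context summaries use the precedence promoter > promoter+ > 5'UTR >
  CDS > 3'UTR > intron > intergenic, while the per-probe table also
  reports every overlapping category; CGI percentages are computed against
  the package's own filtered manifest.
* Whether "correlation" in the original feature-importance step meant
  probe-probe pruning or probe-label ranking is ambiguous; the package
  implements pruning and additionally records each retained probe's
  direction-agnostic Mann-Whitney AUC, covering both readings.

## Problem sizes

The default study (10,000 probes, 274 samples) runs the full discovery
pipeline in ~10 s on one core; 20 rounds of leave-25%-out cross-validation,
each re-running the pipeline from matching onwards, take ~1 minute. The
test suite builds all fixtures in code, using an 800-probe cohort for unit
tests and the default study for the acceptance checks.

## Known limitations

* Beta-scale OLS ignores the mean-variance relationship of bounded data;
  M-value modelling would be a straightforward variant but changes the
  interpretation of effect sizes.
* The silhouette criterion can prefer slightly smaller probe sets than the
  planted truth when extra probes add noise faster than signal; recall
  against planted truth is part of the acceptance suite.
* Reference-based deconvolution assumes the reference spans the sample's
  cell types; unmodelled types bias fractions toward the nearest modelled
  profile.
* The comparison module treats each cohort's signature as exchangeable
  with the package's own outputs; it does not model study-level batch
  differences between cohorts.
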