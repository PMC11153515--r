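# episig

Discovery, validation and cross-cohort comparison of blood DNA-methylation
**episignatures** — reproducible genome-wide methylation patterns that serve
as diagnostic biomarkers for rare genetic disorders such as Mowat-Wilson
syndrome (*ZEB2* haploinsufficiency). The package implements the complete
analytical workflow that turns an EPIC-like beta-value matrix and a sample
sheet into a validated probe signature and a calibrated classifier, together
with a synthetic cohort generator that provides planted ground truth for
every stage (patient-level methylation data of such studies is typically not
shareable).

## Who it is for

Statistical geneticists and bioinformaticians building or auditing
episignature pipelines: every stage is an exported, unit-tested function, and
every threshold (detection-p cutoff, FDR level, matching ratio, pruning
correlation, training fraction, DMR window, annotation distances) is an
explicit argument with the field's conventional default.

## The method

For each probe *g*, methylation beta values are modelled by ordinary least
squares on a case indicator and estimated leukocyte proportions:

    beta_g = a_g + d_g * case + c_g' w + e_g,   e_g ~ N(0, s²_g)

Per-probe residual variances are shrunk by empirical Bayes towards a scaled
inverse-chi-squared prior (d0, s0²) estimated by moment matching on
log s²_g (the trigamma-inversion estimator), giving posterior variances

    s̃²_g = (d0·s0² + d_g·s²_g) / (d0 + d_g)

and moderated t-statistics t_g = d_g / (s̃_g √v_g) referred to a
t-distribution on d0 + d_g degrees of freedom, with Benjamini-Hochberg
control of the false discovery rate. Candidate probe sets from a sweep of
adjusted-p cutoffs are pruned for inter-probe correlation (|r| > 0.9) and
scored by the case/control mean silhouette width; the best-separating set is
the episignature. A linear-kernel SVM trained on cases versus matched
controls plus 75% of all other samples (the remaining 25% held out for
testing), with Platt-calibrated probabilities, yields a
methylation-variant-pathogenicity (**MVP**) score in [0, 1] per sample.
Matched controls are selected greedily without replacement, exact on sex,
batch and array type and nearest on age. Downstream modules annotate
signature probes by CpG-island context (island / shore 0-2 kb / shelf 2-4 kb
/ inter-CGI) and gene context (promoter 0-1 kb and promoter+ 1-5 kb upstream
of the TSS, UTRs/CDS/intron from BED12 models), call differentially
methylated regions (≥ 5 consecutive significant probes within 1 kb), and
compare cohorts by directed top-DMP overlap percentages and a relatedness
tree over median methylation-difference profiles (top n = min(#DMPs, 500)
per cohort).

## Worked example

```r
library(episig)

cfg <- sim_config(seed = 1)            # 24 + 5 cases, 200 controls,
ann <- simulate_annotation(cfg)        # 2 other-disorder cohorts,
sim <- simulate_cohort(cfg, ann)       # planted 296-probe signature

res <- run_discovery_pipeline(sim$beta, sim$detection_p, sim$sheet,
                              ann$manifest, sim$cell_reference,
                              ann$cgis, ann$genes)

length(res$analysis$selection$probes)  # 285 probes selected
res$analysis$selection$score           # 0.692  (case/control silhouette)

filt <- sim$beta[res$filter$retained_probes, ]
val  <- sim$sheet$sample_id[sim$sheet$cohort_role == "validation"]
run_validation_pipeline(filt, res, val)$report
#>   sample_id       mvp cluster co_clusters_with_cases
#> 1      S010 0.9432824       1                   TRUE
#> 2      S015 0.9616630       1                   TRUE
#> 3      S024 0.9546909       1                   TRUE
#> 4      S025 0.9588595       1                   TRUE
#> 5      S028 0.9764398       1                   TRUE
```

All five held-out validation cases score well above the 0.75 reporting bound
and co-cluster with the discovery cases; held-out controls and
other-disorder samples score below 0.01. Of the planted 296-probe signature,
the selected set recovers 96% at precision 1.0 on this seed.

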