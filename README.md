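# organotrope

Pancreatic ductal adenocarcinoma (PDAC) that metastasizes to the liver
behaves very differently from PDAC that spreads only to the lung: liver-avid
disease carries markedly worse survival. Disentangling that organotropism
axis from the well-known basal-like vs classical transcriptional subtype
axis requires a signature-derivation procedure that explicitly removes one
factor's genes from the other's, plus single-sample scoring, survival
statistics and — because tumor immunity is central to the biology — TCRβ
repertoire analytics on matched blood–tumor pairs.

`organotrope` implements that tool chain for computational oncologists and
biostatisticians, end to end and fully testable on synthetic cohorts with
planted ground truth:

* **Two-factor NB differential expression.** Per gene, counts follow
  `y ~ NB(mu, alpha)` with `var = mu + alpha * mu^2` and
  `log mu = b0 + b_org * x_org + b_sub * x_sub + log(s)`, where `x_org`
  indicates liver-like organotropism, `x_sub` basal-like subtype and `s` a
  TMM-scaled library-size offset. Dispersions come from method-of-moments
  estimates shrunk toward a mean–dispersion trend; inference is per-coefficient
  Wald with Benjamini–Hochberg FDR within each factor.
* **Orthogonal signature derivation.** An organotropism signature
  (`pORG`-like) keeps genes up in liver-like samples at FDR < 0.2, then drops
  any gene in the top half of the subtype ranking; the subtype signature
  (`pSUB`-like, FDR < 1e-4) is built symmetrically. Leave-one-out
  cross-validation repeats the whole derivation per held-out sample.
* **Single-sample enrichment (GSVA-style).** Gene-level kernel CDFs
  `z_ij = mean_k Phi((x_ij - x_ik)/h_i)` with `h_i = s_i/4`, symmetric rank
  statistic `|N/2 - rank|`, and a weighted Kolmogorov–Smirnov-like random
  walk yielding scores in [-1, 1]; plus a top-scoring-pairs subtype
  classifier whose coefficients load from a JSON model file.
* **TCRβ repertoire analytics.** Richness, Shannon entropy, clonality
  (1 − H/ln R), Simpson's d/diversity/evenness, public overlap and Jaccard
  index, percent tumor-distinct clones (≥ 10 combined templates, tumor-only),
  shared dominant clonotypes (top-50 by frequency, ≥ 25% prevalence),
  expanded clones (> 1 template per patient on average), reference CDR3
  matching, and blood-sample classification against the disease timeline.
* **Survival statistics.** Kaplan–Meier with Greenwood bands, log-rank, Cox
  proportional hazards (Efron ties), ROC/Youden-index dichotomization at a
  545-day horizon, Fisher's exact tests, correlations and group tests.
* **Synthetic studies.** Seeded generators for NB counts with planted
  two-factor effects, proportional-hazards survival tied to a score, and
  paired blood–tumor repertoires with power-law clone frequencies and
  planted public/tumor-distinct/reference clones.

## Worked example

```r
library(organotrope)

truth <- expression_truth(n_genes = 500, n_samples = 40, n_organ = 40,
                          n_subtype = 40, n_overlap = 8)
study <- generate_expression_study(truth, seed = 7)
cm    <- study$cm
cm    <- cm[mean_tpm_filter(compute_tpm(cm), cutoff = 0.25), ]

de  <- fit_two_factor(cm, two_factor_design(cm$samples))
sig <- derive_signatures(de, fdr_org = 0.2, fdr_sub = 1e-4)
sig
#> signature_pair: organ-like 19 genes, subtype-like 18 genes
#>   gates: organ FDR < 0.2 | subtype FDR < 1e-04 | ranked by p
mean(sig$porg_like %in% truth$organ_genes)
#> [1] 1
```

Every derived organ-signature gene is a planted organotropism gene. Scoring
samples and linking the score to survival:

```r
expr   <- tmm_log_cpm(cm)
scores <- gsva_scores(expr, list(gene_set("pORG_like", sig$porg_like)))
round(scores[, 1:5], 3)
#> sample001 sample002 sample003 sample004 sample005
#>     0.667    -0.652     0.674    -0.590     0.707
table(quartile_cohorts(scores["pORG_like", ]))
#> high  low  mid
#>   10   10   20

surv <- generate_survival(cm$samples, scores["pORG_like", ],
                          survival_truth(beta_score = 0.7), seed = 8)
cox_fit(surv, "score")
#> cox_fit (efron ties, n = 40)
#>    term  beta   hr    se      p ci_lower ci_upper
#> 1 score 0.596 1.81 0.286 0.0374     1.04     3.18
```

Liver-like samples score near +0.7, lung-like near −0.6, and the Cox fit
recovers a hazard ratio of 1.8 (true log-hazard 0.7 per score unit, i.e.
HR ≈ 2 across the score range) with p < 0.05 at n = 40. The whole pipeline —
including the TCR stages when a clonotype manifest is present — runs through
`simulate_study()` / `run_pipeline()`.

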