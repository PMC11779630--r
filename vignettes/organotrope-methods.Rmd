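---
title: "Methods: organotropism signatures, enrichment scoring and TCR repertoire analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organotropism signatures, enrichment scoring and TCR repertoire analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organotrope)
```

# Scope

`organotrope` packages the computational core of an organotropism analysis
of pancreatic ductal adenocarcinoma: deriving a pair of mutually
orthogonalized gene signatures (an organotropism axis and a subtype axis)
from two-factor differential expression, scoring individual samples with a
kernel-CDF rank enrichment statistic, analyzing TCRβ clonotype repertoires
on matched blood–tumor pairs, and connecting scores to outcomes with
standard survival statistics. Everything is exercised on synthetic studies
with planted ground truth, because the motivating patient-level data are
controlled-access.

# The expression model and the differential-expression engine

Counts are modeled per gene as negative binomial with
$\mathrm{var} = \mu + \alpha\mu^2$ and log link
$$\log \mu_{ij} = \beta_0 + \beta_{org}\,x_{org,j} + \beta_{sub}\,x_{sub,j} + \log s_j,$$
with $x_{org}$ the liver-like indicator, $x_{sub}$ the basal-like indicator
and $s_j$ a TMM-scaled effective library size normalized to geometric mean
one. The two binary factors are fitted jointly so that each coefficient is
adjusted for the other axis — the property the signature derivation relies
on.

Choices worth knowing about:

* **Dispersion.** A method-of-moments estimate from group-wise residual
  variance of size-factor-normalized counts, floored at $10^{-8}$ and shrunk
  50/50 on the log scale toward a `lowess` trend of dispersion on mean.
  The equal-weight shrinkage is deliberately simple; it stabilizes small
  per-gene estimates enough to keep Wald type-I error near nominal at the
  validation scale (fraction of null p-values below 0.05 stays within
  0.05 ± 0.02 at 2,000 genes and 40 samples) without an empirical-Bayes
  machinery. The weight is exposed as an argument.
* **Fitting.** Each gene is an IRLS fit (`glm.fit` with a fixed-dispersion
  negative-binomial family). No fold-change shrinkage is applied and genes
  are ranked by the raw Wald p-value — a transparent divergence from the
  reference-grade DE packages, chosen so that every ranking the signature
  derivation consumes is reproducible from first principles. Non-converged
  genes are flagged and assigned p = 1 rather than dropped, so the gene
  universe stays intact for the top-half exclusion rule.
* **Normalization.** TMM scale factors are delegated to `edgeR` (the
  canonical implementation of the published method, with its default trim
  fractions and reference choice) and verified in the test suite against a
  hand-coded oracle. Log-CPM uses a prior count of 0.5; the prior is not
  stated by the procedure this follows, so it is configurable. A note on a
  subtle point: a sample that is an exact scalar multiple of another has
  identical composition, so its TMM factor is 1 — the factors respond to
  composition bias, not library size, which the offset already carries.
* **Expression filter.** Genes with mean TPM below 0.25 across the dataset
  are removed before fitting; the boundary value itself is retained.

# Signature derivation and cross-validation

From the two-factor fit, the organotropism signature keeps genes up in the
liver-like level at FDR < 0.2, then removes any gene falling in the top
half of the universe ranked by the subtype factor; the subtype signature is
built symmetrically with the stricter FDR < $10^{-4}$ gate. Two details
were genuinely open and are resolved as follows:

* **Ranking statistic.** "Top half of the ranked genes" is interpreted as
  ranking by the factor's unadjusted Wald p ascending — the most common DE
  ranking, and monotone in FDR over a single factor anyway. The choice is
  exposed (`rank_by = "p" | "fdr" | "stat"`).
* **Ties at the median.** The whole tied block at the median rank is
  included in the top half, i.e. excluded from the signature — the
  conservative direction for orthogonality.

Leave-one-out cross-validation repeats dispersion estimation, fitting,
gating and exclusion with each sample held out, scores all samples with the
per-fold signature, and keeps only the held-out sample's score. The
combined vector is tested against the factor labels with a two-sided
two-sample t-test. Folds that lose a factor level, or whose signature comes
back empty, contribute a missing score with a warning rather than an error.
On simulations the cross-validated association is, on average, no stronger
than the over-fit in-sample association — the qualitative behavior expected
of any honest CV of a derivation with data-dependent gene selection.

# Kernel-CDF enrichment scoring

For gene $i$ and sample $j$,
$z_{ij} = n^{-1}\sum_k \Phi\!\big((x_{ij}-x_{ik})/h_i\big)$ with bandwidth
$h_i = s_i/4$ (per-gene standard deviation, floored at $10^{-8}$). Within
each sample, genes are ranked by decreasing $z$; the symmetric statistic
$r = |N/2 - \mathrm{rank}|$ weights a random walk down the ranking with
inside-set increments $\propto r^\tau$ ($\tau = 1$ by default) and uniform
outside-set decrements. The default score is the signed sum of the maximum
positive and minimum negative deviations, bounded in $[-1, 1]$; a
two-sided-KS variant (largest-magnitude deviation) is kept for sensitivity
analysis. The Gaussian kernel is appropriate because the scorer is fed
continuous log-CPM; no count-kernel variant is implemented. Ties in $z$ are
broken by stable ordering, making scores deterministic.

The top-scoring-pairs subtype classifier is implemented as an algorithm
whose coefficients (gene pairs, weights, intercept, threshold) load from a
JSON file; the shipped model file is synthetic, for plumbing and tests. The
published classifier's coefficients can be dropped in without code changes.
Quartile cohort assignment uses linearly interpolated percentiles over
whatever sample universe the caller passes (all primaries, all metastases,
or all tumors — the analyses differ, so the universe is an argument).

# TCR repertoire analytics

Clonotype identity is the CDR3 amino-acid sequence alone. Shannon entropy
is in natural log; clonality $1 - H/\ln R$ is base-invariant; a monoclonal
repertoire takes clonality 1 and evenness 0 by convention. Simpson's
evenness is defined as inverse-Simpson over richness — the vendor tool's
exact formula is unpublished, so this standard definition is used and
documented. Repertoires under 100 productive templates are excluded by QC.
The bespoke procedures follow the stated rules exactly: tumor-distinct
clones come from the universe of CDR3s with ≥ 10 combined blood + tumor
templates; shared dominant clones are the union of per-sample top-50 lists
(frequency ties at rank 50 all included) filtered to ≥ 25% prevalence
(boundary inclusive, `ceiling(0.25 n)`); expanded clones need strictly more
than one template per patient on average. Blood samples classify as
primary- or metastasis-associated against resection/recurrence day offsets,
with the 180-day and 30-day windows for non-resected patients.

The shipped reference CDR3 list is synthetic (clearly labeled): the
published driver-mutation-specific sequences live in their original
publications and can be supplied as a plain-text file.

# Survival statistics

Kaplan–Meier, log-rank and Cox PH delegate to the `survival` package
(Efron ties by default, tagged in the result); the median is the earliest
time the curve reaches 0.5. The ROC/Youden dichotomization labels
short-term survivors as deaths before the 545-day horizon and long-term
survivors as anyone observed beyond it; patients censored before the
horizon have an unknowable class and are excluded with a reported count
(the source procedure is silent on them). Deaths exactly at the horizon
match neither strict inequality and are likewise excluded. Ties in the
Youden scan resolve to the lowest cutoff. Fisher's exact test is two-sided
by the "at most as probable" rule; the suite checks it against exhaustive
hypergeometric enumeration.

# The synthetic-data generators

The generators define the validation conditions; they are not tuned per
test. Defaults: 2,000 genes, 80 samples in a balanced organ × subtype
cross, planted log2 fold change 1.5 on 100 + 100 genes with a 20-gene
overlap, NB dispersion 0.05 and library sizes 0.5–2 million — sizes and
effects typical of a bulk RNA-seq cohort study and small enough that the
full validation (including 200-replicate survival recovery) runs in minutes
on one CPU. Survival is exponential with hazard
$\lambda_0 e^{\beta \cdot score}$ ($\beta = 0.7$ by default), independent
exponential censoring and an administrative horizon. Repertoires draw
multinomial templates over Zipf clone frequencies (exponent 1.5, the
heavy-tailed shape of real immunoSEQ exports), with planted cross-patient
public clones placed at the top of the frequency ranking, planted
tumor-only clones at 10–30 templates, and optional planted matches to a
reference CDR3 list. CDR3 strings are random 12–18-mers over the canonical
alphabet, prefixed `CASS` and suffixed `F`, so collisions are negligible.

What the generators do *not* emulate — and what passing tests therefore do
not establish about real data: gene–gene correlation structure, GC/length
bias, batch effects, V/J gene usage, sequencing error in CDR3 calls,
non-proportional hazards, and informative censoring. The generators exist
to prove the procedures recover what was planted under their own model
assumptions, not to certify performance on any patient cohort.

All randomness flows through explicit seeds (`withr::with_seed`), so every
study is byte-reproducible and no generator touches global RNG state.

# Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$; kernel bandwidth floor $10^{-8}$.
* Designs with a single-level factor or confounded factors error before
  any fit; leave-one-out requires ≥ 9 samples so each fold keeps ≥ 8.
* All-zero genes are dropped (with a count) before DE; all-zero samples
  produce zero TPM columns with a warning; zero library sizes error with
  the sample named.
* Gene sets equal to the whole universe, or empty after intersection,
  error by name; enrichment needs ≥ 3 samples for the kernel CDF.
* Empty repertoires error in diversity metrics; a Jaccard of two empty
  sets is defined 0 with a warning; an empty tumor-distinct universe
  yields a missing value with a warning.
* If every score is equal, quartile assignment labels all samples `mid`
  with a warning.

# Validation problem sizes

The test suite validates: type-I error on a 2,000-gene, 40-sample null;
signature recovery precision ≥ 0.8 at the generator defaults; Cox
log-hazard recovery 0.7 ± 0.15 with ~95% CI coverage over 200 replicates of
n = 500; log-rank power ≥ 0.9 at hazard ratio 2 with 200 per arm; exact
recovery of planted tumor-distinct, shared dominant and expanded clones;
and oracle equivalence for the enrichment scorer, TMM, Fisher and Youden
procedures. Cross-validation behavior is checked at 200 genes × 16 samples
over several replicates — large enough to show the over-fitting contrast,
small enough to keep the suite fast.

# Known limitations

* The DE engine is intentionally minimal: no outlier handling, no
  independent filtering, no fold-change shrinkage. Rankings near the FDR
  gates will differ in detail from heavier DE frameworks.
* The published 55/51-gene signature memberships cannot be reproduced
  without the controlled-access cohort; the package derives *signatures of
  the same construction* and accepts the published lists as GMT input.
* `vst_like` is a labeled monotone log transform, not a fitted
  variance-stabilizing transform.
* Patient-level aggregation when a patient has several samples is the
  per-sample mean; other pooling rules may be preferable for unbalanced
  sampling.
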