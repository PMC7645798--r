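---
title: "Mechanism-based genetic stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-based genetic stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Alzheimer's (AD) and Parkinson's disease (PD) share little at the level of
individual causal variants, but overlap substantially at the level of
molecular mechanisms — neuroinflammation, protein misfolding, signaling
cascades around genes such as APOE, MAPT or SNCA. `mechstrat` implements a
joint stratification of AD and PD patients from SNP genotypes aggregated on
exactly this mechanism level: rather than clustering 0/1/2 dosage profiles
directly (which is unstable, because sparse SNP profiles make all pairwise
distances nearly equal), each patient is represented by a short vector of
per-mechanism genetic burden scores, and subgroup structure is sought in that
burden space.

The pipeline has four stages, each its own module:

1. **Burden encoding** — one small sparse autoencoder per mechanism compresses
   the dosages of the SNPs mapping to the mechanism's genes into a single
   bounded score per patient.
2. **Consensus sparse NMF bi-clustering** — the patients x mechanisms burden
   matrix is factorized repeatedly; co-clustering frequencies across restarts
   form a consensus, and the cluster number is chosen by stability criteria
   calibrated against a permutation null.
3. **Transfer and validation** — an L1-penalized multinomial classifier
   carries the discovered cluster labels to an independent cohort; coherence
   is quantified by the In-Group Proportion (IGP) with a permutation test.
4. **Association statistics** — clusters are tested against clinical outcomes
   at baseline (confounder-adjusted multinomial models) and longitudinally
   (random-intercept mixed models on baseline-normalized progression scores),
   with joint Benjamini-Hochberg correction.

A synthetic cohort generator with planted cluster structure stands in for the
access-controlled study cohorts and drives all calibration and
parameter-recovery tests.

## Mechanism catalogue

A catalogue maps mechanisms (named gene sets) to SNPs via gene annotations.
SNPs are assigned to a gene when they fall within a 10 kbp window extended
from both gene ends (1-based, closed intervals); precomputed eQTL pairs can be
unioned in. A SNP whose gene belongs to several mechanisms is deliberately
duplicated into each mechanism's group: burden scores are per-mechanism
aggregates, so sharing is semantically correct.

The packaged catalogue has 15 mechanisms over 27 genes with 148 SNP
positions. The 16 genes named in the AD/PD disease-map literature (AKT1,
IL1B, NLRP3, TP53, MTHFR, MAPK9, APOE, MAPT, SNCA, TOMM40, CDK5, GSK3B,
PICALM, CD33, IL6, CYCS) are complemented by clearly-labelled synthetic
placeholder symbols (`PLGENE17`..`PLGENE27`) to reach the full gene count;
coordinates and SNP identifiers are synthetic (the real rsID panel is not
redistributable). APOE sits in two mechanisms, so per-mechanism group sizes
sum to 157 while the union covers exactly 148 SNPs.

## Burden autoencoders

For a mechanism with $p$ SNPs, dosages are mode-imputed, standardized per SNP
(constant SNPs become zeros), put in canonical lexicographic column order
(making scores invariant to input column order), and fed through

$$h_i = \sigma(w^\top z_i + b), \qquad \hat z_i = v\, h_i + c,$$

with the loss
$$\frac{1}{np}\sum_i \lVert z_i - \hat z_i \rVert^2
  + \lambda_1 \lVert w \rVert_1 + \lambda_2 (\lVert w\rVert_2^2 + \lVert v\rVert_2^2).$$

Design choices, in order of consequence:

* **Bottleneck width 1 with a sigmoid activation.** One burden score per
  mechanism is the point of the construction, and the sigmoid bounds scores
  to $[0,1]$, which simultaneously guarantees the non-negativity the
  downstream NMF requires.
* **Orientation.** A sigmoid bottleneck is sign-ambiguous, so after training
  the score is flipped if it correlates negatively with the total risk-allele
  dosage of the mechanism's SNPs; "higher score" then always reads as "higher
  burden". Contribution weights are unaffected.
* **Sparsity** is an L1 penalty on the encoder weights, default
  $\lambda_1 = 10^{-3}$; the relative contribution of SNP $j$ is
  $|w_j| / \sum_k |w_k|$.
* **Ridge stabilizer.** A small weight decay ($\lambda_2 = 10^{-3}$) resolves
  the degeneracy of perfectly collinear SNPs (for exact duplicates only the
  weight sum is identified by the reconstruction loss) toward the symmetric
  solution, and generally stabilizes training.
* **Optimization**: full-batch Adam, step size 0.05, epoch cap 400, relative
  loss tolerance $10^{-6}$, deterministic given the seed. If the trained
  reconstruction fails to beat the all-mean baseline, training restarts once
  from a fresh derived seed. All-constant input yields a degenerate encoder
  whose score is the constant 0.5 and whose contributions are uniform.

Validation cohorts are scored with the *discovery-trained* encoders
(`apply_encoders()`), so both cohorts live in the same burden space; inside
cross-validation, encoders are refit on each training fold to keep
performance estimates honest.

## Consensus sparse NMF and selection of k

The burden matrix $X$ (patients x mechanisms, entries in $[0,1]$) is
factorized as $X \approx A S$ with $A \ge 0$ the soft patient-to-cluster
assignment and $S \ge 0$ the mechanism loading, minimizing
$\lVert X - AS\rVert_F^2 + \gamma \sum_{ij} S_{ij}$ by multiplicative updates
(tolerance $10^{-6}$, at most 500 iterations, penalty on $S$ only — the
bi-clustering reads each cluster's driving mechanisms off the sparse rows of
$S$, default $\gamma = 0.1$). The objective is non-increasing by
construction; the test suite checks this on random instances and checks the
rank-1 special case against the SVD.

A single run depends on the random initialization of both factors, so the run
is repeated (default 50 times, seeds `seed + run`); the fraction of runs in
which two patients share a hard label (argmax of the scale-normalized rows of
$A$, ties to the lowest index) is the consensus matrix $C$. Final labels cut
the average-linkage tree of $1 - C$ at $k$ groups. Only initializations are
perturbed across restarts, not patient resamples: the instability being
averaged over is explicitly the initialization dependence of the
factorization.

Three stability criteria score each candidate $k$:

* **PAC** — fraction of off-diagonal consensus entries strictly inside
  $(0.1, 0.9)$ (the conventional ambiguity bounds); lower is more stable.
* **Silhouette** — mean silhouette width on the distance $1 - C$.
* **Cophenetic correlation** — Pearson correlation between $1 - C$ and the
  cophenetic distances of the average-linkage tree.

The null model shuffles every burden column independently (destroying patient
structure, preserving marginals) and recomputes everything; default 20
permutations. The selected $k$ is the minimal candidate attaining the minimum
PAC among those whose silhouette *and* cophenetic correlation both exceed the
95th null percentile; if none passes, the selection is `"none"`.

A caveat worth knowing: with very few mechanisms (roughly fewer than 6-8
columns) even column-permuted data clusters almost perfectly — the null
saturates and no observed clustering can exceed it. This is a property of the
selection rule at tiny dimensionality, not a defect of the implementation;
the intended operating regime is the 15-mechanism design.

## Transfer classification and IGP

The transfer model is multinomial logistic regression with an L1 penalty
(glmnet), trained on the discovery burden scores (the default feature space;
a raw-dosage `"snp"` mode exists because both descriptions of the panel are
defensible, and the ambiguity is surfaced rather than hidden). The penalty is
chosen by inner cross-validated deviance over a 30-point log-spaced grid
anchored at the max-gradient lambda. Performance is reported as the Hand-Till
multi-class AUC — the average over unordered class pairs of the two
one-vs-one rank AUCs — under repeated stratified 10x10 cross-validation with
in-fold encoder refits.

The IGP of a cluster is the fraction of its validation patients whose
Euclidean nearest neighbor in the discovery cohort (ties to the lowest
patient index) carries the same label. Significance: discovery labels are
permuted (default 1000 times; nearest neighbors are label-free and stay
fixed) and $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_{\mathrm{perm}}+1)$ —
the add-one estimator, so $p$ is never exactly 0.

## Association statistics

The cluster indicator is the *response* of a multinomial logistic model, so
skewed clinical outcomes need no distributional assumption. Confounders are
chosen once per battery by bidirectional stepwise AIC search from the null
model (the direction is a declared default; the selection criterion is the
AIC throughout), with a guard that drops candidates which (quasi-)separate
the clusters. Each outcome is then tested by a likelihood-ratio test of
`cluster ~ confounders + outcome` against `cluster ~ confounders`
(single-term deletion; df = k - 1), with pairwise Wald tests between all
cluster pairs on nominal significance. All LRT and Wald p-values of one
battery are pooled and BH-adjusted jointly. Imaging-derived outcomes use the
fixed confounder set {age, sex} and are expected pre-normalized by
intracranial volume — a documented preprocessing contract, not a computation
this package performs.

Longitudinal outcomes are converted to progression scores — outcome minus its
baseline value, divided by the SD of the baseline values — and modelled with
fixed cluster, time and cluster x time effects plus a per-patient random
intercept, by maximum likelihood (ML rather than REML so the AIC comparison
of numeric-vs-categorical time coding is valid). The baseline visit is
excluded from the fit (its progression score is identically zero); the
cluster effect is the LRT of the full model against the time-only model, the
interaction the LRT against the additive model. Singular random-effect fits
fall back to the fixed-effects linear model with a warning.

## The synthetic cohort generator

The generator emulates the statistical shape of the emulated study design —
not its LD structure, population stratification or genotyping error:

* 486 AD + 358 PD discovery patients, 561 validation patients (258 AD-like /
  303 PD-like across emulated sub-studies), 148 SNPs in 15 mechanism groups
  (the packaged catalogue's partition, sizes 4-18).
* Four planted clusters in equal proportions with a **cyclic signature**:
  cluster $c$ burdens mechanisms $c, c+4, c+8, \dots$ — every cluster is a
  mixture of mechanisms, none is a single-mechanism caricature.
* Dosages are Hardy-Weinberg binomial draws, $\mathrm{Bin}(2, f_j)$ with
  baseline minor-allele frequencies uniform on $[0.05, 0.45]$; SNPs of a
  burdened mechanism shift their frequency by `effect_delta` (default 0.2,
  the effect size at which the power statements of the test suite are made),
  so the planted per-SNP dosage difference is `2 * effect_delta`.
* Confounders (age by disease, sex, study label) are drawn independently of
  cluster — matching the emulated finding that no confounder associated with
  cluster membership — and baseline outcomes are cluster-linked Gaussians
  with configurable confounder coefficients.
* Longitudinal outcomes anchor the baseline visit at the baseline outcome
  value; follow-up visits add a cluster-specific linear slope, a patient
  random intercept, and visit noise.
* Missingness is off by default; when enabled it is
  missing-completely-at-random per dosage cell.

What passing tests on these data do *not* show: robustness to LD between
SNPs, to population structure, to informative missingness, or to confounders
that actually correlate with cluster membership. Those are real-data
phenomena the generator deliberately omits.

## Numerical and reproducibility choices

* Every stage derives its random stream from one integer seed
  (`seed + fixed offset`, kept inside 32-bit range); reruns are bit-identical
  and the pipeline manifests record MD5 hashes of every artifact.
* NMF multiplicative updates carry an $\varepsilon = 10^{-12}$ denominator
  guard; consensus matrices are exactly symmetric with unit diagonal.
* Nearest-neighbor and argmax ties break deterministically to the lowest
  index.
* Multinomial fits use tightened convergence tolerances so that the k = 2
  LRT agrees with the binomial-logistic LRT to numerical precision.

## Problem sizes used by the test suite

The suite exercises the full default design (844 x 148, 50 restarts,
20 permutations, k grid 2..7) once for the cluster-number recovery check, and
otherwise uses reduced designs chosen as the smallest that leave the tested
property comfortably away from its decision boundary: a 120-patient
two-cluster cohort with 8 mechanism groups for pipeline round-trips, 40 x 12
matrices for consensus calibration, 1000 simulations for type-I error
calibration, 10 seeds per effect size for the recovery ladder, and 50 seeds
for power statements.

## Known limitations

* The autoencoder is intentionally minimal (one bottleneck unit, full-batch
  training); deep or denoising variants are out of scope.
* Only initialization-perturbed consensus is implemented, not row-resampled
  consensus.
* The selection rule can return `"none"` — by design — whenever no candidate
  beats the permutation null; callers must handle that value.
* IGP nearest neighbors default to burden space; raw-SNP space is available
  but Euclidean distance on sparse dosage profiles is exactly the regime the
  burden representation exists to avoid.
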