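---
title: "Misclassified-sample re-modeling for GWAS case-control classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misclassified-sample re-modeling for GWAS case-control classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missnp)
```

## The problem

A case-control GWAS classifier is usually built in one pass: quality
control, univariate SNP pre-selection, then a multivariate model (here
L1-regularized logistic regression) on the surviving markers.  That
protocol optimizes for the majority of samples.  If a minority of subjects
carries a *different* genetic architecture — a hidden sub-class whose
affection status is driven by markers the majority signal drowns out —
those subjects end up systematically misclassified, and their markers never
enter the model.

`missnp` implements the full pipeline plus the feedback step that targets
exactly this failure mode: take the samples the fitted model got wrong,
re-run association and model building *on them alone*, and merge the two
marker sets.  Two merging strategies are provided:

* **SNPs Mix** — union of the two models' *input pools*, refit;
* **Models Mix** — union of the two models' *selected* (nonzero) SNPs,
  refit.

Both refits use the original training samples and are scored on the
original held-out test set, so the comparison with the base model is
apples-to-apples.

## Pipeline and models

### Quality control

Subject level: phenotype clean-up (codes other than 1/2 dropped), then
PCA-based ancestry filtering on EIGENSTRAT-normalized dosages
$(g - \mu_j)/\sqrt{p_j(1-p_j)}$, sampling up to 100,000 SNPs with
per-chromosome quotas.  Within each phenotype group the side of the PC1
threshold (default 0) holding the majority is retained.  One deliberate
addition: the split is applied only when $\lambda_1/\lambda_2 >$ 1.5.
Without real stratification PC1 is exchangeable noise centred on zero and
a threshold split would discard half the cohort; empirically the ratio
sits at $\approx 1.0$ for a homogeneous cohort and $\ge 2$ for two
Balding–Nichols populations at $F_{st} \ge 0.02$, so 1.5 separates the
regimes with a wide margin.

SNP level, in order: autosomes only (PLINK chromosome code $\le 22$);
require an "rs" identifier; call rate $\ge$ 98% computed *within cases and
within controls separately* (removed if strictly below threshold in either
group — the group-wise computation is what makes per-group removal rates
meaningful); monomorphic markers; Hardy–Weinberg equilibrium at
$p < 10^{-5}$.  HWE is tested in controls only by default: a true
association inflates case genotype frequencies away from HWE, so testing
in cases would remove real signal.  Both thresholds are strict
inequalities; a SNP at exactly 98% call rate or exactly $p = 10^{-5}$ is
retained.  The HWE test is the 1-df goodness-of-fit chi-square (a
conditional exact test is available via `hwe_test(..., method =
"exact")`); the chi-square form was chosen as the default because it has a
closed form that unit tests can verify by hand arithmetic.

### Kinship and the corrected association test

Family cohorts violate the independence assumption of the classical
allelic test.  Kinship coefficients $\phi_{ij}$ are computed from the
pedigree by the recursive tabular method (founders unrelated,
$\phi_{jj} = \tfrac12(1+\phi_{fm})$,
$\phi_{ij} = \tfrac12(\phi_{i,f(j)} + \phi_{i,m(j)})$), block-diagonal by
family and stored sparse.  The association statistic is the dosage-trend
contrast with a quasi-likelihood variance correction: with weights
$w_i = 1/n_{\text{case}}$ (cases) and $-1/n_{\text{ctrl}}$ (controls),

$$T = \frac{(w^\top x)^2}{2\,\hat p(1-\hat p)\; w^\top (2\Phi)\, w},
\qquad T \sim \chi^2_1,$$

using the dosage covariance $\mathrm{Cov}(x_i, x_j) = 4\phi_{ij}p(1-p)$
implied by kinship.  With $\Phi = \tfrac12 I$ this reduces *exactly* to
the classical trend test — that identity is enforced to $10^{-12}$ against
a brute-force oracle in the test suite.  Missing dosages are excluded per
SNP with the contrast and kinship submatrix restricted to observed
samples.  A monomorphic SNP returns $T = 0$, $p = 1$.

The calibration study (acceptance suite) uses 500 sib-pair families with
*fully familial* phenotypes — both sibs share their family's case/control
status — because that is the worst case the correction exists for: with
genotype correlation $2\phi = 0.5$ between sibs and concordant labels, the
naive variance is too small and the uncorrected test over-rejects
($\approx 8\%$ at $\alpha = 0.05$ here), while the corrected test stays in
$[0.04, 0.06]$.  A generator draw with independent labels would show no
inflation and test nothing.

### Pre-selection, imputation, model building

Pre-selection offers two modes: `top_k` (default 100; ties broken by
chromosome and position so results are reproducible) and `p_threshold`
(default $10^{-3}$).  The pipeline's base pool is the `p_threshold` pool,
falling back to `top_k` when a scan is too sparse.

One deliberate information-flow choice: the pipeline's
pre-selection scan always excludes the held-out test subjects.  Running
pre-selection on the full cohort leaks test information into the feature
space; excluding the test set makes the "missed-from-train" branch fully
clean, which the test suite asserts by fingerprinting every model's
training IDs.  The "missed-from-test" branch (re-modeling the test set's
misclassified samples) inherently uses test labels; it is kept because it
is the variant practitioners often run in exploratory work, and every
artifact it produces is
stamped `test_informed_selection = TRUE`.

Missing dosages inside a pool are filled by kNN-median imputation: for a
missing cell, the k = 5 samples nearest in Euclidean distance over
mutually observed SNPs (among samples observed at that SNP) contribute
their median, rounded to $\{0,1,2\}$ (halves round up).  k = 5 is a
default, not a fitted value; with LD-free simulated SNPs the neighbours
are only informative when relatives are present, which is why the
recovery experiment in the tests uses a familial cohort.

The LASSO protocol: dosages standardized to zero mean / unit variance on
the training set; penalty grid of 100 values log-spaced four decades down
from the smallest $\lambda$ that zeroes every coefficient; stratified
10-fold CV minimizing mean binomial deviance (the standard "mean
cross-validated error" for penalized logistic models, preferred over
misclassification rate because it is smooth in $\lambda$); final model
refit on the full training set at the chosen penalty.  Coefficients are
reported on both the standardized and the dosage scale.  Out-of-fold
probabilities at the chosen penalty are retained: for tiny sample sets
they are the only evaluation that is not pure resubstitution.

The headline evaluation uses a single seeded stratified 80/20 holdout.
An alternative reading of "internal cross-validation" — resampling the
split itself — is provided by `repeated_holdout()`, which reports
mean ± sd of the metrics over (by default) 20 resplits; the two agree in
expectation, and the repeated mode quantifies how much a single-split
number owes to the particular holdout.

Evaluation: probability threshold 0.5 (a score exactly at 0.5 is called a
case — documented boundary), confusion matrix with case as positive,
accuracy / sensitivity / specificity, and AUC by the trapezoidal rule over
the exact ROC, which equals the Mann–Whitney pair-counting statistic with
the mid-rank tie convention; the identity is asserted exactly on 1,000
random score vectors.

### Re-modeling and mixing

`remodel_missed()` re-runs the kinship-corrected scan restricted to the
misclassified samples — by default together with all members of their
families, since the familial set is what the kinship correction is for; a
`include_family = FALSE` switch restricts to the missed subjects alone —
pre-selects at $p < 10^{-3}$, and fits the LASSO on the missed samples
with CV folds auto-reduced to the smallest class (at least 2; a missed
set with fewer than two subjects per class cannot support a model and is
reported as skipped).  Its evaluation is taken from out-of-fold CV scores
by default (resubstitution is available behind a flag) and is stamped
*optimistic* either way, because the pool was selected on the same
samples.

`mix_snp_pools()` and `mix_model_snps()` implement the two merging
strategies as plain set unions ordered by genomic position;
`refit_and_compare()` refits the merged pool on the unchanged training
set and reports the AUC delta on the unchanged test set.
`model_overlap()` counts pairwise shared and model-specific selected SNPs
and lists selected pairs with dosage $r^2 > 0.95$ (near-duplicate markers
that make model length comparisons slippery).

## The synthetic cohort generator

The generator produces the statistical structure the analysis assumes,
with a truth manifest for every planted feature:

* **Two ancestry clusters** via the Balding–Nichols model: ancestral
  frequencies uniform on `maf_range` (default 0.05–0.5), population
  frequencies Beta-distributed around them with variance
  $F_{st}\,p(1-p)$.
* **Families**: each affected founder receives up to two full siblings.
  Parents are drawn from their exact posterior given the founder's
  genotype under HWE — the transmitted alleles are read off the founder,
  the untransmitted alleles drawn Bernoulli from the population frequency
  — and siblings follow by Mendelian transmission.  This preserves the
  founder's genotype (and with it the planted genotype-phenotype
  association) instead of resampling it, while producing exactly the
  sib/parent-offspring kinship of 0.25 recorded in the manifest.
* **Phenotypes**: a fraction of subjects (default 15%) is flagged as the
  hidden sub-class.  Majority subjects are cases with probability
  $\mathrm{logit}^{-1}(\alpha_{\text{main}} + 0.4\sum_{\text{20 main
  SNPs}} g)$; sub-class subjects follow the analogous model over 15
  different SNPs at effect 0.6.  Intercepts are solved by bisection (to
  $10^{-6}$ on the expected case share) so both groups target the
  configured case:control balance.  Sub-class membership is drawn among
  all subjects, not only cases, so misclassified controls exist too.
* **Planted QC failures**, pairwise disjoint and never causal:
  monomorphic (all dosage 0), Hardy–Weinberg violations (genotypes drawn
  at frequency 0.5 with inbreeding coefficient $F = 0.8$, i.e. het
  probability $2p(1-p)(1-F)$ — $F$ and $n$ chosen so single-SNP detection
  power at $p < 10^{-5}$ is essentially 1), high-missingness SNPs
  (per-SNP rates uniform on 5–15%, safely beyond the 2% threshold), and
  markers stripped of their "rs" prefix.  Background missingness is
  completely at random, applied outside the planted SNPs so that QC
  attribution against the manifest is exact.
* Finally every SNP is oriented to minor-allele dosage on observed calls
  (ties keep the original allele), which makes PLINK text-dialect round
  trips lossless; flipped SNPs are recorded in the manifest.

What the generator deliberately does **not** emulate: linkage
disequilibrium (SNPs are independent), sex chromosomes, covariates such
as age and sex, informative missingness, genotyping batch effects.
Passing tests therefore demonstrate the *protocol's* behaviour under its
own assumptions, not performance on real arrays — in particular,
imputation and the $r^2$ redundancy check are exercised on structure
(families) rather than on LD, and real-data pool sizes will differ.

## Reference study conditions and what they show

The package's reference validation cohort is 2,000 unrelated subjects and
20,000 SNPs, majority signal 20 SNPs at log-odds 0.4, sub-class 15% of
subjects driven by 15 SNPs at log-odds 0.6.  Under these conditions the
oracle (Bayes) AUC of the full generative model is $\approx 0.74$ against
$\approx 0.70$ for the majority-only predictor, so the ceiling on any
re-modeling gain is a few AUC points.

A per-SNP power budget explains what the feedback step can and cannot do
here.  Within the sub-class, each causal SNP carries a dosage-label
correlation of roughly $r \approx 0.15$; in a misclassified training set
the sub-class is diluted to roughly a quarter of the samples, giving
$r \approx 0.03$–0.04 at $n \approx 450$, i.e. a z-score well below the
$\approx 3.3$ needed for the $p < 10^{-3}$ pre-selection.  The
misclassified-sample scan therefore recovers sub-class SNPs only rarely,
and the Models-Mix pool is typically the base pool plus a couple of dozen
noise markers.  Across seeded replicates the held-out delta-AUC is
slightly *negative* on average (about -0.01 to -0.02) — and the companion
null study with `subclass_fraction = 0` shows the same small negative
shift, identifying it as the cost of injecting the missed model's noise
SNPs into a small pool rather than anything sub-class-specific.  With a base
pool in the thousand-SNP range the same injection is relatively far
smaller and correspondingly less costly.  The
acceptance suite runs both studies and reports the deltas as measured;
the recovery criterion is expected to read negative at these effect
sizes.  The mechanism
itself is demonstrated where it has power: when the missed set *is* the
planted sub-class and the sub-class is large enough for single-SNP power
(the permutation-enrichment test in the remodel suite), the recovered
pool is significantly enriched for the true sub-class SNPs.  The honest
summary is that misclassification feedback pays off when the hidden
class's per-marker signal is strong enough to clear pre-selection inside
the missed subset; at the reference effect sizes it is not, and the
pipeline reports that faithfully rather than manufacturing a gain.

## Numerical and implementation choices

* Dosage storage is a plain numeric matrix with `NA` for missing — never
  0 — so monomorphism detection is independent of missingness.
* The PLINK binary codec follows the 1.9 layout exactly (SNP-major,
  3-byte header, 2-bit codes `00`/`01`/`10`/`11` = hom-A1 / missing /
  het / hom-A2, zero-padded final byte per SNP); binary dosages count A1
  *as stored*, making binary round trips bit-exact.  Text `.ped` carries
  no allele order, so the reader counts the rarer observed allele with
  alphabetical tie-break, and a monomorphic text SNP reads as all-zero
  dosage with its single allele as the major allele.
* Kinship matrices are sparse symmetric (`Matrix`), block-diagonal by
  family; the association scan uses a bulk vectorized path for
  complete-case SNPs and a per-SNP sparse quadratic form otherwise.
* All randomness flows from explicit seeds; the pipeline draws one
  sub-seed per stage from the master seed, so the full run (simulation
  through mixing) is byte-reproducible, which the acceptance suite
  checks on serialized summaries.
* Problem sizes in the test suite are scaled to the structure each check
  needs: module tests use cohorts of a few hundred subjects and a few
  hundred to a few thousand SNPs; the calibration study uses 500
  families x 10,000 SNPs; the re-modeling study runs the reference
  2,000 x 20,000 configuration across 20 seeded replicates plus 10 null
  replicates.

## Limitations

* No LD means pool sizes and redundancy counts are not comparable to
  array data; the $r^2 > 0.95$ check is exercised via duplicated columns.
* The misclassified-sample evaluation is optimistically biased by
  construction (pool chosen on overlapping samples); it is reported with
  an explicit flag rather than hidden.
* The corrected test uses a single pooled allele frequency; it is a
  score-type approximation, not a full mixed-model association.
* Subject-level call-rate filtering is not implemented (only SNP-level),
  and PLINK 2 formats, VCF and multiallelic sites are out of scope.
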