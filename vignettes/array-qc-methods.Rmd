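---
title: "Quality control for genotyping-array cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for genotyping-array cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayqc)
```

# Scope

`arrayqc` implements the sample- and variant-level quality control (QC)
sequence used to clean genotyping-array data from human cohort studies before
imputation and association analysis: genetic sex inference, relatedness
estimation and resolution, PCA-based ancestry inference, exact
Hardy-Weinberg (HWE) testing and variant filtering, duplicate-pair
concordance, runs-of-homozygosity (ROH) diagnostics, post-imputation quality
stratification, *APOE* diplotype calling, and candidate-SNP replication.
Because the cohorts this pipeline is designed for are access-controlled, the
package ships a synthetic-cohort generator with ground-truth sidecars; every
stage is validated by parameter recovery on data whose answer is known by
construction.

This vignette records the models behind each stage, the defaults and why they
were chosen, the numerical conventions, and the limitations of the synthetic
evidence.

# The synthetic cohort generator

`cohort_spec()` + `simulate_cohort()` produce a `geno_dataset` (sample and
variant tibbles plus an integer call matrix coded 0/1/2/NA counting A1
copies) together with truth tables for sex, pedigree kinship, planted ROH
segments, ancestry and variant defects.

**Population structure.** Allele frequencies follow the Balding-Nichols
model: an ancestral frequency $p$ drawn uniformly on `ancestral_maf_range`
(default $[0.05, 0.45]$), and per-population frequencies
$p_k \sim \mathrm{Beta}\!\left(p\tfrac{1-F_{ST}}{F_{ST}},
(1-p)\tfrac{1-F_{ST}}{F_{ST}}\right)$, which has mean $p$ and variance
$F_{ST}\,p(1-p)$. The default is two populations at $F_{ST} = 0.15$ in a
90/10 split — the magnitude of European/African differentiation, which is
what makes the first principal component separate the two self-reported
groups cleanly. Variants are drawn independently (linkage equilibrium): all
of the pipeline's statistics are defined on genotypes, not haplotypes, so LD
is not needed for their validation, and the LD-pruning step is exercised
with explicitly constructed correlated blocks in the test-suite instead.

**Relatives.** Planted pairs are produced by gene dropping on the autosomes:
duplicates copy the genotype vector; full siblings each receive one
transmitted allele from each of two simulated parents; 2nd- and 3rd-degree
pairs are built by chaining parent-offspring transmissions
(grandparent-grandchild, great-grandparent-great-grandchild). Under linkage
equilibrium the realised kinship concentrates tightly around the pedigree
values (0.5, 0.25, 0.125, 0.0625), which is what makes bin-recovery tests
sharp. X genotypes of non-duplicate relatives are drawn independently - the
X is used only for sex inference here.

**Sex.** Males are hemizygous on the X, coded 0/2. The default cohort is 64%
female. Planted sex swaps flip the self-report relative to the genetic truth.

**Specimen, site, batch.** Blood samples miss each genotype with default
probability 0.002 (call rates ~99.6-99.9%) and serum with 0.02 (~97.1-98.9%),
the two-specimen contrast this design emulates; samples are assigned to array
batches of 6-8 in enrollment order. A named `batch_effects` entry adds
missingness to one batch, planting a batch outlier. Missing masks are
per-genotype independent Bernoulli draws with probability
specimen + batch (+ per-variant defect), clipped to $[0,1]$.

**Genotype errors.** Two error processes are available. The default
`"uniform"` model replaces a hit genotype by one of the other two codes with
equal probability - a maximally agnostic convention that the concordance
oracle enumerates exactly. The `"adjacent"` model misreads a single allele
copy: homozygotes become heterozygous, heterozygotes become either
homozygote. Real array miscalls have the adjacent structure; opposite-
homozygote jumps essentially never occur. The distinction matters for
identity checks: uniform errors create IBS0 events between duplicate copies,
and at a 0.5% error rate they alone push the expected PI_HAT of a true
duplicate down to ~0.95, below the conventional >0.98 identity criterion;
adjacent errors leave PI_HAT at ~0.99. The duplicate-identity validations
therefore use the adjacent model, and the uniform model remains the default
contract for the enumeration-based concordance checks.

**Autozygosity.** Each sample receives a target fraction of its genome in
ROH (default uniform on 0.5-4%, the human range). Tracts are planted by
forcing contiguous stretches (3-6 Mb spans, with a final shorter top-up
tract when the remaining target is small) homozygous for the major allele;
inter-SNP spacing is 25 kb, so the density and gap rules of the detector are
satisfied by construction and the truth is exact. Samples listed in
`dispersed_homozygosity` instead get the same excess homozygosity scattered
over random positions - elevated inbreeding coefficient with no tracts, the
signature of the low-ROH outlier the LOESS rule is designed to flag. Two
practical notes from validation: dispersed fractions must lie inside the
cohort's normal F range (a lone extreme-F point anchors the local fit and
its own residual vanishes), and samples in planted relative pairs receive no
tracts so their pedigree kinship stays exact.

**Planted variant defects.** `variant_defects` plants unambiguous failures:
low-MAF variants (ancestral frequency 0.0005-0.002, far enough below the 1%
threshold that sampling noise cannot rescue them), low-call variants (+20%
missingness), and HWE violations (heterozygote probability inflated to
$\min(0.9, 2\cdot 2pq)$ at mid-range frequencies 0.25-0.45, so the exact
test rejects decisively at any realistic cohort size).

**Determinism.** The whole cohort is a function of `spec$seed`;
`draw_allele_frequencies()` consumes the RNG stream first so its public
output matches what `simulate_cohort()` used internally. The overlay
functions accept their own optional seeds.

# Sample QC

**Call rates and group comparisons.** Per-sample call rate is the fraction
of non-missing calls. Specimen and site comparisons use a two-sided Wilcoxon
rank-sum test on per-sample missing rates; missing-rate distributions are
skewed, so a rank test is the appropriate default. When all rates are tied
the test carries no evidence and p = 1 is returned. The site comparison can
be stratified by specimen (`stratify_by = "specimen"`) to hold the
specimen mix fixed - the package's interpretation of "accounting for" a
confounded specimen distribution, chosen over a model-based adjustment
because it makes no distributional assumption.

**Sex inference.** The X inbreeding coefficient is
$F = (O_{hom} - E_{hom}) / (N - E_{hom})$ with
$E_{hom} = \sum_i \left(1 - 2p_i(1-p_i)\tfrac{N_i}{N_i-1}\right)$ over the
sample's non-missing polymorphic X variants; the $N_i/(N_i-1)$ factor is the
small-sample correction of expected heterozygosity. Hemizygous males have no
X heterozygotes, so $F \to 1$; females under Hardy-Weinberg proportions sit
near 0. Decision thresholds default to $F \ge 0.8$ male and $F \le 0.2$
female (the conventional values; both configurable), with the band between
left undetermined rather than guessed. A mismatch is flagged only when a
confident call contradicts a known self-report, so noisy samples degrade to
"undetermined" instead of producing false swaps. Monomorphic X variants are
excluded (zero information; avoids division artifacts). With a few hundred
X markers the sampling SD of female $F$ is ~0.05-0.07, which is why the
0.2/0.8 band recovers planted swaps exactly while tolerating noise.

**Batch outliers.** Batch means of the missing rate are flagged above
$Q_3 + 1.5\,(Q_3 - Q_1)$, quartiles over the batch means by the
linear-interpolation convention (`quantile(type = 7)`), fixed so the rule is
reproducible. The rule is invariant to batch order and location shifts.
Because batch means inherit the blood/serum contrast, a cohort with a mixed
specimen design spreads the batch-mean distribution; the planted-batch
recovery validation uses an all-blood cohort so the batch effect is the only
batch-level signal.

# Relatedness

**GRM.** Entry $(j,k)$ averages
$(x_{ij} - 2p_i)(x_{ik} - 2p_i)/(2p_i(1-p_i))$ over variants non-missing in
*both* samples (pairwise-complete, not mean-imputed - the estimator stays
unbiased per pair and degrades gracefully under serum missingness). The
off-diagonal is twice the kinship coefficient for outbred pairs;
`classify_relationships()` therefore halves it before applying the bins
$> 0.354$ (duplicate/MZ), $[0.177, 0.354)$ (1st degree), $[0.0884, 0.177)$
(2nd), $[0.0442, 0.0884)$ (3rd). Halving is the only reading under which a
full sibling (kinship 0.25) lands in the printed 1st-degree interval.
Intervals are closed on the left and open on the right; kinship exactly
0.177 is 1st degree and exactly 0.354 classifies as duplicate/MZ.

A caution demonstrated in the test suite: with pooled allele frequencies and
strong two-population structure ($F_{ST} = 0.15$), GRM entries between
members of the minority population are inflated by roughly $2F_{ST}$ - a
property of the estimator, not an error. On mixed cohorts the initial
relatedness pass should be read together with the per-ancestry second pass.

**Method-of-moments IBD.** Observed IBS 0/1/2 counts are combined with their
expectations under IBD state 0/1/2. The expectations replace powers of the
allele frequency with unbiased falling-factorial estimators from the $2N$
sampled alleles (e.g. $\widehat{p^2} = X(X-1)/(2N(2N-1))$ for allele count
$X$), the standard small-sample correction. Solving the moment equations in
order gives $Z_0, Z_1, Z_2$; negative or >1 estimates are clipped and the
triple renormalised to sum to one (the reference convention), and
$\hat{\pi} = Z_2 + Z_1/2$. Pairs with $\hat{\pi} > 0.98$ are treated as
genetically identical.

# Ancestry

**LD pruning** slides a 50-SNP window by 5 SNPs; while any retained pair in
the window has $r^2 > 0.1$ (Pearson correlation of genotype codes,
pairwise-complete), one member of the worst pair is removed, preferring
higher missing rate, then lower MAF, then later position. The retained set
is verified pair-by-pair against a brute-force window check in the tests.

**PCA** standardises genotypes by $1/\sqrt{2p(1-p)}$ (the reference scaling
for genotype PCA), sets missing entries to zero after centring (mean
imputation - preserves the eigenstructure under low missingness), and takes
eigenvectors of the sample covariance; variance explained is
eigenvalue/trace. Component signs are fixed by forcing the first non-zero
variant loading positive so that repeated runs are bitwise identical;
scores are eigenvectors scaled by the singular values.

**The six-SD rule.** Within each eligible self-reported group (>= 3 members
by default), members within six SDs of the group's PC1 mean receive the
group's ancestry label; members outside are flagged outliers and left
unassigned. Samples from groups too small to estimate a mean and SD are left
unassigned rather than force-clustered - their ancestry cannot be
confidently inferred. The second-pass PCA is the same procedure re-run per
assigned ancestry group on a tighter variant set (call rate > 98%,
MAF > 0.05, pruned), and its top 10 scores are emitted as analysis
covariates.

# Variant QC

**Exact HWE test.** Conditional on the rare-allele count $n_r$, the
probability of each feasible heterozygote count $h$ (same parity as $n_r$)
is computed by the stable mid-out recurrence starting at the conditional
mode; the p-value sums probabilities of tables no more probable than the
observed one (two-sided exact, no mid-p by default; a mid-p variant is
available). Monomorphic tables give p = 1 and the test is symmetric in the
homozygote counts. The implementation is checked against an independent
factorial-formula enumerator for every genotype table up to n = 50 at 1e-12,
and its null calibration (conservativeness at the 1e-6 threshold) is
verified by simulation.

**Stats and filters.** MAF is $\min(\hat p, 1-\hat p)$ from non-missing
calls; on the X, reported males contribute one allele each and HWE is
computed in females only (hemizygotes are not draws from a diploid
Hardy-Weinberg model). Filters are strict inequalities exactly as printed:
call rate > 0.95, MAF > 0.01, HWE p > 1e-6 for the final set; > 0.95 /
> 0.05 / > 1e-6 for the sample-QC subset; a variant exactly at a bound is
removed. All-missing variants have undefined MAF and fail every threshold.

**Duplicate concordance.** Comparable variants are non-missing in both
copies and not double-heterozygous (a double heterozygote cannot reveal a
mismatch between unphased genotypes); concordance is the concordant fraction
of comparable variants, and discordant variant ids are pooled across pairs
into a per-variant hit count. A sensitivity mode keeps double-heterozygotes
in the denominator.

# ROH and the low-ROH outlier rule

`detect_roh()` follows the scanning-window algorithm: 50-SNP windows are
"homozygous" if they contain at most 1 heterozygous and 5 missing calls; a
SNP is a hit when at least 5% of the windows covering it are homozygous;
consecutive hits form candidates, split at inter-SNP gaps above 1,000 kb,
and reported when they have >= 100 SNPs, span >= 1,000 kb
(length = end - start + 1, 1-based), and average <= 50 kb per SNP. The five
printed parameters are the configuration surface; the window allowances
(1 het / 5 missing) and the 5% hit threshold are the reference tool's
defaults, also configurable. Chromosomes shorter than one window are scanned
as a single truncated window. Every reported segment is re-checked in the
tests by a direct rule evaluator, and the detector is invariant to extending
heterozygous flanks once those flanks are at least one window wide (inside
that width, edge windows change by construction).

`heterozygosity_f()` is the same $F$ estimator as the sex check, on
autosomes. `loess_outliers()` fits total ROH (kb) against $F$ by local
quadratic regression with tricube weights, span 0.5, no robustness
iterations (robust refitting would shift the percentile cut), and flags
residuals below the 1st percentile of the group's residual distribution.
Two structural consequences, verified in the tests: the rule flags ~1% of
any cohort by construction - on a cohort with no planted problems those
flags are the price of a fixed-percentile rule - and a planted outlier is
recovered exactly when the planted count matches the percentile's expected
flag count.

# Post-imputation validity checks

`summarize_imputation()` stratifies variants into MAF bins (rare < 1%,
low-frequency 1-5%, common >= 5%, closed-left bins) and reports the fraction
with imputation $R^2$ at or above 0.3/0.5/0.8/0.9; rows with missing $R^2$
are excluded and counted. Fractions are monotone non-increasing in the
threshold on any input.

*APOE* diplotypes are derived from rs429358 and rs7412 hard-called dosages
(nearest integer within 0.1, else missing; the common convention, since how
dosages become genotypes is a caller's choice). The epsilon haplotypes on
the (rs429358, rs7412) allele pair are e2 = T/T, e3 = T/C, e4 = C/C,
e1 = C/T; eight of the nine two-SNP genotype combinations determine the
diplotype uniquely, and the double heterozygote (e2/e4 vs e1/e3) is resolved
to e2/e4 - e1 is vanishingly rare in all populations - and flagged
`ambiguous` so carrier analyses can drop it in sensitivity runs.
`apoe_concordance()` reports diplotype concordance against a gold standard
plus the e4-carrier misclassification cross-tabulation.

`replicate_snp()` truncates the trait to mean +/- 4 SD in a single
non-iterative pass (iteration is not implied by a fixed-threshold
truncation), then fits OLS of trait on dosage plus caller-supplied
covariates (top PCs, specimen, site - the covariate set is an input, since
different analyses adjust differently); replication requires a two-sided
p < 0.05 *and* a coefficient sign matching the prior report. Under the null
this fires at ~2.5% for a fixed expected sign.

# Pipeline

`run_pipeline()` executes: pre-filter (sample call rate >= 90%, then
MAF >= 1%); sample QC on a high-quality SNP subset (sex mismatches dropped;
2nd-degree-or-closer pairs resolved by keeping the higher-call-rate member;
specimen/site tests and batch flags recorded); preliminary PCA + six-SD
ancestry assignment (outliers and non-eligible groups excluded); duplicate
concordance (diagnostic only); per-ancestry ROH/LOESS outlier exclusion;
per-ancestry final variant filters; per-ancestry second-pass PCA with a
covariate table (top PCs, specimen, site, batch-outlier flag). Counts
telescope: each stage's input equals the previous stage's output, checked
in the run report. A GRM variant cap (`grm_max_variants`, default 50,000)
bounds the relatedness pass on very dense inputs.

# Problem sizes used in validation

Relatedness checks use 50,000 independent common variants (where duplicate
and sibling kinship estimates have SDs of a few thousandths); the
planted-structure recovery runs on a 600-sample x 100,000-variant cohort;
PCA separation uses 400 samples x 20,000 variants at $F_{ST} = 0.15$; the
HWE implementation is compared exhaustively to its oracle up to n = 50.
These sizes were chosen so that each statistic's sampling noise is an order
of magnitude smaller than the decision margin it is tested against.

# Limitations

The generator draws variants in linkage equilibrium and plants exact
homozygous tracts; it does not emulate haplotype-level coalescent structure,
imputation-server behaviour (imputation quality enters as user-specified
$R^2$ distributions), strand or allele-harmonisation issues (allele codes
are opaque and never flipped), sex-chromosome aneuploidy, or
batch-correlated genotype error. Passing the recovery suite therefore shows
that the estimators and decision rules are implemented correctly at
realistic signal sizes - it does not certify behaviour under artefacts the
generator does not model, and on real mixed-ancestry cohorts the
pooled-frequency relatedness caveat above applies.
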