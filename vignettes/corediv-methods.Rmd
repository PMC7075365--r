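---
title: "Methods: diversity statistics, maximum-length-subtree cores, and mixed-model GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics, maximum-length-subtree cores, and mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the conventions adopted where the underlying
methodology literature leaves choices open, and what a green test does —
and does not — establish.

## 1. Data model

A panel is a `genotype_matrix`: accessions × biallelic SNP sites coded
as ALT-allele dosage {0, 1, 2}, with `NA` as the missing sentinel (never
0, which is a legal homozygote). Major/minor allele status is always
derived from observed frequencies, *not* from REF/ALT: reporting tables
name major/minor alleles, and at sites where the ALT allele is the
majority the two framings disagree. Coordinates are 1-based as in VCF;
scaffold and pseudo-group labels are carried verbatim, with no liftover.

## 2. Marker and diversity statistics

For allele frequencies *p*, *q* = 1 − *p* estimated from non-missing
alleles:

* MAF = min(*p*, *q*);
* PIC = 1 − (*p*² + *q*²) − 2 *p*²*q*², the two-allele specialization of
  1 − ΣPᵢ² − ΣΣ2Pᵢ²Pⱼ². It is 0 iff the site is monomorphic and reaches
  its biallelic maximum 0.375 at *p* = 0.5. Both facts are tested, as is
  invariance under allele relabeling.
* Ho (per accession) = heterozygous calls / called sites; undefined
  (reported `NA`) for an accession with no calls.
* IBS distance d(a,b) = mean over pairwise-complete sites of
  |xₐ − x_b| / 2.

**Convention (het–het sharing).** Two heterozygotes at a site are
scored distance 0 (full allele sharing). The alternative probabilistic
convention (0.5, from random allele draws) would make d(a,a) > 0 for
any heterozygous accession; determinism and d(a,a) = 0 decide the
choice. Consequently distances run slightly lower than under the
probabilistic convention.

**Group summaries.** The per-group table reports S (size), ASC —
interpreted as the *mean count of non-missing genotyped sites per
accession* in the group, the reading consistent with a whole-panel ASC
below the total site count — and mean ± SE for Ho, and for PIC and MAF
*recomputed within the group*. The ± values are standard errors of the
mean: reference tables of this kind print ±≈0.006 at n ≈ 400, the
magnitude of an SE, not an SD. Both interpretations are named in output
headers so downstream comparisons are explicit.

## 3. Filtering

The four-step retention chain runs in a fixed, documented order: hard
QUAL/INFO thresholds → biallelic restriction → MAF/missingness → LD
pruning. A site fails the hard filter only on an annotation *present*
for it; absent keys are logged, never treated as failure. Thresholds
(defaults): QUAL < 50, QD < 2.0, FS > 60.0, MQ < 40.0,
MQRankSum < −12.5, ReadPosRankSum < −8.0; MAF ≥ 0.05 (fraction);
missingness ≤ 0.10.

LD pruning uses windows counted in sites (50), advanced by 10, with
r² > 0.2, where r² is the squared Pearson correlation of dosages over
pairwise-complete samples (composite LD — phase is never inferred,
because only dosages exist). The upstream tools' exact intra-window
removal rule is not published, so the package fixes a deterministic one:
pairs are visited in (i, j) order and the lower-MAF member of a
violating pair is removed (tie: the later site). A brute-force windowed
all-pairs oracle in the tests pins this behavior down, and a re-scan
asserts no surviving within-window pair exceeds the threshold.

## 4. Tree building

IBS dissimilarities are element-wise square-root transformed
("Euclidean" scale — the scale on which the synonym threshold below is
expressed), then classic Saitou–Nei neighbor joining is run with the
rate-corrected criterion Q(i,j) = (m−2)d(i,j) − rᵢ − rⱼ.

Numerical conventions: ties in Q resolve toward the lexicographically
smallest pair of cluster labels (a cluster is labeled by its smallest
leaf), so output is deterministic; negative branch estimates are clamped
to 0 *without* transferring length (simplest defensible rule; it touches
only near-zero edges). On additive matrices the reconstruction is exact,
which the tests verify to 1e-10 against random additive matrices and
against `ape::nj` as an independent oracle.

Bootstrap supports resample sites with replacement, rebuild
IBS → sqrt → NJ per replicate, and score each internal bipartition of
the point tree by its replicate frequency; a duplicated accession pair's
cherry therefore has support 1 under any resample. `cut_into_groups()`
(remove the k−1 longest internal edges) is a *reproducible stand-in*
for expert visual cluster delineation; published group counts obtained
by eye are deliberately not an acceptance target.

## 5. Maximum-length-subtree core selection

The exact algorithm inside the original core-collection software is
proprietary in detail; the package adopts the greedy rule that directly
embodies "prune the redundant, keep the long edges":

1. among retained leaves not in `must_keep`, remove the one with the
   shortest terminal edge (ties: the lexicographically *latest* tied
   leaf goes, so the smallest label survives — the convention that
   matches duplicate-pair behavior);
2. suppress the resulting degree-2 node, its two edges merging by
   addition (the tree is *not* re-estimated, preserving the backbone);
3. log the removed accession, its terminal-edge value, its cherry
   partner at removal time, the retained total length, retained size,
   and the sphericity index of the retained set.

One call therefore yields the whole nested family of cores; nestedness
is asserted in the tests rather than assumed.

**Sphericity index.** No published formula accompanies the name in the
core-collection literature the package follows; the implemented
definition — mean pairwise distance / max pairwise distance within the
retained set, in (0, 1], defined as 1 for a pair or an all-identical
set — is an artifact convention chosen to be bounded, monotone under
removal of near-duplicates, and testable. It is flagged as such
wherever it is reported.

**Stopping size.** The flat-slope visual judgment used in practice is
operationalized as the knee of the (retained size, sphericity-or-length)
curve: the point of maximum perpendicular distance from the chord
joining the curve's endpoints, ties toward the larger retained size, a
"no knee" flag when the curve is linear within 1e-12 relative
tolerance.

**Synonyms.** Any removal whose removed-edge value falls below 0.0008
(on the Euclidean, i.e. square-root, scale — the scale on which that
threshold is conventionally quoted) flags the removed accession as a
presumptive synonym of its cherry partner. Duplicate genotypes are
removed at value 0 and always flagged.

**must_keep.** Reference cultivars re-added by hand to published
mini-cores generalize to a `must_keep` set that the greedy rule may
never remove; its twin is removed instead (tested).

## 6. Phenotypes

MLSI = MLL/MLW and MLA = 0.75·MLL·MLW are recomputed from the defining
formulas; MLW = 0 or negative dimensions are errors, missing dimensions
propagate `NA` without dropping the record. Skewness and kurtosis use
the small-sample adjusted estimators (G1; excess G2) with their
closed-form SEs — the only conventions under which descriptive tables
printing SE(skew) ≈ 0.122 at n ≈ 400 are reproducible in form:
SE(G1) = √(6n(n−1)/((n−2)(n+1)(n+3))) = 0.1220185 at n = 400. Pearson
correlations are computed pairwise-complete within season and, per
trait, across seasons on accession-matched values, with two-sided p
from the t transform.

## 7. Mixed-model association

Model: y = Xβ + m·b + u + e, u ~ N(0, σ²g K), e ~ N(0, σ²e I), X an
intercept plus Q-matrix (one ancestry column dropped) or top principal
components (default 3, sign fixed so each component's largest-magnitude
loading is positive). REML estimates δ = σ²e/σ²g via the spectral
decomposition of K: a 100-point grid on log δ ∈ [−10, 10] refined by
golden-section to 1e-6. P3D fixes δ at the no-marker null; `exact`
re-estimates per marker. The marker test is the F test on the dosage
coefficient in the whitened model; marker R² is the proportional
reduction in whitened residual sum of squares against the
covariates-only fit (the reference reporting says only that R² is "the
phenotypic variation explained", so the definition is fixed here).
With K = I the whitening is a scalar and every p-value collapses to the
OLS F test exactly — the tests assert agreement to 1e-8.

Kinship: `ibs` (1 − IBS distance; duplicates hit 1) or `vanraden`
(standardized-dosage cross-product / site count), both with a 1e-6
diagonal ridge for numerical PSD. The estimator used is recorded in the
fit metadata, since the reference workflow does not name its estimator.

Missing dosages at a tested marker drop those accessions *for that
marker only* (pairwise deletion), implemented as a per-marker Cholesky
GLS on the complete subset; complete markers share one cached
decomposition and a vectorized scan. Allele-class effects are genotype
class means minus the grand mean of phenotyped, genotyped accessions —
a reproducible stand-in for the unpublished two-number allele-effect
parameterization in reference hit tables; an empty homozygote class
yields a missing effect, never 0.

Model choice between Q+K and P+K follows the Q-Q-plot comparison,
operationalized as the model whose genomic inflation factor
λ = median(χ²obs)/qchisq(0.5, 1) is closest to 1; both λ values are
kept in the pipeline manifest. The Bonferroni threshold is α/m at full
precision (and 3-significant-digit rounding for display; 0.05/30,282
prints as 1.65e-06).

## 8. The simulator: what it emulates, and what it does not

`simulate_panel()` is a Balding–Nichols generator with admixture —
exactly the covariance structure the Q+K model assumes: ancestral
frequencies ~ U(0.05, 0.95), subpopulation frequencies
~ Beta(p(1−F)/F, (1−p)(1−F)/F) with F = 0.10 per subpopulation (3
subpopulations), individual ancestries ~ Dirichlet(0.2) (mostly
assigned, partly admixed), genotypes ~ Binomial(2, ancestry-weighted
frequency), 2% uniform missingness, 20 pseudo-group labels with sorted
unique positions. Default dimensions 400 × 5,000 scale the reference
design of ~415 accessions × ~30k SNPs down ~6× in sites for desk speed.

`simulate_traits()` builds a standardized latent value from variance
shares — planted causal SNPs (`causal_r2`, defaults 0.03/0.05/0.08,
the marker-R² magnitudes reference hit tables report), a polygenic
remainder up to h² (default 0.4), a season-shared environmental share
lifting the cross-season correlation to 0.9 (the magnitude of published
cross-season trait correlations), and per-season noise — then scales to
leaf-width/length units (MLW 3.748 ± 0.933 cm, MLL 8.655 ± 2.251 cm,
within-season latent correlation 0.86, matching published descriptive
tables), derives MLSI and MLA by their formulas, and floors dimensions
at 0.05 cm (an event of probability ~3e-5 per record under the
defaults, documented rather than resampled). Per-subpopulation latent
mean shifts are the confounding switch for type-I-error experiments.

What the simulator does *not* emulate: linkage (sites are exchangeable
given structure, so LD pruning exercises correlation planted by the
test fixtures, not recombination maps), allele-frequency spectra shaped
by ascertainment, genotyping-error structure beyond uniform
missingness, and selection/demography. A green simulation test
establishes that the *pipeline machinery* behaves as specified under
the model the analysis itself assumes — it does not certify performance
on real GBS data, and the published study's exact headline numbers
(which depend on an undeposited genotype panel) are out of reach by
construction. Under the stated defaults the generator's mean observed
heterozygosity sits near the top of the asserted [0.15, 0.35] bracket,
above the ~0.22 of the motivating panel — a consequence of the uniform
ancestral spectrum, accepted and documented rather than recalibrated.

## 9. Calibration experiments: two design notes

Two constructions in the acceptance suite deserve explanation because
the obvious alternatives are subtly wrong:

* **Null markers must be null.** Drawing a polygenic background from
  the very markers being tested gives every marker a real micro-effect
  (R² ≈ h²/m each), which at desk scale (m = 240) measurably inflates
  the null rejection rate. The type-I experiment therefore uses h² = 0:
  confounding enters only through subpopulation mean shifts, and every
  tested marker is exactly null.
* **Held-out kinship.** Estimating K from the tested markers themselves
  deflates each marker's own test (proximal contamination ~1/m) —
  negligible at tens of thousands of sites, visible at hundreds. The
  calibration replicates simulate twice the sites and estimate K from
  the held-out half, so the binomial confidence band is the right
  yardstick.

Both are faithful renderings of the stated criteria at reduced scale,
not tolerance adjustments; thresholds and replicate counts are as
specified.

## 10. Known limitations

* NJ is O(n³) in pure R; practical to ~1,000 leaves, beyond the
  package's intended panel sizes but not genome-scale.
* `exact` mode re-solves REML per marker and is meant for small panels
  and audits; P3D is the default, and the suite bounds their
  −log₁₀ p disagreement by 0.2 on simulated panels.
* The sphericity index and knee rule are conventions; retained sizes
  from other software's internal definitions will differ, and
  reproducing specific published core sizes is explicitly not
  attempted.
* The PHYLIP square-matrix writer rejects labels containing whitespace
  rather than quoting them.
* Genotype-likelihood (GL/PL) fields, BCF/indexed access, imputation,
  haplotype-phase LD, and multi-locus or Bayesian association models
  are out of scope.
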