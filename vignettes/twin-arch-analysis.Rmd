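---
title: "Twin variance-component analysis of dental arch traits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin variance-component analysis of dental arch traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinarch)
```

This vignette documents the statistical model behind `twinarch`, the
geometric conventions used to turn 3D dental-model landmarks into arch
traits, the design of the synthetic twin-data generator, and the numerical
choices made where the methodology left genuine freedom. It is the place
to look when deciding whether a default is appropriate for your data.

## The classical twin model

A quantitative trait measured on twin pairs is decomposed into latent
sources of variance: additive genetic effects (A), non-additive genetic
effects such as dominance (D), environment shared by co-twins (C), and
environment unique to each twin (E), which also absorbs measurement
error. With path coefficients $a, c, d, e$ (mm) the phenotypic variance is
$a^2 + c^2 + d^2 + e^2$, and the biology of twinning fixes the cross-twin
correlations of the latent factors: 1 in MZ pairs and 0.5 in DZ pairs for
A, 1 and 0.25 for D, 1 and 1 for C, 0 for E. Hence the model-implied
cross-twin covariances

$$\operatorname{cov}_{MZ} = a^2 + c^2 + d^2, \qquad
  \operatorname{cov}_{DZ} = \tfrac12 a^2 + c^2 + \tfrac14 d^2 .$$

C and D are confounded in twins reared together (both are identified only
through the contrast of the two covariances above), so ACE and ADE
families are fitted separately — `twin_model_spec()` refuses models
containing both. Every model contains E: a likelihood with zero
unique-environment variance is degenerate.

**Sex limitation.** With five zygosity-by-sex groups (MZ female, MZ male,
DZ female, DZ male, DZ opposite-sex) the model can let variance components
differ by sex (*quantitative* differences: per-sex paths $a_f, a_m,
\dots$) and, using the opposite-sex pairs, let the cross-twin correlation
itself depart from its default (*qualitative* differences). The
opposite-sex covariance is $r_A a_m a_f + r_C c_m c_f + r_D d_m d_f$ with
defaults $r_A = 0.5$, $r_C = 1$, $r_D = 0.25$. A full sex-limitation model
cannot free $r_A$ and $r_C$ simultaneously — they trade off one against
the other in a single statistic — so the package frees $r_A$ (bounded in
$[0, 0.5]$) with $r_C$ fixed at 1 by default; `qual_free = "rC"` (or
`"rD"` for ADE) selects the alternative identification. Means are
estimated per sex and equated across zygosity and twin order; the package
does not test mean structures.

**Assumptions inherited from the design**: random mating, equal shared
environments for MZ and DZ pairs, no gene–environment correlation or
interaction, bivariate normality within groups, and pairs missing a
co-twin are dropped rather than modelled (no raw-data FIML).

## Estimation

`fit_twin_model()` maximizes the sum over groups of bivariate-normal
log-likelihoods evaluated from per-group sufficient statistics (counts,
sums, squares, cross-products), so the cost of a likelihood evaluation is
independent of the number of pairs. Parameters are optimized
unconstrained: variances enter as squares of real path coefficients, which
enforces non-negativity without constraints (the sign of a path is not
identified and estimates are reported as magnitudes); the freed
qualitative correlation is mapped to its admissible interval by a scaled
logistic. Optimization is BFGS with `reltol = 1e-12`, at most 2000
iterations, and 5 seeded starts by default: the first start is a
Falconer-style method-of-moments point ($a^2_0 = 2(r_{MZ} - r_{DZ})$ and
its analogues, clipped into the simplex with an E floor of 0.05 so every
start has a full-rank covariance), the rest are multiplicative jitters of
it. The best likelihood wins; the fit records per-start values, the
central-difference gradient norm at the optimum, and a boundary flag when
a share collapses to ~0. A covariance that loses positive-definiteness
during search is penalized rather than inverted.

**Confidence intervals.** `profile_ci()` reports likelihood-based
intervals for standardized shares: the set of values whose profile
log-likelihood lies within $\chi^2_1(0.95)/2 = 1.92$ of the maximum. For
profiling, the model is reparameterized per sex block as (log total
variance, stick-broken shares) so one share can be pinned while the rest
stay on the simplex; the boundary is found by `uniroot` bisection on each
side (tolerance $10^{-5}$ on the share scale) and truncated to $[0, 1]$.
If the constrained optimization fails, a pair-resampling bootstrap
percentile interval (200 refits) is substituted and labelled as such in
the output.

**Model selection.** `select_model()` is deterministic given a seed:
first the sex-structure ladder (qualitative → quantitative → none) is
descended per family with likelihood-ratio tests, keeping the simpler
structure unless it loses fit at p < .05; then within the accepted
structure components are dropped (ACE→AE, ACE→CE, ADE→AE, ADE→DE, →E)
under the same parsimony rule; the non-nested survivors are compared by
smallest AIC ($-2\ln L + 2k$), ties broken toward fewer parameters. Tests
of a variance component against its boundary at zero are referred to the
naive $\chi^2$ distribution, which is conservative; this matches common
twin-study practice and is stated in the selection trace. The trace
records every fit (logLik, k, AIC) and every test (chi-square, df, p,
decision). Narrow-sense heritability is the standardized A of the winning
model — identically 0 when the winner has no A component, which is a
statement about the best-fitting decomposition, not an estimate that
additive variance is absent.

## Trait geometry

Landmarks use a functional controlled vocabulary
(`landmark_vocabulary()`): the same name denotes the stage-appropriate
tooth (second primary molar in the primary dentition, first permanent
molar later), which keeps trait code free of tooth numbering.

Intra-arch traits are computed in full 3D: intercanine and intermolar
widths as Euclidean distances between cusp tips, arch length as the
perpendicular distance from the incisal midpoint to the infinite line
through the distal contact points. The occlusal plane is reserved for
inter-arch measures only. Three conventions had to be fixed where the
measurement definitions leave freedom:

- **Incisal reference point** for overjet/overbite: the midpoint of the
  two central-incisor mesial incisal landmarks of each arch. Any
  single-incisor choice would make the measures sensitive to which
  incisor is more protruded; the midpoint is symmetric and uses only
  landmarks already required for the occlusal plane and arch length.
- **Plane normal orientation**: toward the mandibular arch (decided by the
  sign of the mandibular landmark centroid along the normal), so normal
  vertical incisor overlap yields positive overbite and an open bite a
  negative value. Without a mandibular set the sign is fixed
  deterministically from the largest normal component.
- **Anteroposterior axis**: the in-plane unit vector from the molar-cusp
  midpoint toward the incisal midpoint, one global axis for both sides'
  molar relationships. A per-side axis would make left and right
  relationships incommensurable under arch asymmetry. Overjet is the
  signed AP component of (maxillary − mandibular) incisal reference after
  in-plane projection; molar relationship the same for the molar
  references, so a mandibular landmark distal to its maxillary reference
  is positive (distocclusion).

Degenerate inputs error early and by name: a missing landmark names
itself, coincident distal contacts make the arch-length line undefined,
collinear defining points make the plane undefined. `extract_all_traits()`
downgrades these errors to `NA` traits with warnings so one damaged model
does not abort a cohort.

## The synthetic-data generator

`simulate_twin_pairs()` realises the path model literally: each latent
factor is an independent standard Gaussian pair with the prescribed
cross-twin correlation (1/0.5 for A, 1/0.25 for D, 1/1 for C, 0 for E;
opposite-sex pairs use $r_A, r_C, r_D$), scaled by the per-sex path
coefficients and added to the per-sex mean. This makes the implied
covariance algebra auditable in the generator itself rather than hidden in
a Cholesky factor. Opposite-sex pairs are stored female-first throughout
the package.

Defaults are calibrated to the motivating cohort's primary-dentition
maxillary intercanine width: 90 MZ and 98 DZ pairs (split 45/45 MZ and
33/32/33 DZ same-sex/opposite-sex, since only zygosity totals are
reported), female/male means 28.0/29.1 mm with SDs 2.0/1.9 mm, an AE
structure with $a^2 = 0.85$, and a measurement-error SD of 0.2 mm for
reliability replicates (mid-range of the reported intra-examiner Dahlberg
errors, 0.10–0.33 mm). Stages are generated independently, matching an
analysis that models each dentition stage separately.

`simulate_landmarks()` inverts the trait map: it builds a canonical arch
(maxillary occlusal plane at $z = 0$, anterior $+y$, normal toward the
mandible) in which nine traits are honoured by construction and the
mandibular distal-contact height is solved (closed form in the
mixed/permanent dentition, `uniroot` to $10^{-12}$ in the primary
dentition, where the molar relationship pins the contacts' AP positions)
so the mandibular arch length holds too. Trait targets that admit no such
arch — a mandibular arch length shorter than the incisor–molar separation
implied by the other traits — raise an informative error rather than a
distorted arch. An optional seed jitters only nuisance coordinates that no
trait depends on.

**What the generator does not emulate.** Real cohorts have attrition with
possible selection, non-normal and floor-bounded traits (overjet and molar
relationships in particular), age variation within stage, cross-stage
within-child correlation, and digitization error correlated across
landmarks. Passing tests on generator data therefore validate the
estimators under the model's own assumptions — correctness of the
likelihood, the selection procedure and the interval coverage — not
robustness to violations of those assumptions in real data.

## Reliability and descriptive statistics

`icc_agreement()` implements the two-way absolute-agreement single-measure
coefficient ICC(A,1) from the McGraw–Wong formulation,
$(MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$ with
$k = 2$ occasions; absolute agreement (rather than consistency) is the
variant that penalizes a systematic offset between sessions or examiners.
Negative estimates are returned as computed, with a warning, rather than
truncated. `dahlberg()` is $\sqrt{\sum d_i^2 / 2n}$, the classical
random-error estimate for paired repeats; ICC is computed per trait, not
pooled. `twin_icc()` is the distinct one-way pair-resemblance coefficient
$(MS_B - MS_W)/(MS_B + MS_W)$, bootstrapped by resampling pairs (1000
seeded replicates by default) to support ridge-style density displays of
MZ/DZ separation.

Descriptive choices: sample SDs use the $n-1$ denominator; the Bonferroni
family size defaults to $m = 20$ (ten traits by two contrasts per stage),
giving the per-test threshold $0.05/20 = 0.0025$; the family-clustered
comparison is a Gaussian mixed model with a random family intercept fitted
by ML through `lme4`, with a Wald z test on the group coefficient and no
small-sample correction; the unclustered comparison (for attrition-style
checks on unrelated groups) is Welch's t-test, preferred to the
pooled-variance test because group variances are not assumed equal.
Outlier flagging uses $|z| \ge 3$ — roughly 0.27% of a normal sample —
and reports rather than removes; Shapiro–Wilk is delegated to
`stats::shapiro.test()` (reproducibly subsampled above its n = 5000
limit) and is informational only: analyses proceed untransformed.

## Problem sizes used in validation

The test suite validates estimators at the cohort's own scales: heritability
recovery uses 200 replicates of 69 MZ + 65 DZ pairs (the permanent-dentition
sample), profile-interval coverage uses 500 replicates at 90 MZ + 98 DZ
pairs (the primary-dentition sample), and selection consistency uses 100
replicates of 5000 pairs per scenario, where the generating structure
(CE with $c^2 = 0.5$, or AE with $a^2 = 0.5$) should be recovered almost
always. Oracle checks compare the ICC implementations against independent
`aov()`-based ANOVA decompositions on hundreds of random small tables, and
all geometry is checked for invariance under random rigid motions.

## Known limitations

- No multivariate (cross-trait or cross-stage) models; each trait × stage
  cell is analysed separately, so longitudinal covariance is ignored.
- No raw-data FIML: incomplete pairs are dropped.
- Boundary LRT p-values use the naive $\chi^2$ reference (conservative).
- The DE model is fittable for comparison but dominance without additive
  variance is biologically implausible and should be interpreted as a
  descriptive fit, not a mechanism.
- Mesh processing, landmark digitization and zygosity determination are
  upstream of this package: it starts from landmark coordinates or trait
  tables.
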