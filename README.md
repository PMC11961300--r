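# twinarch

Variance-component analysis of dental-arch development in twins.

`twinarch` supports longitudinal twin studies of dental-arch morphology —
the kind of study that digitizes landmarks on 3D dental models of
monozygotic (MZ) and dizygotic (DZ) twin pairs across the primary, mixed
and permanent dentitions and asks how much of the phenotypic variance of
each arch trait is genetic. It provides, as a single pipeline or as
standalone functions:

- **Trait geometry** — the ten standard arch traits from named 3D landmark
  coordinates (mm): maxillary/mandibular intercanine width, intermolar
  width and arch length; and, referred to the maxillary occlusal plane,
  overjet, overbite and right/left molar relationship (signed: positive =
  distocclusion, negative = mesiocclusion).
- **Examiner reliability** — two-way absolute-agreement single-measure
  intraclass correlation, ICC(A,1), and Dahlberg's random error
  `sqrt(Σd²/2n)` on paired repeat measurements.
- **Descriptives** — means/SDs by zygosity and sex, Bonferroni-corrected
  contrasts (default family of 20 comparisons per stage, so α = 0.05 maps
  to a per-test threshold of 0.0025), family-clustered mixed-model
  comparisons, z-score outlier flags, Shapiro–Wilk checks.
- **The twin-model engine** — a from-scratch maximum-likelihood
  implementation of the classical twin design. Each zygosity-by-sex group
  contributes a bivariate-normal likelihood whose cross-twin covariance is
  model-implied: with path coefficients a, c, d, e (so variances a², c²,
  d², e²),

  | group | cross-twin covariance |
  |---|---|
  | MZ | a² + c² + d² |
  | same-sex DZ | ½a² + c² + ¼d² |
  | opposite-sex DZ | rA·am·af + rC·cm·cf + rD·dm·df |

  with rA = 0.5, rC = 1, rD = 0.25 by default; the full sex-limitation
  model frees per-sex components (quantitative differences) and one
  opposite-sex correlation (qualitative differences). C and D are
  confounded in twins reared together and are fitted in separate (ACE vs
  ADE) families. Model selection walks the sex-structure ladder and the
  component drops by likelihood-ratio tests under the parsimony rule
  (keep the simpler model unless p < .05) and compares non-nested
  survivors by AIC. Narrow-sense heritability is the standardized A share,
  h² = a²/(a²+c²+d²+e²), with profile-likelihood 95% confidence intervals.
- **A calibrated twin simulator** — bivariate-normal pairs built from
  independent Gaussian latent factors with the classical cross-twin
  correlations, plus a landmark constructor that inverts the trait map so
  geometry, reliability and modelling can all be exercised end to end
  without cohort data.

## Worked example

Simulate a primary-dentition cohort at the default calibration (90 MZ and
98 DZ pairs; maxillary intercanine width with female/male means 28.0/29.1
mm, SDs 2.0/1.9 mm; an AE structure with heritability 0.85), then run the
twin analysis:

```r
library(twinarch)

cfg   <- twin_sim_config(seed = 2026)
pairs <- simulate_twin_pairs(cfg)
gd    <- grouped_twin_data(pairs)

twin_icc(gd, "MZ", nboot = 1000, seed = 1)
#> MZ twin ICC = 0.871 (90 pairs; bootstrap 2.5%-97.5%: 0.821-0.907)
twin_icc(gd, "DZ", nboot = 1000, seed = 1)
#> DZ twin ICC = 0.525 (98 pairs; bootstrap 2.5%-97.5%: 0.364-0.642)

sel <- select_model(gd, seed = 1)
sel$best
#> <twin_fit> AE model (sex structure: none) on maxillary_intercanine_width
#>   logLik -692.363, k = 4, AIC 1392.726
#>   F: A = 0.857, E = 0.143 (h2 = 0.857)
#>   M: A = 0.857, E = 0.143 (h2 = 0.857)

twin_fit_table(sel)
#>   model sex component  estimate     lower     upper  method        h2
#> 1    AE   P         A 0.8570901 0.8021589 0.8956746 profile 0.8570901
#> 2    AE   P         E 0.1429099 0.1043254 0.1978411 profile 0.8570901
```

Reading the output: the MZ pair resemblance (ICC 0.87) is far above the DZ
resemblance (0.53), the parsimony/AIC procedure settles on an AE model
with no sex differences, and the additive-genetic share — the narrow-sense
heritability — is estimated at 0.86 (95% profile CI 0.80–0.90), recovering
the generating value of 0.85 at this sample size.

The same stages run from a config file (YAML or list) through
`run_pipeline()`, or from a shell via the thin CLI in `inst/exec/twinarch`
(subcommands `simulate`, `traits`, `describe`, `reliability`, `twin-fit`,
`run-all`).

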