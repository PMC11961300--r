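Package: twinarch
Title: Twin Variance-Component Analysis of Dental Arch Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for longitudinal twin studies of dental arch morphology:
    computation of intra- and inter-arch traits (intercanine and intermolar
    widths, arch lengths, overjet, overbite, molar relationships) from 3D
    landmark coordinates digitized on dental models, including occlusal-plane
    construction; examiner reliability statistics (two-way absolute-agreement
    single-measure intraclass correlation and Dahlberg's random error);
    group descriptives with Bonferroni-corrected and family-clustered
    comparisons; a maximum-likelihood engine for classical twin
    variance-component models (ACE/ADE families with quantitative and
    qualitative sex-limitation), likelihood-ratio and AIC model selection,
    profile-likelihood confidence intervals and narrow-sense heritability;
    and a calibrated bivariate-normal twin-pair simulator for validation
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
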