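## Group descriptives and comparisons: per-group means/SDs, Bonferroni
## threshold arithmetic, family-clustered and independent-sample group
## comparisons, z-score outlier flagging and Shapiro-Wilk normality checks.

#' Expand a twin-pair data frame to one row per individual
#'
#' @param pairs A `twin_pairs` data frame.
#' @return Long-format data frame with columns `family_id`, `twin`,
#'   `zygosity`, `sex`, `stage`, `trait`, `value`.
#' @export
pairs_to_long <- function(pairs) {
  rbind(
    data.frame(family_id = pairs$family_id, twin = 1L, zygosity = pairs$zygosity,
               sex = pairs$sex1, stage = pairs$stage, trait = pairs$trait,
               value = pairs$value1, stringsAsFactors = FALSE),
    data.frame(family_id = pairs$family_id, twin = 2L, zygosity = pairs$zygosity,
               sex = pairs$sex2, stage = pairs$stage, trait = pairs$trait,
               value = pairs$value2, stringsAsFactors = FALSE)
  )
}

#' Group means and standard deviations
#'
#' Per trait and stage, computes mean, sample SD (n - 1 denominator) and n
#' for the overall sample and the MZ, DZ, male and female subgroups.
#'
#' @param traits Long-format data frame with columns `trait`, `stage`,
#'   `value` and (for the subgroup rows) `zygosity` and `sex`, e.g. from
#'   [pairs_to_long()]; a `twin_pairs` data frame is accepted and expanded.
#' @return Data frame with columns `trait`, `stage`, `group`, `mean`, `sd`,
#'   `n`.
#' @export
summarize_traits <- function(traits) {
  if (inherits(traits, "twin_pairs")) traits <- pairs_to_long(traits)
  stopifnot(all(c("trait", "stage", "value") %in% names(traits)))
  groups <- list(
    overall = function(d) rep(TRUE, nrow(d)),
    MZ = function(d) d$zygosity == "MZ",
    DZ = function(d) d$zygosity == "DZ",
    male = function(d) d$sex == "M",
    female = function(d) d$sex == "F"
  )
  if (is.null(traits$zygosity)) groups <- groups["overall"]
  out <- do.call(rbind, lapply(
    split(traits, list(traits$trait, traits$stage), drop = TRUE),
    function(d) {
      do.call(rbind, lapply(names(groups), function(g) {
        v <- d$value[groups[[g]](d)]
        v <- v[!is.na(v)]
        if (!length(v)) return(NULL)
        data.frame(trait = d$trait[1], stage = d$stage[1], group = g,
                   mean = mean(v), sd = sd(v), n = length(v),
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected per-comparison significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of comparisons in the family (default 20: ten traits by
#'   two contrasts per dentition stage).
#' @return Per-comparison alpha, `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 20) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Compare trait means between twin groups
#'
#' Tests the MZ-vs-DZ or male-vs-female mean difference for one trait. With
#' `clustered = TRUE`, a Gaussian linear mixed model with a random family
#' intercept (compound-symmetry covariance within families) is fitted by
#' maximum likelihood and the group coefficient tested by a Wald z test,
#' accounting for the clustering of twins within families. With
#' `clustered = FALSE`, a Welch two-sample t-test is used (appropriate for
#' comparisons of unrelated groups such as an attrition check).
#'
#' @param traits Long-format data frame (or `twin_pairs`) with columns
#'   `value`, `family_id` and `zygosity`/`sex`.
#' @param contrast `"MZ_vs_DZ"` or `"M_vs_F"`.
#' @param clustered Account for family clustering (default `TRUE`).
#' @return List with `estimate` (mean difference, first group minus second),
#'   `statistic`, `p_value`, `method`, and for clustered fits `logLik` and
#'   `logLik_no_cluster`.
#' @export
group_compare <- function(traits, contrast = c("MZ_vs_DZ", "M_vs_F"),
                          clustered = TRUE) {
  contrast <- match.arg(contrast)
  if (inherits(traits, "twin_pairs")) traits <- pairs_to_long(traits)
  g <- if (contrast == "MZ_vs_DZ") factor(traits$zygosity, c("DZ", "MZ"))
       else factor(traits$sex, c("F", "M"))
  ok <- !is.na(traits$value) & !is.na(g)
  d <- data.frame(value = traits$value[ok], g = g[ok],
                  family_id = traits$family_id[ok])
  if (min(table(d$g)) < 2L) stop("each group needs at least 2 observations")
  if (clustered) {
    fit <- lme4::lmer(value ~ g + (1 | family_id), data = d, REML = FALSE)
    est <- lme4::fixef(fit)[[2]]
    se <- sqrt(vcov(fit)[2, 2])
    z <- est / se
    list(estimate = est, statistic = z, p_value = 2 * pnorm(-abs(z)),
         method = "mixed-model Wald z (random family intercept, ML)",
         logLik = as.numeric(logLik(fit)),
         logLik_no_cluster = as.numeric(logLik(lm(value ~ g, data = d))))
  } else {
    tt <- t.test(value ~ g, data = d)
    ## report second-level minus first-level mean, like the model coefficient
    list(estimate = diff(tt$estimate)[[1]], statistic = -tt$statistic[[1]],
         p_value = tt$p.value, method = "Welch two-sample t-test")
  }
}

#' Flag frank outliers by z-score
#'
#' Flags values whose absolute z-score meets or exceeds `threshold`
#' (default 3). Flagged values are reported, never removed.
#'
#' @param values Numeric vector.
#' @param threshold Absolute z-score cutoff.
#' @return Logical vector, `TRUE` for flagged values (`NA` values are never
#'   flagged). A constant vector flags nothing.
#' @export
flag_outliers <- function(values, threshold = 3) {
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  z <- (values - mean(values, na.rm = TRUE)) / s
  out <- abs(z) >= threshold
  out[is.na(out)] <- FALSE
  out
}

#' Shapiro-Wilk normality check
#'
#' Delegates to [stats::shapiro.test()]. The result is informational: the
#' downstream analyses proceed regardless of the outcome. Vectors longer
#' than 5000 (the test's limit) are subsampled reproducibly.
#'
#' @param values Numeric vector (3 to 5000 finite values used).
#' @return List with `statistic`, `p_value` and `n_used`.
#' @export
normality_check <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) > 5000L) {
    v <- withr::with_seed(1L, sample(v, 5000L))
  }
  sw <- shapiro.test(v)
  list(statistic = unname(sw$statistic), p_value = sw$p.value, n_used = length(v))
}

#' Table of group comparisons for every trait and stage
#'
#' Runs [summarize_traits()] and both [group_compare()] contrasts per trait
#' and stage, flagging significance at the Bonferroni-corrected threshold.
#'
#' @param traits Long-format trait data frame or `twin_pairs`.
#' @param alpha Family-wise alpha (default 0.05).
#' @param m Bonferroni family size (default 20).
#' @param clustered Use the family-clustered comparison (default `TRUE`).
#' @return Data frame with one row per trait/stage: group means/SDs and the
#'   two contrast p-values with significance flags.
#' @export
describe_traits <- function(traits, alpha = 0.05, m = 20, clustered = TRUE) {
  if (inherits(traits, "twin_pairs")) traits <- pairs_to_long(traits)
  thr <- bonferroni_threshold(alpha, m)
  summ <- summarize_traits(traits)
  cells <- split(traits, list(traits$trait, traits$stage), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    s <- summ[summ$trait == d$trait[1] & summ$stage == d$stage[1], ]
    gv <- function(g, col) {
      i <- match(g, s$group)
      if (is.na(i)) NA_real_ else s[[col]][i]
    }
    p_zyg <- tryCatch(group_compare(d, "MZ_vs_DZ", clustered)$p_value,
                      error = function(e) NA_real_)
    p_sex <- tryCatch(group_compare(d, "M_vs_F", clustered)$p_value,
                      error = function(e) NA_real_)
    data.frame(
      trait = d$trait[1], stage = d$stage[1],
      mean_overall = gv("overall", "mean"), sd_overall = gv("overall", "sd"),
      mean_MZ = gv("MZ", "mean"), sd_MZ = gv("MZ", "sd"),
      mean_DZ = gv("DZ", "mean"), sd_DZ = gv("DZ", "sd"),
      mean_male = gv("male", "mean"), sd_male = gv("male", "sd"),
      mean_female = gv("female", "mean"), sd_female = gv("female", "sd"),
      p_MZ_vs_DZ = p_zyg, sig_MZ_vs_DZ = !is.na(p_zyg) & p_zyg < thr,
      p_M_vs_F = p_sex, sig_M_vs_F = !is.na(p_sex) & p_sex < thr,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  out
}
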