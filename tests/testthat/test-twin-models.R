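## The ML twin-model engine: expected covariances, twin ICC, fitting,
## profile intervals, likelihood-ratio tests and model selection.

test_that("model-implied covariances reproduce the classical twin expectations", {
  expect_equal(expected_cov("MZ", a2 = 1)[1, 2], 1)
  expect_equal(expected_cov("DZ", a2 = 1)[1, 2], 0.5)
  expect_equal(expected_cov("DZ", d2 = 1)[1, 2], 0.25)
  expect_equal(expected_cov("MZ", c2 = 1)[1, 2], 1)
  expect_equal(expected_cov("DZ", c2 = 1)[1, 2], 1)
  for (g in c("MZ", "DZ", "DZOS")) {
    expect_equal(expected_cov(g, e2 = 1)[1, 2], 0)
  }
  ## opposite-sex default weights: rA = 0.5, rC = 1
  s <- expected_cov("DZOS", a2 = c(F = 0.4, M = 0.6), c2 = c(F = 0.2, M = 0.1),
                    e2 = c(F = 0.4, M = 0.3))
  expect_equal(s[1, 1], 1)
  expect_equal(s[2, 2], 1)
  expect_equal(s[1, 2], 0.5 * sqrt(0.4 * 0.6) + sqrt(0.2 * 0.1))

  ## symmetric PSD, and MZ off-diagonal >= same-sex DZ when a2 + d2 > 0
  withr::with_seed(51, for (i in 1:50) {
    sh <- diff(c(0, sort(runif(2)), 1))  # random 3-simplex point
    mz <- expected_cov("MZ", a2 = sh[1], c2 = sh[2], e2 = sh[3])
    dz <- expected_cov("DZ", a2 = sh[1], c2 = sh[2], e2 = sh[3])
    expect_equal(mz, t(mz))
    expect_gte(min(eigen(mz, symmetric = TRUE)$values), -1e-12)
    if (sh[1] > 0) expect_gt(mz[1, 2], dz[1, 2]) else expect_equal(mz[1, 2], dz[1, 2])
  })
})

test_that("twin ICC matches a hand/brute-force one-way ANOVA oracle", {
  x <- cbind(c(27.1, 28.4, 30.2, 26.5, 29.0, 31.3),
             c(27.8, 28.0, 30.9, 27.2, 28.1, 30.6))
  gd <- grouped_twin_data(list(MZ = x))
  expect_equal(twin_icc(gd, "MZ", nboot = 0)$estimate, oracle_pair_icc(x),
               tolerance = 1e-12)

  ## perfect resemblance
  y <- cbind(1:5, 1:5)
  expect_equal(twin_icc(grouped_twin_data(list(MZ = y)), "MZ", nboot = 0)$estimate, 1)

  ## 500 random small tables against the oracle
  withr::with_seed(52, for (i in 1:500) {
    n <- sample(4:15, 1)
    z <- rnorm(n)
    m <- cbind(z + rnorm(n, sd = 0.7), z + rnorm(n, sd = 0.7))
    gd <- grouped_twin_data(list(DZ = m))
    expect_equal(twin_icc(gd, "DZ", nboot = 0)$estimate, oracle_pair_icc(m),
                 tolerance = 1e-10)
  })
})

test_that("pure-additive DZ pairs give twin ICC near 0.5 and bootstrap is centred", {
  cfg <- twin_sim_config(n_pairs = c(DZF = 50000), mean = 0, var = 1,
                         a2 = 1, e2 = 0, seed = 53)
  gd <- grouped_twin_data(simulate_twin_pairs(cfg))
  ti <- twin_icc(gd, "DZ", nboot = 200, seed = 5)
  expect_equal(ti$estimate, 0.5, tolerance = 4 / sqrt(50000))
  ## bootstrap mean within 2 bootstrap SEs of the point estimate
  expect_lt(abs(mean(ti$boot) - ti$estimate), 2 * sd(ti$boot))
})

test_that("model spec validation enforces E and the C/D confound", {
  expect_error(twin_model_spec(c("A", "C")), "E must be included")
  expect_error(twin_model_spec(c("A", "C", "D", "E")), "confounded")
  expect_identical(model_label(twin_model_spec(c("E", "A"))), "AE")
})

test_that("ML fitting recovers structure and respects MLE dominance", {
  gd <- sim_gtd(a2 = 0.85, seed = 54)
  f <- fit_twin_model(gd, "AE", seed = 1)
  ## standardized shares sum to 1, h2 in [0, 1]
  expect_equal(colSums(f$shares[f$spec$components, , drop = FALSE]),
               setNames(1, colnames(f$shares)), tolerance = 1e-8)
  expect_true(all(f$h2 >= 0 & f$h2 <= 1))
  expect_equal(f$AIC, -2 * f$logLik + 2 * f$k)

  ## the fitted likelihood dominates the generating parameters
  tmpl <- twinarch:::.par_template(f$spec, gd)
  negll <- twinarch:::.negll_factory(gd, tmpl)
  truth <- c(28.5, sqrt(0.85 * 2.1^2), sqrt(0.15 * 2.1^2))
  expect_gte(f$logLik, -negll(truth) - 1e-6)

  ## independence limit: zero cross-twin covariance pushes A to 0
  gd0 <- sim_gtd(a2 = 0, seed = 55, n_mz = 2000, n_dz = 2000)
  f0 <- fit_twin_model(gd0, "AE", seed = 1)
  expect_lt(f0$shares["A", 1], 0.05)
  expect_gt(f0$shares["E", 1], 0.95)
})

test_that("fitting on data sampled from expected_cov recovers the matrices", {
  ## large-sample oracle equivalence: model-implied vs sample covariance
  cfg <- twin_sim_config(n_pairs = c(MZF = 40000, DZF = 40000), mean = 0, var = 1,
                         a2 = 0.6, c2 = 0.2, e2 = 0.2, seed = 56)
  p <- simulate_twin_pairs(cfg)
  gd <- grouped_twin_data(p)
  f <- fit_twin_model(gd, "ACE", seed = 1)
  for (g in c("MZF", "DZF")) {
    d <- p[p$group == g, ]
    emp <- cov(cbind(d$value1, d$value2))
    fitted <- twinarch:::.sigma_for_group(
      list(paths = f$paths, r = f$r), g)
    expect_equal(fitted, emp, tolerance = 0.03, ignore_attr = TRUE)
  }
  expect_equal(f$shares["A", 1], 0.6, tolerance = 0.05)
  expect_equal(f$shares["C", 1], 0.2, tolerance = 0.05)
})

test_that("log-likelihoods are monotone along the nesting chain ACE >= AE >= E", {
  for (seed in 57:59) {
    gd <- sim_gtd(a2 = 0.6, c2 = 0.15, seed = seed, n_mz = 60, n_dz = 60)
    ll <- vapply(c("ACE", "AE", "E"), function(m)
      fit_twin_model(gd, m, seed = 1)$logLik, numeric(1))
    expect_gte(ll[["ACE"]], ll[["AE"]] - 1e-6)
    expect_gte(ll[["AE"]], ll[["E"]] - 1e-6)
  }
})

test_that("likelihood-ratio test arithmetic matches the chi-square reference", {
  f1 <- structure(list(logLik = -100, k = 4), class = "twin_fit")
  f0 <- structure(list(logLik = -102.5, k = 3), class = "twin_fit")
  tt <- lrt(f1, f0)
  expect_equal(tt$chi2, 5)
  expect_equal(tt$df, 1)
  expect_equal(tt$p_value, 0.02535, tolerance = 1e-3)

  ## identical fits: chi2 0, p 1
  f0b <- structure(list(logLik = -100, k = 3), class = "twin_fit")
  tt0 <- lrt(f1, f0b)
  expect_equal(tt0$chi2, 0)
  expect_equal(tt0$p_value, 1)
  expect_error(lrt(f0, f1), "more free parameters")
})

test_that("boundary LRT of ACE vs AE under AE truth is conservative", {
  rej <- vapply(1:150, function(i) {
    gd <- sim_gtd(a2 = 0.7, seed = 600 + i, n_mz = 90, n_dz = 98)
    full <- fit_twin_model(gd, "ACE", starts = 2, seed = i)
    sub <- fit_twin_model(gd, "AE", starts = 2, seed = i)
    lrt(full, sub)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 150))
})

test_that("profile intervals contain the MLE and tighten with sample size", {
  gd_small <- sim_gtd(a2 = 0.7, seed = 61, n_mz = 100, n_dz = 100)
  gd_big <- sim_gtd(a2 = 0.7, seed = 61, n_mz = 1000, n_dz = 1000)
  f_small <- fit_twin_model(gd_small, "AE", seed = 1)
  f_big <- fit_twin_model(gd_big, "AE", seed = 1)
  ci_s <- profile_ci(f_small, "A")
  ci_b <- profile_ci(f_big, "A")
  expect_lte(ci_s$lower, f_small$shares["A", 1])
  expect_gte(ci_s$upper, f_small$shares["A", 1])
  expect_lt(ci_b$upper - ci_b$lower, ci_s$upper - ci_s$lower)
  expect_gte(ci_s$lower, 0)
  expect_lte(ci_s$upper, 1)
  ## complementary component: E interval mirrors the A interval in AE
  ci_e <- profile_ci(f_small, "E")
  expect_equal(ci_e$lower, 1 - ci_s$upper, tolerance = 1e-3)
  expect_equal(ci_e$upper, 1 - ci_s$lower, tolerance = 1e-3)
})

test_that("model selection is consistent for clear generating structures", {
  ## no familial resemblance: E wins
  gd <- sim_gtd(a2 = 0, seed = 62, n_mz = 400, n_dz = 400)
  sel <- select_model(gd, seed = 1)
  expect_identical(model_label(sel$best$spec), "E")

  ## strong additive structure at the primary-stage sample size: AE wins
  gd <- sim_gtd(a2 = 0.85, seed = 63)
  sel <- select_model(gd, seed = 1)
  expect_identical(model_label(sel$best$spec), "AE")
  expect_true(all(c("comparison", "chi2", "df", "p", "decision") %in%
                    names(sel$tests)))
  expect_true(nrow(sel$fits) >= 5)

  ## shared-environment structure: CE wins over AE by AIC
  gd <- sim_gtd(a2 = 0, c2 = 0.5, seed = 64, n_mz = 2000, n_dz = 2000)
  sel <- select_model(gd, seed = 1)
  expect_identical(model_label(sel$best$spec), "CE")
})

test_that("heritability is the standardized A share, zero without A", {
  gd <- sim_gtd(a2 = 0.8, seed = 65, n_mz = 3000, n_dz = 3000, mean = 0, var = 5)
  f <- fit_twin_model(gd, "AE", seed = 1)
  ## raw a2 ~ 4, e2 ~ 1 -> h2 ~ 0.8
  expect_equal(unname(f$variances["A", 1] / f$total_variance[[1]]),
               unname(heritability(f)[1]))
  expect_equal(unname(heritability(f)[1]), 0.8, tolerance = 0.03)

  ce <- fit_twin_model(sim_gtd(a2 = 0, c2 = 0.5, seed = 66), "CE", seed = 1)
  expect_equal(unname(heritability(ce)[1]), 0)
  eo <- fit_twin_model(sim_gtd(a2 = 0, seed = 67), "E", seed = 1)
  expect_equal(unname(heritability(eo)[1]), 0)
})

test_that("sex-limitation models detect quantitative heterogeneity when present", {
  ## different per-sex variance shares, same means: quantitative structure
  cfg <- twin_sim_config(
    n_pairs = c(MZF = 800, MZM = 800, DZF = 800, DZM = 800, DZOS = 800),
    mean = 0, var = 1, a2 = c(F = 0.8, M = 0.3), e2 = c(F = 0.2, M = 0.7),
    seed = 68)
  gd <- grouped_twin_data(simulate_twin_pairs(cfg))
  fq <- fit_twin_model(gd, twin_model_spec(c("A", "E"), "quantitative"), seed = 1)
  expect_equal(unname(fq$shares["A", "F"]), 0.8, tolerance = 0.07)
  expect_equal(unname(fq$shares["A", "M"]), 0.3, tolerance = 0.09)
  fn <- fit_twin_model(gd, twin_model_spec(c("A", "E"), "none"), seed = 1)
  expect_gt(lrt(fq, fn)$chi2, qchisq(0.95, fq$k - fn$k))

  sel <- select_model(gd, seed = 1)
  expect_true(sel$best$spec$sex %in% c("quantitative", "qualitative"))

  ## qualitative model recovers a reduced opposite-sex genetic correlation
  cfg2 <- twin_sim_config(
    n_pairs = c(MZF = 3000, MZM = 3000, DZF = 3000, DZM = 3000, DZOS = 3000),
    mean = 0, var = 1, a2 = 0.7, e2 = 0.3, rA = 0.15, seed = 69)
  gd2 <- grouped_twin_data(simulate_twin_pairs(cfg2))
  fqual <- fit_twin_model(gd2, twin_model_spec(c("A", "E"), "qualitative"), seed = 1)
  expect_lt(abs(fqual$r[["rA"]] - 0.15), 0.06)
})
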