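## Inference on fitted twin models: profile-likelihood confidence intervals
## for standardized variance components, likelihood-ratio tests between
## nested models, and the parsimony-driven model-selection procedure
## (sex-structure ladder, component drops, AIC among non-nested survivors).

## ---- share parameterization (used for profiling) --------------------------
## A model is re-expressed per sex block as (log total variance, stick-broken
## standardized shares); one share can be pinned to a fixed value so the
## likelihood can be profiled over it.

.share_layout <- function(spec, tmpl, fixed = NULL) {
  nE <- setdiff(spec$components, "E")
  blocks <- tmpl$path_sexes
  nz <- vapply(blocks, function(b) {
    if (!is.null(fixed) && identical(fixed$block, b)) length(nE) - 1L
    else length(nE)
  }, integer(1))
  list(nE = nE, blocks = blocks, nz = nz, fixed = fixed)
}

## shares for one block from its z parameters
.block_shares <- function(z, layout, block) {
  sh <- c(A = 0, C = 0, D = 0, E = 0)
  nE <- layout$nE
  fixed <- layout$fixed
  if (!is.null(fixed) && identical(fixed$block, block)) {
    if (fixed$comp == "E") {
      sh["E"] <- fixed$value
      mass <- 1 - fixed$value
      if (length(nE) > 1L) {
        for (i in seq_len(length(nE) - 1L)) {
          sh[nE[i]] <- mass * plogis(z[i])
          mass <- mass - sh[nE[i]]
        }
      }
      if (length(nE)) sh[nE[length(nE)]] <- mass
    } else {
      sh[fixed$comp] <- fixed$value
      mass <- 1 - fixed$value
      rest <- setdiff(nE, fixed$comp)
      for (i in seq_along(rest)) {
        sh[rest[i]] <- mass * plogis(z[i])
        mass <- mass - sh[rest[i]]
      }
      sh["E"] <- mass
    }
  } else {
    mass <- 1
    for (i in seq_along(nE)) {
      sh[nE[i]] <- mass * plogis(z[i])
      mass <- mass - sh[nE[i]]
    }
    sh["E"] <- mass
  }
  sh
}

## invert .block_shares for initialization from a fitted model's shares
.block_init_z <- function(shares, layout, block) {
  cl <- function(x) qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6))
  nE <- layout$nE
  fixed <- layout$fixed
  if (!is.null(fixed) && identical(fixed$block, block)) {
    if (fixed$comp == "E") {
      mass <- 1 - fixed$value
      tot <- sum(shares[nE])
      scale <- if (tot > 1e-12) mass / tot else 1
      z <- numeric(0)
      if (length(nE) > 1L) {
        for (i in seq_len(length(nE) - 1L)) {
          z <- c(z, cl(shares[nE[i]] * scale / mass))
          mass <- mass - shares[nE[i]] * scale
        }
      }
      z
    } else {
      rest <- setdiff(nE, fixed$comp)
      mass <- 1 - fixed$value
      tot <- sum(shares[rest]) + shares["E"]
      scale <- if (tot > 1e-12) mass / tot else 1
      z <- numeric(0)
      for (i in seq_along(rest)) {
        z <- c(z, cl(shares[rest[i]] * scale / mass))
        mass <- mass - shares[rest[i]] * scale
      }
      z
    }
  } else {
    mass <- 1
    z <- numeric(0)
    for (i in seq_along(nE)) {
      z <- c(z, cl(shares[nE[i]] / mass))
      mass <- mass - shares[nE[i]]
    }
    z
  }
}

## negative log-likelihood in the share parameterization
.share_negll_factory <- function(fit, fixed = NULL) {
  data <- fit$data
  spec <- fit$spec
  tmpl <- .par_template(spec, data)
  layout <- .share_layout(spec, tmpl, fixed)
  nmu <- length(tmpl$sexes)
  blocks <- layout$blocks
  base <- .negll_factory(data, tmpl)

  to_path_par <- function(par) {
    mu <- par[seq_len(nmu)]
    idx <- nmu
    out <- mu
    for (b in blocks) {
      logv <- par[idx + 1L]
      z <- if (layout$nz[[b]] > 0L) par[idx + 1L + seq_len(layout$nz[[b]])] else numeric(0)
      idx <- idx + 1L + layout$nz[[b]]
      sh <- .block_shares(z, layout, b)
      v <- exp(logv)
      out <- c(out, sqrt(sh[spec$components] * v))
    }
    if (spec$sex == "qualitative") out <- c(out, par[idx + 1L])
    out
  }
  list(
    fn = function(par) base(to_path_par(par)),
    init = function() {
      par <- unname(fit$mu[tmpl$sexes])
      for (b in blocks) {
        s <- if (b == "P") colnames(fit$shares)[1] else b
        par <- c(par, log(fit$total_variance[[s]]),
                 .block_init_z(fit$shares[, s], layout, b))
      }
      if (spec$sex == "qualitative") par <- c(par, fit$par[[spec$qual_free]])
      par
    }
  )
}

#' Profile-likelihood confidence interval for a standardized component
#'
#' The interval contains the standardized share values whose profile
#' log-likelihood lies within `qchisq(level, 1) / 2` (1.92 for 95%) of the
#' maximum, found by root bisection on each side of the estimate and
#' truncated to \[0, 1\]. If profiling fails numerically, a pair-resampling
#' bootstrap percentile interval is used instead (flagged in the result).
#'
#' @param fit A `twin_fit` from [fit_twin_model()].
#' @param component `"A"`, `"C"`, `"D"` or `"E"` (must be in the model).
#' @param level Confidence level (default 0.95).
#' @param sex For sex-structured fits, restrict to `"F"` or `"M"`; default
#'   computes every block.
#' @return Data frame with columns `component`, `sex`, `estimate`, `lower`,
#'   `upper`, `method`.
#' @export
profile_ci <- function(fit, component = "A", level = 0.95, sex = NULL) {
  stopifnot(inherits(fit, "twin_fit"))
  comp <- toupper(component)
  if (!comp %in% fit$spec$components) {
    stop(sprintf("component %s is not in the fitted %s model", comp,
                 model_label(fit$spec)))
  }
  tmpl <- .par_template(fit$spec, fit$data)
  blocks <- tmpl$path_sexes
  if (!is.null(sex)) blocks <- intersect(blocks, sex)
  if (!length(blocks)) stop("no matching sex block")
  out <- lapply(blocks, function(b) {
    s <- if (b == "P") colnames(fit$shares)[1] else b
    est <- fit$shares[comp, s]
    ci <- tryCatch(.profile_one(fit, comp, b, est, level),
                   error = function(e) NULL)
    if (is.null(ci)) {
      ci <- .boot_ci(fit, comp, s, level)
      method <- "bootstrap"
    } else {
      method <- "profile"
    }
    data.frame(component = comp, sex = b, estimate = est,
               lower = ci[1], upper = ci[2], method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.profile_one <- function(fit, comp, block, est, level) {
  q <- qchisq(level, 1) / 2
  pll <- function(s) {
    sf <- .share_negll_factory(fit, fixed = list(comp = comp, block = block,
                                                 value = s))
    p0 <- sf$init()
    opt <- optim(p0, sf$fn, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-11))
    ## polish with Nelder-Mead if BFGS stalled
    if (opt$convergence != 0) {
      opt <- optim(opt$par, sf$fn, control = list(maxit = 2000, reltol = 1e-11))
    }
    -opt$value
  }
  f <- function(s) fit$logLik - pll(s) - q
  eps <- 1e-6
  lower <- if (est <= eps) 0 else {
    flo <- f(eps)
    if (flo <= 0) 0 else uniroot(f, c(eps, max(est, 2 * eps)), tol = 1e-5)$root
  }
  upper <- if (est >= 1 - eps) 1 else {
    fhi <- f(1 - eps)
    if (fhi <= 0) 1 else uniroot(f, c(min(est, 1 - 2 * eps), 1 - eps), tol = 1e-5)$root
  }
  c(max(0, lower), min(1, upper))
}

## Bootstrap percentile fallback: resample pairs within groups, refit.
.boot_ci <- function(fit, comp, s, level, B = 200L) {
  reps <- withr::with_seed(fit$seed + 1L, vapply(seq_len(B), function(i) {
    groups <- lapply(fit$data$groups, function(m) {
      m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]
    })
    gd <- grouped_twin_data(groups, trait = fit$data$trait, stage = fit$data$stage)
    f <- tryCatch(fit_twin_model(gd, fit$spec, starts = 2L, seed = i),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$shares[comp, s]
  }, numeric(1)))
  unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE))
}

#' Likelihood-ratio test between nested twin models
#'
#' `chi2 = 2 (lnL_full - lnL_sub)` referred to a chi-square distribution
#' with `df = k_full - k_sub`. For tests of a variance component against its
#' boundary at zero the naive chi-square reference is conservative; p-values
#' are reported from it regardless, matching common twin-study practice.
#'
#' @param full,sub `twin_fit` objects; `sub` must be nested in `full`.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
lrt <- function(full, sub) {
  stopifnot(inherits(full, "twin_fit"), inherits(sub, "twin_fit"))
  if (full$k <= sub$k) stop("`full` must have more free parameters than `sub`")
  if (full$logLik < sub$logLik - 1e-4) {
    warning(sprintf("full-model logLik (%.6f) below sub-model (%.6f): optimization issue?",
                    full$logLik, sub$logLik))
  }
  chi2 <- max(0, 2 * (full$logLik - sub$logLik))
  df <- full$k - sub$k
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

## ---- model selection ------------------------------------------------------

#' Select the best-fitting twin model by parsimony and AIC
#'
#' Deterministic procedure: (1) for each family (ACE and ADE) fit the
#' qualitative sex-limitation, quantitative-only and no-sex-difference
#' variants (as the data allow) and walk down the sex-structure ladder,
#' keeping the simpler structure unless it loses fit significantly
#' (LRT p < `alpha`); (2) within the accepted structure, drop components
#' (ACE to AE/CE, ADE to AE/DE, then to E), a sub-model surviving when the
#' LRT against its parent is non-significant; (3) compare the non-nested
#' survivors by smallest AIC.
#'
#' @param data A [grouped_twin_data()] object.
#' @param starts,seed Passed to [fit_twin_model()].
#' @param alpha LRT significance level for the parsimony rule (default
#'   0.05).
#' @param qual_free Opposite-sex correlation freed by qualitative models
#'   (see [twin_model_spec()]).
#' @return Object of class `twin_selection`: `best` (the winning
#'   `twin_fit`), `fits` (table of every model fitted: label, sex
#'   structure, logLik, k, AIC), `tests` (every LRT: comparison, chi2, df,
#'   p, decision) and `candidates` (the AIC-compared survivors).
#' @export
select_model <- function(data, starts = 5L, seed = 1L, alpha = 0.05,
                         qual_free = "rA") {
  stopifnot(inherits(data, "grouped_twin_data"))
  gn <- names(data$groups)
  has_f <- any(gn %in% c("MZF", "DZF", "DZOS"))
  has_m <- any(gn %in% c("MZM", "DZM", "DZOS"))
  sexed <- data$sexed && has_f && has_m
  has_os <- "DZOS" %in% gn
  cache <- new.env(parent = emptyenv())
  fits_log <- list()
  fitf <- function(comps, sexstr) {
    ## a freed correlation needs its component present; degrade gracefully
    if (sexstr == "qualitative") {
      qf <- qual_free
      need <- c(rA = "A", rC = "C", rD = "D")[[qf]]
      if (!need %in% comps) {
        qf <- if ("A" %in% comps) "rA" else if ("C" %in% comps) "rC"
              else if ("D" %in% comps) "rD" else NA
        if (is.na(qf)) sexstr <- "quantitative"
      }
      if (sexstr == "qualitative") {
        key <- paste(paste(comps, collapse = ""), sexstr, qf)
        if (!is.null(cache[[key]])) return(cache[[key]])
        f <- fit_twin_model(data, twin_model_spec(comps, sexstr, qf),
                            starts = starts, seed = seed)
        cache[[key]] <- f
        fits_log[[key]] <<- f
        return(f)
      }
    }
    key <- paste(paste(comps, collapse = ""), sexstr)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fit_twin_model(data, twin_model_spec(comps, sexstr),
                        starts = starts, seed = seed)
    cache[[key]] <- f
    fits_log[[key]] <<- f
    f
  }
  tests <- list()
  note_test <- function(label, tt, keep) {
    tests[[length(tests) + 1L]] <<- data.frame(
      comparison = label, chi2 = tt$chi2, df = tt$df, p = tt$p_value,
      decision = keep, stringsAsFactors = FALSE)
  }
  structures <- "none"
  if (sexed) structures <- c("quantitative", structures)
  if (sexed && has_os) structures <- c("qualitative", structures)

  accept_structure <- function(comps) {
    lab <- paste(comps, collapse = "")
    cur <- structures[1]
    i <- 1L
    while (i < length(structures)) {
      fx <- fitf(comps, structures[i])
      fs <- fitf(comps, structures[i + 1L])
      tt <- lrt(fx, fs)
      if (tt$p_value < alpha) {
        note_test(sprintf("%s: %s vs %s", lab, structures[i], structures[i + 1L]),
                  tt, paste("keep", structures[i]))
        return(structures[i])
      }
      note_test(sprintf("%s: %s vs %s", lab, structures[i], structures[i + 1L]),
                tt, paste("simplify to", structures[i + 1L]))
      cur <- structures[i + 1L]
      i <- i + 1L
    }
    cur
  }

  candidates <- list()
  add_candidate <- function(f) {
    key <- paste(model_label(f$spec), f$spec$sex)
    candidates[[key]] <<- f
  }
  for (fam in list(c("A", "C", "E"), c("A", "D", "E"))) {
    lab <- paste(fam, collapse = "")
    sx <- accept_structure(fam)
    parent <- fitf(fam, sx)
    twos <- list(c("A", "E"), c(setdiff(fam, c("A", "E")), "E"))
    surv <- list()
    for (two in twos) {
      sub <- fitf(two, sx)
      tt <- lrt(parent, sub)
      ok <- tt$p_value >= alpha
      note_test(sprintf("%s vs %s (%s)", lab, model_label(sub$spec), sx), tt,
                if (ok) paste("drop to", model_label(sub$spec)) else paste("keep", lab))
      if (ok) surv[[model_label(sub$spec)]] <- sub
    }
    if (!length(surv)) {
      add_candidate(parent)
    } else {
      efit <- fitf("E", sx)
      for (sub in surv) {
        tt <- lrt(sub, efit)
        ok <- tt$p_value >= alpha
        note_test(sprintf("%s vs E (%s)", model_label(sub$spec), sx), tt,
                  if (ok) "drop to E" else paste("keep", model_label(sub$spec)))
        if (ok) add_candidate(efit) else add_candidate(sub)
      }
    }
  }
  aics <- vapply(candidates, `[[`, numeric(1), "AIC")
  ks <- vapply(candidates, `[[`, numeric(1), "k")
  ord <- order(aics, ks)
  best <- candidates[[ord[1]]]
  fits_tab <- do.call(rbind, lapply(fits_log, function(f) {
    data.frame(model = model_label(f$spec), sex_structure = f$spec$sex,
               logLik = f$logLik, k = f$k, AIC = f$AIC,
               stringsAsFactors = FALSE)
  }))
  rownames(fits_tab) <- NULL
  structure(list(best = best, fits = fits_tab,
                 tests = do.call(rbind, tests),
                 candidates = data.frame(model = names(candidates), AIC = aics,
                                         row.names = NULL)),
            class = "twin_selection")
}

#' @export
print.twin_selection <- function(x, ...) {
  cat(sprintf("<twin_selection> best model: %s (sex structure: %s), AIC %.3f\n",
              model_label(x$best$spec), x$best$spec$sex, x$best$AIC))
  cat("candidates compared by AIC:\n")
  print(x$candidates)
  invisible(x)
}

#' Variance-component table with profile confidence intervals
#'
#' Summarizes a fitted or selected model in the layout of a twin-study
#' results table: per sex block, the standardized A/C/D/E estimates with
#' profile-likelihood confidence intervals and the narrow-sense
#' heritability.
#'
#' @param x A `twin_fit` or `twin_selection`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per sex block and component.
#' @export
twin_fit_table <- function(x, level = 0.95) {
  fit <- if (inherits(x, "twin_selection")) x$best else x
  stopifnot(inherits(fit, "twin_fit"))
  rows <- lapply(fit$spec$components, function(cc) {
    ci <- profile_ci(fit, cc, level = level)
    ci$model <- model_label(fit$spec)
    ci
  })
  out <- do.call(rbind, rows)
  h <- heritability(fit)
  out$h2 <- vapply(seq_len(nrow(out)), function(i) {
    s <- out$sex[i]
    if (s == "P") unname(h[1]) else unname(h[[s]])
  }, numeric(1))
  out[, c("model", "sex", "component", "estimate", "lower", "upper",
          "method", "h2")]
}
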