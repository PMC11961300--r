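## Maximum-likelihood engine for classical twin variance-component models.
## Each zygosity-by-sex group contributes a bivariate-normal log-likelihood
## with model-implied covariance; path coefficients are optimized as
## unconstrained reals (variances enter as squares, so non-negativity holds
## by construction) with seeded multi-start quasi-Newton optimization.

#' Specify a twin variance-component model
#'
#' @param components Subset of `c("A", "C", "D", "E")`. `E` is always
#'   required; `C` and `D` are mutually exclusive (confounded in twins
#'   reared together).
#' @param sex Sex structure: `"none"` (pooled variance components),
#'   `"quantitative"` (per-sex components) or `"qualitative"` (per-sex
#'   components plus a free opposite-sex latent correlation).
#' @param qual_free Which opposite-sex correlation the qualitative model
#'   frees: `"rA"` (on \[0, 0.5\], with rC fixed at 1 — the standard
#'   identification), `"rC"` (on \[0, 1\], with rA fixed at 0.5) or `"rD"`
#'   (on \[0, 0.25\], for ADE-family models).
#' @return Object of class `twin_model_spec`.
#' @export
twin_model_spec <- function(components = c("A", "E"),
                            sex = c("none", "quantitative", "qualitative"),
                            qual_free = c("rA", "rC", "rD")) {
  sex <- match.arg(sex)
  qual_free <- match.arg(qual_free)
  components <- unique(toupper(components))
  bad <- setdiff(components, c("A", "C", "D", "E"))
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "))
  if (!"E" %in% components) stop("E must be included in every model")
  if (all(c("C", "D") %in% components)) {
    stop("C and D cannot be estimated together: they are confounded")
  }
  if (qual_free == "rC" && !"C" %in% components) {
    stop("qual_free = 'rC' requires a C component")
  }
  if (qual_free == "rD" && !"D" %in% components) {
    stop("qual_free = 'rD' requires a D component")
  }
  if (qual_free == "rA" && !"A" %in% components && sex == "qualitative") {
    stop("qual_free = 'rA' requires an A component")
  }
  structure(list(components = intersect(c("A", "C", "D", "E"), components),
                 sex = sex, qual_free = qual_free),
            class = "twin_model_spec")
}

#' Model label, e.g. "AE" or "ACE"
#' @param spec A [twin_model_spec()].
#' @return Character scalar.
#' @export
model_label <- function(spec) paste(spec$components, collapse = "")

.group_kind <- function(group) {
  switch(group,
         MZ = , MZF = , MZM = "MZ",
         DZ = , DZF = , DZM = "DZss",
         DZOS = "DZOS",
         stop("unknown group: ", group))
}

.group_member_sexes <- function(group) {
  switch(group,
         MZ = , DZ = c("P", "P"),
         MZF = , DZF = c("F", "F"),
         MZM = , DZM = c("M", "M"),
         DZOS = c("F", "M"))
}

## Latent cross-twin correlation weights by kind; the DZOS entries can be
## overridden by a qualitative sex-limitation model.
.kind_weights <- function(kind, rA = 0.5, rC = 1, rD = 0.25) {
  switch(kind,
         MZ = c(A = 1, C = 1, D = 1),
         DZss = c(A = 0.5, C = 1, D = 0.25),
         DZOS = c(A = rA, C = rC, D = rD))
}

#' Model-implied twin-pair covariance matrix
#'
#' Builds the 2x2 cross-twin covariance matrix for a zygosity-by-sex group
#' from raw variance components: diagonal `a2 + c2 + d2 + e2` (per member's
#' sex), off-diagonal `a2 + c2 + d2` for MZ pairs,
#' `a2/2 + c2 + d2/4` for same-sex DZ pairs, and
#' `rA*sqrt(a2F*a2M) + rC*sqrt(c2F*c2M) + rD*sqrt(d2F*d2M)` for
#' opposite-sex DZ pairs.
#'
#' @param group Group name: `"MZ"`, `"DZ"`, `"MZF"`, `"MZM"`, `"DZF"`,
#'   `"DZM"` or `"DZOS"`.
#' @param a2,c2,d2,e2 Raw variance components; scalar (both sexes) or named
#'   per-sex vector `c(F =, M =)`. Standardized models use shares summing
#'   to 1.
#' @param rA,rC,rD Opposite-sex cross-twin correlations of the latent
#'   factors (defaults 0.5, 1, 0.25).
#' @return Symmetric positive semi-definite 2x2 matrix.
#' @export
expected_cov <- function(group, a2 = 0, c2 = 0, d2 = 0, e2 = 0,
                         rA = 0.5, rC = 1, rD = 0.25) {
  sx <- .group_member_sexes(group)
  if (all(sx == "P")) sx <- c("F", "F")  # pooled: either column works
  comp <- rbind(a2 = .per_sex(a2, "a2"), c2 = .per_sex(c2, "c2"),
                d2 = .per_sex(d2, "d2"), e2 = .per_sex(e2, "e2"))
  v1 <- sum(comp[, sx[1]])
  v2 <- sum(comp[, sx[2]])
  w <- .kind_weights(.group_kind(group), rA, rC, rD)
  off <- w[["A"]] * sqrt(comp["a2", sx[1]] * comp["a2", sx[2]]) +
    w[["C"]] * sqrt(comp["c2", sx[1]] * comp["c2", sx[2]]) +
    w[["D"]] * sqrt(comp["d2", sx[1]] * comp["d2", sx[2]])
  matrix(c(v1, off, off, v2), 2, 2)
}

## ---- internal parameterization -------------------------------------------

## Template describing the free-parameter layout for a spec/data pair.
.par_template <- function(spec, data) {
  pooled <- !data$sexed
  if (pooled && spec$sex != "none") {
    stop("sex-limitation models require sexed twin groups")
  }
  gn <- names(data$groups)
  sexes <- if (pooled) "P" else {
    s <- character(0)
    if (any(gn %in% c("MZF", "DZF", "DZOS"))) s <- c(s, "F")
    if (any(gn %in% c("MZM", "DZM", "DZOS"))) s <- c(s, "M")
    s
  }
  path_sexes <- if (spec$sex == "none") "P" else sexes
  comps <- spec$components
  nm <- c(paste0("mu_", sexes),
          as.vector(t(outer(path_sexes, tolower(comps), paste0))))
  if (spec$sex == "qualitative") {
    if (!"DZOS" %in% gn) stop("qualitative sex-limitation requires DZOS pairs")
    nm <- c(nm, spec$qual_free)
  }
  list(names = nm, sexes = sexes, path_sexes = path_sexes, comps = comps,
       pooled = pooled, spec = spec)
}

## Unpack an unconstrained parameter vector into means, a 4 x sex path
## matrix (rows A, C, D, E) and the DZOS latent correlations.
.unpack <- function(par, tmpl) {
  names(par) <- tmpl$names
  mu <- setNames(par[paste0("mu_", tmpl$sexes)], tmpl$sexes)
  paths <- matrix(0, 4, length(tmpl$sexes),
                  dimnames = list(c("A", "C", "D", "E"), tmpl$sexes))
  for (s in tmpl$sexes) {
    ps <- if (tmpl$spec$sex == "none") "P" else s
    for (cc in tmpl$comps) {
      paths[cc, s] <- par[[paste0(ps, tolower(cc))]]
    }
  }
  r <- c(rA = 0.5, rC = 1, rD = 0.25)
  if (tmpl$spec$sex == "qualitative") {
    qf <- tmpl$spec$qual_free
    cap <- c(rA = 0.5, rC = 1, rD = 0.25)[[qf]]
    r[[qf]] <- cap * plogis(par[[qf]])
  }
  list(mu = mu, paths = paths, r = r)
}

.sigma_for_group <- function(up, group) {
  sx <- .group_member_sexes(group)
  sx[sx == "P"] <- colnames(up$paths)[1]
  p1 <- up$paths[, sx[1]]
  p2 <- up$paths[, sx[2]]
  w <- .kind_weights(.group_kind(group), up$r[["rA"]], up$r[["rC"]], up$r[["rD"]])
  off <- w[["A"]] * p1[["A"]] * p2[["A"]] + w[["C"]] * p1[["C"]] * p2[["C"]] +
    w[["D"]] * p1[["D"]] * p2[["D"]]
  matrix(c(sum(p1^2), off, off, sum(p2^2)), 2, 2)
}

## Bivariate-normal negative log-likelihood of one group from sufficient
## statistics, for mean (m1, m2) and covariance sigma.
.group_negll <- function(st, m1, m2, sigma) {
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  if (!is.finite(det) || det <= 1e-12 || sigma[1, 1] <= 0) return(Inf)
  i11 <- sigma[2, 2] / det
  i22 <- sigma[1, 1] / det
  i12 <- -sigma[1, 2] / det
  n <- st$n
  q11 <- st$s11 - 2 * m1 * st$s1 + n * m1^2
  q22 <- st$s22 - 2 * m2 * st$s2 + n * m2^2
  q12 <- st$s12 - m1 * st$s2 - m2 * st$s1 + n * m1 * m2
  n * log(2 * pi) + n / 2 * log(det) + 0.5 * (i11 * q11 + 2 * i12 * q12 + i22 * q22)
}

.negll_factory <- function(data, tmpl) {
  groups <- names(data$groups)
  force(data); force(tmpl)
  function(par) {
    up <- .unpack(par, tmpl)
    total <- 0
    for (g in groups) {
      sx <- .group_member_sexes(g)
      m1 <- up$mu[[if (sx[1] == "P") tmpl$sexes[1] else sx[1]]]
      m2 <- up$mu[[if (sx[2] == "P") tmpl$sexes[1] else sx[2]]]
      nll <- .group_negll(data$stats[[g]], m1, m2, .sigma_for_group(up, g))
      if (!is.finite(nll)) return(1e10)
      total <- total + nll
    }
    total
  }
}

## ---- initial values -------------------------------------------------------

.clip01 <- function(x, lo = 0.02, hi = 0.95) pmin(pmax(x, lo), hi)

## Symmetrized pair correlation pooled over groups of one kind.
.pooled_pair_cor <- function(data, kinds) {
  gn <- names(data$groups)[vapply(names(data$groups), function(g)
    .group_kind(g) %in% kinds, logical(1))]
  x <- do.call(rbind, data$groups[gn])
  if (is.null(x) || nrow(x) < 3L) return(NA_real_)
  cor(c(x[, 1], x[, 2]), c(x[, 2], x[, 1]))
}

## Falconer-style method-of-moments starting shares for the spec's
## components, from pooled MZ and DZ pair correlations.
.mom_shares <- function(spec, rmz, rdz) {
  comps <- spec$components
  if (is.na(rmz)) rmz <- 0.5
  if (is.na(rdz)) rdz <- 0.25
  sh <- c(A = 0, C = 0, D = 0, E = 1)
  if (all(c("A", "C") %in% comps)) {
    sh["A"] <- .clip01(2 * (rmz - rdz))
    sh["C"] <- .clip01(2 * rdz - rmz)
  } else if (all(c("A", "D") %in% comps)) {
    sh["A"] <- .clip01(4 * rdz - rmz)
    sh["D"] <- .clip01(2 * rmz - 4 * rdz)
  } else if ("A" %in% comps) {
    sh["A"] <- .clip01(rmz)
  } else if ("C" %in% comps) {
    sh["C"] <- .clip01((rmz + rdz) / 2)
  } else if ("D" %in% comps) {
    sh["D"] <- .clip01(rmz)
  }
  ## keep a floor on E so every start has full-rank covariance
  tot <- sum(sh[c("A", "C", "D")])
  if (tot > 0.95) sh[c("A", "C", "D")] <- sh[c("A", "C", "D")] * 0.95 / tot
  sh["E"] <- 1 - sum(sh[c("A", "C", "D")])
  sh
}

.start_par <- function(tmpl, data, jitter = FALSE) {
  gn <- names(data$groups)
  mu0 <- vapply(tmpl$sexes, function(s) {
    sel <- if (s == "P") gn else {
      keep <- vapply(gn, function(g) s %in% .group_member_sexes(g), logical(1))
      gn[keep]
    }
    vals <- unlist(lapply(sel, function(g) {
      m <- data$groups[[g]]
      sx <- .group_member_sexes(g)
      c(if (sx[1] %in% c(s, "P")) m[, 1], if (sx[2] %in% c(s, "P")) m[, 2])
    }))
    mean(vals)
  }, numeric(1))
  v0 <- var(unlist(lapply(data$groups, as.vector)))
  sh <- .mom_shares(tmpl$spec,
                    .pooled_pair_cor(data, "MZ"),
                    .pooled_pair_cor(data, c("DZss", "DZOS")))
  par <- numeric(0)
  for (s in tmpl$sexes) par <- c(par, mu0[[s]])
  for (s in tmpl$path_sexes) {
    for (cc in tmpl$comps) par <- c(par, sqrt(sh[[cc]] * v0))
  }
  if (tmpl$spec$sex == "qualitative") par <- c(par, 0)
  names(par) <- tmpl$names
  if (jitter) {
    np <- length(tmpl$sexes)
    par[seq_len(np)] <- par[seq_len(np)] + rnorm(np, 0, 0.2 * sqrt(v0))
    idx <- seq(np + 1, length(par))
    par[idx] <- par[idx] * exp(rnorm(length(idx), 0, 0.3))
    if (tmpl$spec$sex == "qualitative") par[length(par)] <- rnorm(1, 0, 1)
  }
  par
}

## ---- fitting --------------------------------------------------------------

#' Fit a twin variance-component model by maximum likelihood
#'
#' Maximizes the sum over zygosity-by-sex groups of bivariate-normal
#' log-likelihoods with model-implied covariances and one mean per sex
#' (equated across zygosity and twin order). Path coefficients are
#' optimized unconstrained; multi-start BFGS (seeded jitters around
#' Falconer-style method-of-moments starting values) guards against local
#' optima. Deterministic for a given seed.
#'
#' @param data A [grouped_twin_data()] object.
#' @param spec A [twin_model_spec()], or a component string such as `"AE"`
#'   (combined with the `sex` argument).
#' @param sex Sex structure, used when `spec` is given as a string.
#' @param starts Number of optimizer starts (>= 1; the first is the
#'   method-of-moments start, the rest are jittered).
#' @param seed Integer seed controlling the jittered starts.
#' @return Object of class `twin_fit`: parameter estimates, per-sex means,
#'   path coefficients and raw/standardized variance components, `logLik`,
#'   `k` (free-parameter count), `AIC`, heritability `h2`, and convergence
#'   diagnostics (per-start table, gradient norm, boundary flag).
#' @export
fit_twin_model <- function(data, spec = twin_model_spec(), sex = "none",
                           starts = 5L, seed = 1L) {
  stopifnot(inherits(data, "grouped_twin_data"))
  if (is.character(spec)) {
    spec <- twin_model_spec(strsplit(spec, "")[[1]], sex = sex)
  }
  if (sum(vapply(data$groups, nrow, integer(1)) >= 3L) < 2L &&
      length(data$groups) > 1L) {
    stop("need at least 2 groups with at least 3 complete pairs")
  }
  tmpl <- .par_template(spec, data)
  negll <- .negll_factory(data, tmpl)
  run <- function() {
    best <- NULL
    trace <- list()
    for (i in seq_len(max(1L, starts))) {
      p0 <- .start_par(tmpl, data, jitter = i > 1L)
      opt <- tryCatch(
        optim(p0, negll, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(opt)) next
      trace[[i]] <- data.frame(start = i, value = opt$value,
                               convergence = opt$convergence)
      if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
    }
    list(best = best, trace = do.call(rbind, trace))
  }
  res <- withr::with_seed(seed, run())
  if (is.null(res$best) || res$best$value >= 1e10) {
    stop("twin model fit failed to converge from any start; groups: ",
         paste(names(data$groups), collapse = ", "))
  }
  best <- res$best
  up <- .unpack(best$par, tmpl)
  ## numerical gradient norm at the optimum (central differences)
  gr <- vapply(seq_along(best$par), function(j) {
    h <- 1e-5 * max(1, abs(best$par[j]))
    pp <- pm <- best$par
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    (negll(pp) - negll(pm)) / (2 * h)
  }, numeric(1))
  paths <- abs(up$paths)  # sign of a path coefficient is not identified
  vtot <- colSums(paths^2)
  shares <- sweep(paths^2, 2, vtot, "/")
  boundary <- any(shares[tmpl$comps, ] < 1e-6) ||
    (spec$sex == "qualitative" && abs(best$par[[spec$qual_free]]) > 8)
  ll <- -best$value
  k <- length(best$par)
  fit <- structure(list(
    spec = spec, data = data, par = best$par,
    mu = up$mu, paths = paths, variances = paths^2,
    total_variance = vtot, shares = shares, r = up$r,
    logLik = ll, k = k, AIC = -2 * ll + 2 * k,
    h2 = setNames(shares["A", ], colnames(shares)),
    convergence = list(code = best$convergence, grad_norm = sqrt(sum(gr^2)),
                       starts = res$trace, boundary = boundary),
    seed = seed, starts = starts
  ), class = "twin_fit")
  fit
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<twin_fit> %s model (sex structure: %s) on %s\n",
              model_label(x$spec), x$spec$sex, x$data$trait))
  cat(sprintf("  logLik %.3f, k = %d, AIC %.3f\n", x$logLik, x$k, x$AIC))
  for (s in colnames(x$shares)) {
    lab <- if (s == "P") "pooled" else s
    sh <- x$shares[x$spec$components, s]
    cat(sprintf("  %s: %s (h2 = %.3f)\n", lab,
                paste(sprintf("%s = %.3f", names(sh), sh), collapse = ", "),
                x$h2[[s]]))
  }
  if (x$spec$sex == "qualitative") {
    cat(sprintf("  %s = %.3f\n", x$spec$qual_free, x$r[[x$spec$qual_free]]))
  }
  invisible(x)
}

#' @export
logLik.twin_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' Narrow-sense heritability from a fitted twin model
#'
#' The standardized additive-genetic share of the fitted model, per sex when
#' the model has sex-specific components; 0 for models without an A
#' component.
#'
#' @param fit A `twin_fit` (or the result of [select_model()], in which
#'   case its best fit is used).
#' @return Named numeric vector of h2 values (one per sex, or one pooled).
#' @export
heritability <- function(fit) {
  if (inherits(fit, "twin_selection")) fit <- fit$best
  stopifnot(inherits(fit, "twin_fit"))
  h <- fit$h2
  if (!"A" %in% fit$spec$components) h[] <- 0
  h
}
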