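## Synthetic twin-pair generator. Phenotypes are built by summing independent
## Gaussian latent factors with the classical-twin cross-pair correlations
## (A: 1 in MZ / 0.5 in DZ; D: 1 / 0.25; C: 1 / 1; E: 0), which realises the
## path model literally and makes the implied covariance structure explicit.

## Per-sex recycling helper: accepts scalar or c(F=, M=).
.per_sex <- function(x, what) {
  if (length(x) == 1L) x <- c(F = unname(x), M = unname(x))
  if (is.null(names(x)) && length(x) == 2L) names(x) <- c("F", "M")
  if (!all(c("F", "M") %in% names(x))) {
    stop(sprintf("`%s` must be a scalar or a named vector with elements F and M", what))
  }
  x[c("F", "M")]
}

#' Configuration for the twin-pair simulator
#'
#' Defaults are calibrated to the primary-dentition maxillary intercanine
#' width of the motivating cohort: 90 MZ and 98 DZ pairs, female/male means
#' 28.0/29.1 mm with SDs 2.0/1.9 mm, and an AE structure with a heritability
#' of 0.85.
#'
#' @param n_pairs Named integer vector of pair counts per zygosity-by-sex
#'   group (`MZF`, `MZM`, `DZF`, `DZM`, `DZOS`).
#' @param mean,var Trait mean (mm) and total phenotypic variance (mm^2);
#'   scalar or named per-sex vector `c(F =, M =)`.
#' @param a2,c2,d2,e2 Standardized variance shares (additive genetic, shared
#'   environmental, non-additive genetic, non-shared environmental); scalar
#'   or per-sex. Must be non-negative and sum to 1 for each sex; `c2` and
#'   `d2` may not both be positive (they are confounded in twins reared
#'   together and are modelled separately).
#' @param rA,rC,rD Opposite-sex cross-twin correlations of the A, C and D
#'   latent factors; defaults 0.5, 1 and 0.25 (no qualitative sex
#'   difference). `rA` must lie in \[0, 0.5\], `rC` in \[0, 1\], `rD` in
#'   \[0, 0.25\].
#' @param trait,stage Labels attached to the generated records.
#' @param error_sd Measurement-error SD (mm) used by
#'   [simulate_repeated_measures()].
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   byte-for-byte.
#'
#' @return An object of class `twin_sim_config`.
#' @export
twin_sim_config <- function(n_pairs = c(MZF = 45, MZM = 45, DZF = 33, DZM = 32, DZOS = 33),
                            mean = c(F = 28.0, M = 29.1),
                            var = c(F = 2.0^2, M = 1.9^2),
                            a2 = 0.85, c2 = 0, d2 = 0, e2 = 0.15,
                            rA = 0.5, rC = 1, rD = 0.25,
                            trait = "maxillary_intercanine_width",
                            stage = "primary",
                            error_sd = 0.2,
                            seed = NULL) {
  if (is.null(names(n_pairs))) names(n_pairs) <- .GROUPS[seq_along(n_pairs)]
  full <- setNames(integer(5), .GROUPS)
  full[names(n_pairs)] <- as.integer(n_pairs)
  if (any(full < 0)) stop("pair counts must be non-negative")
  cfg <- list(
    n_pairs = full,
    mean = .per_sex(mean, "mean"),
    var = .per_sex(var, "var"),
    a2 = .per_sex(a2, "a2"), c2 = .per_sex(c2, "c2"),
    d2 = .per_sex(d2, "d2"), e2 = .per_sex(e2, "e2"),
    rA = rA, rC = rC, rD = rD,
    trait = trait, stage = stage, error_sd = error_sd, seed = seed
  )
  for (s in c("F", "M")) {
    sh <- c(cfg$a2[s], cfg$c2[s], cfg$d2[s], cfg$e2[s])
    if (any(sh < 0)) stop("variance shares must be non-negative")
    if (abs(sum(sh) - 1) > 1e-12) {
      stop(sprintf("a2 + c2 + d2 + e2 must sum to 1 (sex %s: %.15g)", s, sum(sh)))
    }
    if (cfg$c2[s] * cfg$d2[s] > 0) {
      stop("c2 and d2 may not both be positive: C and D are confounded")
    }
  }
  if (any(cfg$var <= 0)) stop("total variance must be positive")
  if (rA < 0 || rA > 0.5) stop("rA must lie in [0, 0.5]")
  if (rC < 0 || rC > 1) stop("rC must lie in [0, 1]")
  if (rD < 0 || rD > 0.25) stop("rD must lie in [0, 0.25]")
  if (error_sd < 0) stop("error_sd must be non-negative")
  structure(cfg, class = "twin_sim_config")
}

## Latent cross-twin correlations per group.
.group_latent_r <- function(group, cfg) {
  switch(group,
    MZF = , MZM = c(rA = 1, rC = 1, rD = 1),
    DZF = , DZM = c(rA = 0.5, rC = 1, rD = 0.25),
    DZOS = c(rA = cfg$rA, rC = cfg$rC, rD = cfg$rD)
  )
}

.group_sexes <- function(group) {
  switch(group,
    MZF = c("F", "F"), MZM = c("M", "M"),
    DZF = c("F", "F"), DZM = c("M", "M"),
    DZOS = c("F", "M")  # opposite-sex pairs are stored female-first
  )
}

#' Simulate twin pairs under a classical twin model
#'
#' Draws bivariate-normal twin pairs for each zygosity-by-sex group with the
#' model-implied cross-twin covariance: `a^2 + c^2 + d^2` for MZ pairs,
#' `a^2/2 + c^2 + d^2/4` for same-sex DZ pairs, and
#' `rA*am*af + rC*cm*cf + rD*dm*df` for opposite-sex pairs (path
#' coefficients in mm, i.e. the square roots of the variance shares scaled
#' by the trait SD).
#'
#' @param cfg A [twin_sim_config()].
#' @return A data frame of class `twin_pairs` with columns `family_id`,
#'   `group`, `zygosity`, `sex1`, `sex2`, `stage`, `trait`, `value1`,
#'   `value2`.
#' @export
simulate_twin_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "twin_sim_config"))
  sim <- function() {
    paths <- sapply(c("F", "M"), function(s) {
      sqrt(c(a = cfg$a2[[s]], c = cfg$c2[[s]], d = cfg$d2[[s]], e = cfg$e2[[s]]) *
             cfg$var[[s]])
    })  # 4 x 2 matrix, columns F, M
    rows <- list()
    fam <- 0L
    for (g in .GROUPS) {
      n <- cfg$n_pairs[[g]]
      if (n == 0L) next
      r <- .group_latent_r(g, cfg)
      sx <- .group_sexes(g)
      ## Latent factors: twin 1 gets z; twin 2 gets r*z + sqrt(1-r^2)*z'.
      lat <- lapply(c(A = r[["rA"]], C = r[["rC"]], D = r[["rD"]], E = 0),
                    function(rho) {
                      z1 <- rnorm(n)
                      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
                      cbind(z1, z2)
                    })
      val <- vapply(1:2, function(j) {
        p <- paths[, sx[j]]
        cfg$mean[[sx[j]]] +
          p[["a"]] * lat$A[, j] + p[["c"]] * lat$C[, j] +
          p[["d"]] * lat$D[, j] + p[["e"]] * lat$E[, j]
      }, numeric(n))
      val <- matrix(val, ncol = 2L)  # keep matrix shape when n = 1
      rows[[g]] <- data.frame(
        family_id = sprintf("fam%05d", fam + seq_len(n)),
        group = g,
        zygosity = if (g %in% c("MZF", "MZM")) "MZ" else "DZ",
        sex1 = sx[1], sex2 = sx[2],
        stage = cfg$stage, trait = cfg$trait,
        value1 = val[, 1], value2 = val[, 2],
        stringsAsFactors = FALSE
      )
      fam <- fam + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("twin_pairs", class(out))
    out
  }
  if (is.null(cfg$seed)) sim() else withr::with_seed(cfg$seed, sim())
}

#' Simulate paired repeat measurements
#'
#' Adds independent zero-mean Gaussian measurement error to each true value
#' twice, emulating repeated landmark digitization for reliability analysis.
#'
#' @param values Numeric vector of true trait values (mm).
#' @param error_sd Measurement-error SD (mm).
#' @param seed Optional integer seed.
#' @return Data frame with columns `subject`, `value1`, `value2`.
#' @export
simulate_repeated_measures <- function(values, error_sd, seed = NULL) {
  stopifnot(is.numeric(values), error_sd >= 0)
  sim <- function() {
    n <- length(values)
    data.frame(
      subject = seq_len(n),
      value1 = values + rnorm(n, 0, error_sd),
      value2 = values + rnorm(n, 0, error_sd)
    )
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Construct landmark sets that reproduce target arch traits
#'
#' Places landmarks on a parametric arch (maxillary occlusal plane at z = 0,
#' anterior towards +y, occlusal-plane normal towards the mandible at +z)
#' such that [extract_all_traits()] on the result reproduces the ten target
#' traits. The mandibular posterior landmark height is solved numerically so
#' that the mandibular arch length is honoured jointly with the overjet,
#' overbite and molar-relationship constraints; targets that admit no such
#' arch (mandibular arch length shorter than the horizontal incisor-molar
#' separation they imply) raise an error.
#'
#' @param target Named list or one-row data frame containing the ten trait
#'   values (see [extract_all_traits()] for names) and optionally `stage`
#'   (default `"permanent"`) and `subject_id`.
#' @param seed Optional seed for jitter of nuisance coordinates (positions
#'   that do not enter any trait); `NULL` gives the deterministic canonical
#'   arch.
#' @return List with elements `maxilla` and `mandible` ([landmark_set()]s).
#' @export
simulate_landmarks <- function(target, seed = NULL) {
  t <- as.list(target)
  need <- .TRAITS
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("target is missing trait(s): ", paste(miss, collapse = ", "))
  stage <- if (!is.null(t$stage)) as.character(t$stage) else "permanent"
  stage <- match.arg(stage, .STAGES)
  id <- if (!is.null(t$subject_id)) t$subject_id else "synthetic"
  v <- vapply(need, function(nm) as.numeric(t[[nm]]), numeric(1))
  if (any(v[1:6] <= 0)) stop("widths and arch lengths must be positive")

  build <- function() {
    jit <- function(sd) if (is.null(seed)) 0 else rnorm(1, 0, sd)
    L <- v[["maxillary_arch_length"]]
    yi_md <- L - v[["overjet"]]           # mandibular incisal midpoint, AP
    zi_md <- v[["overbite"]]
    if (yi_md <= 0) stop("infeasible target: overjet >= maxillary arch length")
    mrr <- v[["molar_relationship_right"]]
    mrl <- v[["molar_relationship_left"]]
    half <- function(x) x / 2
    ## Maxilla: incisal midpoint (0, L, 0); molar landmarks on y = 0 so the
    ## arch length is exact by construction and the AP axis is +y.
    xoff <- 2 + abs(jit(0.3))
    y_can_mx <- 0.65 * L + jit(0.5)
    mx <- rbind(
      incisor_mesial_R = c(-xoff, L, 0),
      incisor_mesial_L = c(xoff, L, 0),
      canine_cusp_R = c(half(v[["maxillary_intercanine_width"]]), y_can_mx, 0),
      canine_cusp_L = c(-half(v[["maxillary_intercanine_width"]]), y_can_mx, 0),
      molar_mb_cusp_R = c(half(v[["maxillary_intermolar_width"]]), 0, 0),
      molar_mb_cusp_L = c(-half(v[["maxillary_intermolar_width"]]), 0, 0),
      molar_distal_contact_R = c(half(v[["maxillary_intermolar_width"]]) + 1.5, 0, 0),
      molar_distal_contact_L = c(-half(v[["maxillary_intermolar_width"]]) - 1.5, 0, 0)
    )
    ## Mandible. The molar-relationship reference landmark sits at
    ## y = -(relationship) because the maxillary reference is at y = 0.
    wdm <- v[["mandibular_intermolar_width"]] + 3
    Lmd <- v[["mandibular_arch_length"]]
    p <- c(0, yi_md, zi_md)
    if (stage == "primary") {
      ## distal contacts carry the molar relationship: AP positions pinned,
      ## so the contact height h is solved to honour the arch length
      y_dc <- c(R = -mrr, L = -mrl)
      a_of <- function(h) c(half(wdm), y_dc[["R"]], h)
      b_of <- function(h) c(-half(wdm), y_dc[["L"]], h)
      dist_h <- function(h) {
        a <- a_of(h); b <- b_of(h)
        u <- (b - a) / sqrt(sum((b - a)^2))
        w <- p - a
        sqrt(sum((w - sum(w * u) * u)^2))
      }
      if (dist_h(zi_md) > Lmd) {
        stop(sprintf(paste0("infeasible target: mandibular arch length %.2f mm is ",
                            "shorter than the horizontal incisor-molar separation ",
                            "%.2f mm implied by the other traits"), Lmd,
                     dist_h(zi_md)))
      }
      h <- uniroot(function(h) dist_h(h) - Lmd, c(zi_md, zi_md + Lmd + 10),
                   tol = 1e-12)$root
    } else {
      ## buccal grooves carry the relation, so the distal-contact AP position
      ## is free: place the contact line at height h and back-solve its AP
      ## offset from the arch length (closed form)
      h <- zi_md + 1 + abs(jit(0.3))
      if (Lmd <= h - zi_md) {
        stop(sprintf("infeasible target: mandibular arch length %.2f mm too short",
                     Lmd))
      }
      y_dc_shared <- yi_md - sqrt(Lmd^2 - (h - zi_md)^2)
      y_dc <- c(R = y_dc_shared, L = y_dc_shared)
      a_of <- function(h) c(half(wdm), y_dc[["R"]], h)
      b_of <- function(h) c(-half(wdm), y_dc[["L"]], h)
    }
    y_can_md <- 0.6 * yi_md + jit(0.5)
    md <- rbind(
      incisor_mesial_R = c(-xoff, yi_md, zi_md),
      incisor_mesial_L = c(xoff, yi_md, zi_md),
      canine_cusp_R = c(half(v[["mandibular_intercanine_width"]]), y_can_md, 1.5),
      canine_cusp_L = c(-half(v[["mandibular_intercanine_width"]]), y_can_md, 1.5),
      molar_mb_cusp_R = c(half(v[["mandibular_intermolar_width"]]), 0.5, 1.5),
      molar_mb_cusp_L = c(-half(v[["mandibular_intermolar_width"]]), 0.5, 1.5),
      molar_distal_contact_R = a_of(h),
      molar_distal_contact_L = b_of(h)
    )
    if (stage != "primary") {
      md <- rbind(md,
        molar_buccal_groove_R = c(half(v[["mandibular_intermolar_width"]]) + 1, -mrr, 1.5),
        molar_buccal_groove_L = c(-half(v[["mandibular_intermolar_width"]]) - 1, -mrl, 1.5)
      )
    }
    list(
      maxilla = landmark_set(id, stage, "maxillary", mx),
      mandible = landmark_set(id, stage, "mandibular", md)
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

## read.csv turns an all-"F" sex column into logical FALSE; undo that.
.fix_sex_col <- function(df) {
  if ("sex" %in% names(df) && is.logical(df$sex)) {
    df$sex <- ifelse(is.na(df$sex), NA_character_, ifelse(df$sex, "T", "F"))
  }
  df
}

#' Write twin pairs to a long-format CSV
#'
#' One row per twin: `family_id, twin, zygosity, sex, stage, trait, value`.
#' The generator seed (if any) is recorded in a `#`-comment header.
#'
#' @param pairs A `twin_pairs` data frame from [simulate_twin_pairs()].
#' @param path Output file path.
#' @param seed Optional seed to record in the header.
#' @export
write_twin_pairs <- function(pairs, path, seed = NULL) {
  long <- rbind(
    data.frame(family_id = pairs$family_id, twin = 1L, zygosity = pairs$zygosity,
               sex = pairs$sex1, stage = pairs$stage, trait = pairs$trait,
               value = pairs$value1, stringsAsFactors = FALSE),
    data.frame(family_id = pairs$family_id, twin = 2L, zygosity = pairs$zygosity,
               sex = pairs$sex2, stage = pairs$stage, trait = pairs$trait,
               value = pairs$value2, stringsAsFactors = FALSE)
  )
  long <- long[order(long$family_id, long$twin), ]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  write.csv(long, con, row.names = FALSE)
  invisible(long)
}

#' Read a long-format twin trait CSV into pair form
#'
#' Inverse of [write_twin_pairs()]: expects columns `family_id, twin,
#' zygosity, sex, stage, trait, value`; `#`-comment lines are skipped.
#' Families without both twins for a trait/stage are dropped with a warning.
#'
#' @param path CSV file path.
#' @return A `twin_pairs` data frame.
#' @export
read_twin_pairs <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- .fix_sex_col(df)
  need <- c("family_id", "twin", "zygosity", "sex", "stage", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("twin CSV is missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(df$family_id, df$stage, df$trait, drop = TRUE)
  rows <- lapply(split(df, key), function(d) {
    if (!all(c(1L, 2L) %in% d$twin) || nrow(d) != 2L) {
      warning(sprintf("family %s (%s, %s): incomplete pair dropped",
                      d$family_id[1], d$stage[1], d$trait[1]), call. = FALSE)
      return(NULL)
    }
    d <- d[order(d$twin), ]
    ## canonical ordering: opposite-sex pairs female-first
    if (d$sex[1] == "M" && d$sex[2] == "F") d <- d[2:1, ]
    zy <- d$zygosity[1]
    if (zy == "MZ" && d$sex[1] != d$sex[2]) {
      warning(sprintf("family %s: MZ pair with discordant sexes dropped",
                      d$family_id[1]), call. = FALSE)
      return(NULL)
    }
    g <- if (d$sex[1] != d$sex[2]) "DZOS"
         else paste0(zy, d$sex[1])
    data.frame(family_id = d$family_id[1], group = g, zygosity = zy,
               sex1 = d$sex[1], sex2 = d$sex[2], stage = d$stage[1],
               trait = d$trait[1], value1 = d$value[1], value2 = d$value[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("twin_pairs", class(out))
  out
}
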