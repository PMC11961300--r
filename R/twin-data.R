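## Grouped twin data: complete trait pairs partitioned into zygosity-by-sex
## groups, with cached sufficient statistics for the bivariate-normal
## likelihood (per group: n, sums, sums of squares and cross-products).

#' Partition twin pairs into zygosity-by-sex groups for one trait and stage
#'
#' Retains complete pairs only. Sexed data are split into the five groups
#' `MZF`, `MZM`, `DZF`, `DZM`, `DZOS` (opposite-sex pairs female-first);
#' unsexed data (missing `sex1`/`sex2`) are split into `MZ` and `DZ` and can
#' only be fitted with models without sex differences.
#'
#' @param pairs A `twin_pairs` data frame (see [simulate_twin_pairs()]), or
#'   a named list of two-column numeric matrices keyed by group name.
#' @param trait,stage Optional filters when `pairs` holds several traits or
#'   stages.
#' @return An object of class `grouped_twin_data`.
#' @export
grouped_twin_data <- function(pairs, trait = NULL, stage = NULL) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    groups <- lapply(pairs, function(m) {
      m <- as.matrix(m)
      stopifnot(ncol(m) == 2L)
      m[stats::complete.cases(m), , drop = FALSE]
    })
    bad <- setdiff(names(groups), c(.GROUPS, "MZ", "DZ"))
    if (length(bad)) stop("unknown group name(s): ", paste(bad, collapse = ", "))
    return(.new_gtd(groups, trait %||% "trait", stage %||% NA_character_))
  }
  stopifnot(is.data.frame(pairs))
  d <- pairs
  if (!is.null(trait)) d <- d[d$trait == trait, ]
  if (!is.null(stage)) d <- d[d$stage == stage, ]
  if (!nrow(d)) stop("no pairs left after filtering")
  if (length(unique(d$trait)) > 1L || length(unique(d$stage)) > 1L) {
    stop("data contain multiple traits/stages; pass `trait` and `stage` filters")
  }
  ok <- is.finite(d$value1) & is.finite(d$value2)
  d <- d[ok, ]
  sexed <- !is.null(d$sex1) && !anyNA(d$sex1) && !anyNA(d$sex2)
  if (sexed) {
    swap <- d$sex1 == "M" & d$sex2 == "F"
    tmp <- d$value1[swap]
    d$value1[swap] <- d$value2[swap]
    d$value2[swap] <- tmp
    s1 <- ifelse(swap, d$sex2, d$sex1)
    s2 <- ifelse(swap, d$sex1, d$sex2)
    g <- ifelse(s1 != s2, "DZOS", paste0(d$zygosity, s1))
    if (any(g == "MZOS" | (d$zygosity == "MZ" & s1 != s2))) {
      stop("MZ pairs with discordant sexes found")
    }
  } else {
    g <- d$zygosity
  }
  keys <- if (sexed) .GROUPS else c("MZ", "DZ")
  groups <- lapply(setNames(keys, keys), function(k) {
    cbind(d$value1, d$value2)[g == k, , drop = FALSE]
  })
  groups <- groups[vapply(groups, nrow, integer(1)) > 0L]
  .new_gtd(groups, d$trait[1], d$stage[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_gtd <- function(groups, trait, stage) {
  stats <- lapply(groups, function(m) {
    list(n = nrow(m),
         s1 = sum(m[, 1]), s2 = sum(m[, 2]),
         s11 = sum(m[, 1]^2), s22 = sum(m[, 2]^2), s12 = sum(m[, 1] * m[, 2]))
  })
  structure(list(groups = groups, stats = stats, trait = trait, stage = stage,
                 sexed = !any(names(groups) %in% c("MZ", "DZ"))),
            class = "grouped_twin_data")
}

#' @export
print.grouped_twin_data <- function(x, ...) {
  ns <- vapply(x$groups, nrow, integer(1))
  cat(sprintf("<grouped_twin_data> %s (%s): %s\n", x$trait, x$stage,
              paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")))
  invisible(x)
}

## Pair ICC from the one-way random-effects ANOVA decomposition:
## (MSB - MSW) / (MSB + MSW) for k = 2 members per pair.
.pair_icc <- function(x) {
  n <- nrow(x)
  if (n < 3L) stop("twin ICC requires at least 3 pairs")
  gm <- mean(x)
  pm <- rowMeans(x)
  if (sum((x - gm)^2) < 1e-300) stop("twin ICC undefined: zero total variance")
  msb <- 2 * sum((pm - gm)^2) / (n - 1)
  msw <- sum((x - pm)^2) / n
  (msb - msw) / (msb + msw)
}

#' Twin intraclass correlation with bootstrap distribution
#'
#' One-way random-effects ICC of pair resemblance,
#' `(MSB - MSW) / (MSB + MSW)` from the between- and within-pair mean
#' squares, for all pairs of one zygosity (MZ pools the MZ groups; DZ pools
#' same- and opposite-sex DZ groups). The bootstrap resamples pairs with
#' replacement, giving the replicate vector used for ridge-style density
#' displays.
#'
#' @param data A [grouped_twin_data()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param nboot Number of bootstrap replicates (default 1000; 0 disables).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `twin_icc`: `estimate`, `boot` (replicate vector),
#'   `n_pairs`, `zygosity`.
#' @export
twin_icc <- function(data, zygosity = c("MZ", "DZ"), nboot = 1000, seed = 1L) {
  stopifnot(inherits(data, "grouped_twin_data"))
  zygosity <- match.arg(zygosity)
  keys <- if (zygosity == "MZ") c("MZ", "MZF", "MZM") else c("DZ", "DZF", "DZM", "DZOS")
  x <- do.call(rbind, data$groups[intersect(keys, names(data$groups))])
  if (is.null(x) || nrow(x) < 3L) stop("fewer than 3 ", zygosity, " pairs")
  est <- .pair_icc(x)
  boot <- numeric(0)
  if (nboot > 0) {
    boot <- withr::with_seed(seed, vapply(seq_len(nboot), function(i) {
      .pair_icc(x[sample.int(nrow(x), replace = TRUE), , drop = FALSE])
    }, numeric(1)))
  }
  structure(list(estimate = est, boot = boot, n_pairs = nrow(x),
                 zygosity = zygosity),
            class = "twin_icc")
}

#' @export
print.twin_icc <- function(x, ...) {
  cat(sprintf("%s twin ICC = %.3f (%d pairs", x$zygosity, x$estimate, x$n_pairs))
  if (length(x$boot)) {
    q <- quantile(x$boot, c(0.025, 0.975))
    cat(sprintf("; bootstrap 2.5%%-97.5%%: %.3f-%.3f", q[1], q[2]))
  }
  cat(")\n")
  invisible(x)
}
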