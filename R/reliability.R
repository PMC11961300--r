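## Examiner reliability: two-way absolute-agreement single-measure ICC
## (McGraw & Wong ICC(A,1)) for systematic error and Dahlberg's formula for
## random error, both on paired repeat measurements.

#' Two-way absolute-agreement single-measure ICC
#'
#' ICC(A,1) from the two-way ANOVA decomposition of an n-subjects by
#' k-occasions table (k = 2 here):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' where MSR, MSC and MSE are the subject, occasion and residual mean
#' squares. Absolute agreement penalizes a systematic offset between
#' occasions, so `values2 = values1 + const` yields ICC < 1. Negative
#' estimates are returned as computed (not truncated) with a warning.
#'
#' @param values1,values2 Paired measurements (mm), equal length, n >= 3.
#' @return ICC point estimate in \[-1, 1\].
#' @export
icc_agreement <- function(values1, values2) {
  stopifnot(length(values1) == length(values2))
  n <- length(values1)
  if (n < 3L) stop("ICC requires at least 3 paired observations")
  x <- cbind(values1, values2)
  k <- 2L
  gm <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  mse <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + gm)^2) /
    ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || sum((x - gm)^2) < 1e-300) {
    stop("ICC undefined: no variance in the measurements")
  }
  icc <- (msr - mse) / denom
  if (icc < 0) {
    warning(sprintf("negative ICC (%.4f): agreement worse than chance", icc))
  }
  icc
}

#' Dahlberg's random error
#'
#' `sqrt(sum(d_i^2) / (2n))` over paired repeat measurements, where
#' `d_i = values1_i - values2_i`. Estimates the measurement-error SD.
#'
#' @inheritParams icc_agreement
#' @return Random error in the units of the measurements (mm).
#' @export
dahlberg <- function(values1, values2) {
  stopifnot(length(values1) == length(values2))
  n <- length(values1)
  if (n < 1L) stop("no paired observations")
  d <- values1 - values2
  sqrt(sum(d^2) / (2 * n))
}

#' Per-trait reliability table
#'
#' Computes ICC(A,1) and Dahlberg's error for each trait in a replicate
#' table.
#'
#' @param replicates Data frame with columns `subject`, `trait`,
#'   `measurement_occasion` (1 or 2) and `value`, or columns `value1` /
#'   `value2` (plus optional `trait`).
#' @return Data frame with one row per trait: `trait`, `n`, `icc`,
#'   `dahlberg`.
#' @export
reliability_table <- function(replicates) {
  if (all(c("value1", "value2") %in% names(replicates))) {
    wide <- replicates
    if (is.null(wide$trait)) wide$trait <- "trait"
  } else {
    need <- c("subject", "trait", "measurement_occasion", "value")
    miss <- setdiff(need, names(replicates))
    if (length(miss)) {
      stop("replicate table is missing column(s): ", paste(miss, collapse = ", "))
    }
    sp <- split(replicates, replicates$trait)
    wide <- do.call(rbind, lapply(sp, function(d) {
      w1 <- d[d$measurement_occasion == 1, c("subject", "value")]
      w2 <- d[d$measurement_occasion == 2, c("subject", "value")]
      m <- merge(w1, w2, by = "subject", suffixes = c("1", "2"))
      data.frame(trait = d$trait[1], value1 = m$value1, value2 = m$value2,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, lapply(split(wide, wide$trait), function(d) {
    data.frame(trait = d$trait[1], n = nrow(d),
               icc = icc_agreement(d$value1, d$value2),
               dahlberg = dahlberg(d$value1, d$value2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
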