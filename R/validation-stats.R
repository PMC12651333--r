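## Analytical-validation statistics: CLSI EP17-A2 detection limits,
## categorical agreement with Wilson score intervals, Cohen's kappa
## (unweighted and weighted), Pearson correlation and Welch confidence
## intervals. Wilson intervals and kappa are implemented in closed form
## with z fixed at 1.959964; Welch and Pearson delegate to stats.

.WILSON_Z <- 1.959964

#' Limit of blank (CLSI EP17-A2)
#'
#' \eqn{LoB = \bar x_{blank} + 1.645 \, SD_{blank}} with the sample
#' standard deviation (n-1 denominator).
#'
#' @param blanks numeric vector of blank measurements (n >= 2), or `NULL`
#'   when `mean` and `sd` are given directly.
#' @param mean,sd summary statistics used when `blanks` is `NULL`.
#' @return A list of class `"DetectionLimits"` with `meanBlank`,
#'   `sdBlank` and `lob` (the remaining fields are filled by
#'   [limitOfDetection()]).
#' @examples
#' limitOfBlank(mean = 0.5, sd = 0.2)$lob  # 0.829
#' @export
limitOfBlank <- function(blanks = NULL, mean = NULL, sd = NULL) {
  if (!is.null(blanks)) {
    if (length(blanks) < 2L) stop("need at least 2 blank replicates")
    mean <- base::mean(blanks)
    sd <- stats::sd(blanks)
  } else if (is.null(mean) || is.null(sd)) {
    stop("give either raw blanks or both mean and sd")
  }
  if (sd < 0) stop("sd must be non-negative")
  structure(list(meanBlank = mean, sdBlank = sd, sdLow = NA_real_,
                 lob = mean + 1.645 * sd, lod = NA_real_),
            class = "DetectionLimits")
}

#' Limit of detection (CLSI EP17-A2)
#'
#' \eqn{LoD = LoB + 1.645 \, SD_{low}} from low-level replicates near the
#' detection limit.
#'
#' @param lob a `"DetectionLimits"` from [limitOfBlank()], or the LoB as
#'   a number.
#' @param lowReplicates numeric vector of low-level measurements
#'   (n >= 2), or `NULL` when `sdLow` is given.
#' @param sdLow low-level standard deviation used when `lowReplicates` is
#'   `NULL`.
#' @return The completed `"DetectionLimits"` list.
#' @examples
#' limitOfDetection(limitOfBlank(mean = 0.5, sd = 0.2), sdLow = 2.5)$lod
#' @export
limitOfDetection <- function(lob, lowReplicates = NULL, sdLow = NULL) {
  if (!inherits(lob, "DetectionLimits"))
    lob <- structure(list(meanBlank = NA_real_, sdBlank = NA_real_,
                          sdLow = NA_real_, lob = lob, lod = NA_real_),
                     class = "DetectionLimits")
  if (!is.null(lowReplicates)) {
    if (length(lowReplicates) < 2L) stop("need at least 2 low-level replicates")
    sdLow <- stats::sd(lowReplicates)
  } else if (is.null(sdLow)) {
    stop("give either low-level replicates or sdLow")
  }
  if (sdLow < 0) stop("sdLow must be non-negative")
  lob$sdLow <- sdLow
  lob$lod <- lob$lob + 1.645 * sdLow
  lob
}

#' @export
print.DetectionLimits <- function(x, ...) {
  cat(sprintf("DetectionLimits: LoB = %.3f", x$lob))
  if (!is.na(x$lod)) cat(sprintf(", LoD = %.3f", x$lod))
  cat(" ng/mL\n")
  invisible(x)
}

## Validate a K x K contingency table (rows = candidate, cols = reference).
checkContingency <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("contingency table must be square")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (sum(tab) <= 0) stop("contingency table is empty")
  tab
}

#' Percent agreement of a contingency table
#'
#' Overall agreement is `100 * trace / total`; per-category agreement for
#' reference category j is `100 * tab[j, j] / colsum(j)`. A reference
#' category with zero column total has undefined (not zero) agreement and
#' is reported as `NA`.
#'
#' @param tab K x K matrix of counts, rows = candidate method's calls,
#'   columns = reference method's calls.
#' @return List with `overall` and `perCategory` (percent).
#' @export
percentAgreement <- function(tab) {
  tab <- checkContingency(tab)
  cs <- colSums(tab)
  per <- ifelse(cs > 0, 100 * diag(tab) / cs, NA_real_)
  names(per) <- colnames(tab)
  list(overall = 100 * sum(diag(tab)) / sum(tab), perCategory = per)
}

#' Wilson score confidence interval for a proportion
#'
#' The score-test interval with `z = 1.959964` for 95% confidence and no
#' continuity correction; well-behaved at 0/n and n/n.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param conf confidence level.
#' @return Named numeric `(lo, hi)` as proportions.
#' @examples
#' round(100 * wilsonCI(14, 15), 1)  # 70.2 98.8
#' @export
wilsonCI <- function(successes, n, conf = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- if (conf == 0.95) .WILSON_Z else stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Cohen's kappa for a contingency table
#'
#' \eqn{\kappa = (P_o - P_e) / (1 - P_e)} with the weighted
#' generalization \eqn{w_{ij} = 1 - (|i - j| / (K - 1))^q} for ordinal
#' categories: `q = 1` (linear), `q = 2` (quadratic); `weights = "none"`
#' uses identity weights (plain kappa). A table with perfect agreement
#' returns 1 even when all observations fall in a single category (where
#' the ratio is formally 0/0); a degenerate table with chance agreement 1
#' but imperfect observed agreement is an error.
#'
#' @param tab K x K matrix of counts.
#' @param weights `"none"` (default), `"linear"` or `"quadratic"`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohenKappa <- function(tab, weights = c("none", "linear", "quadratic")) {
  weights <- match.arg(weights)
  tab <- checkContingency(tab)
  K <- nrow(tab)
  p <- tab / sum(tab)
  idx <- seq_len(K)
  w <- switch(weights,
    none = diag(K),
    linear = 1 - abs(outer(idx, idx, "-")) / (K - 1),
    quadratic = 1 - (abs(outer(idx, idx, "-")) / (K - 1))^2)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  ## single-category guard: with all observations in one agreeing cell,
  ## observed and chance agreement are both 1; perfect agreement is
  ## reported as kappa = 1 rather than 0/0
  if (po >= 1 - 1e-12) return(1)
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: chance agreement equals 1 (degenerate marginals)")
  (po - pe) / (1 - pe)
}

#' Pearson correlation and coefficient of determination
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `r2` (`= r^2` for a simple correlation).
#' @export
pearsonR2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2)
}

#' Welch confidence interval for a difference of means
#'
#' Welch's t interval (Welch–Satterthwaite degrees of freedom) on
#' `mean(x) - mean(y)`, via [stats::t.test()].
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param conf confidence level.
#' @return List with `estimate`, `lo`, `hi`, `df`.
#' @export
welchCI <- function(x, y, conf = 0.95) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  tt <- stats::t.test(x, y, conf.level = conf)
  list(estimate = unname(diff(rev(tt$estimate))),
       lo = tt$conf.int[1], hi = tt$conf.int[2],
       df = unname(tt$parameter))
}

#' Full agreement report for a method-comparison table
#'
#' Combines overall and per-category percent agreement, Wilson score
#' intervals for each, and Cohen's kappa (unweighted plus linear- and
#' quadratic-weighted). The unweighted kappa is the headline statistic.
#'
#' @param tab K x K matrix of counts (rows = candidate, cols = reference).
#' @param conf confidence level for the Wilson intervals.
#' @return A list of class `"AgreementReport"`.
#' @export
agreementReport <- function(tab, conf = 0.95) {
  tab <- checkContingency(tab)
  pa <- percentAgreement(tab)
  cs <- colSums(tab)
  perCI <- t(vapply(seq_along(cs), function(j) {
    if (cs[j] > 0) 100 * wilsonCI(tab[j, j], cs[j], conf)
    else c(lo = NA_real_, hi = NA_real_)
  }, numeric(2)))
  rownames(perCI) <- colnames(tab)
  overallCI <- 100 * wilsonCI(sum(diag(tab)), sum(tab), conf)
  structure(list(
    table = tab,
    overall = pa$overall, overallCI = overallCI,
    perCategory = pa$perCategory, perCategoryCI = perCI,
    kappa = cohenKappa(tab, "none"),
    kappaLinear = cohenKappa(tab, "linear"),
    kappaQuadratic = cohenKappa(tab, "quadratic"),
    n = sum(tab), conf = conf),
    class = "AgreementReport")
}

#' @export
print.AgreementReport <- function(x, ...) {
  cat(sprintf("AgreementReport (n = %d)\n", x$n))
  cat(sprintf("  overall agreement: %.1f%% (%.1f-%.1f%%)\n",
              x$overall, x$overallCI[1], x$overallCI[2]))
  for (j in seq_along(x$perCategory)) {
    nm <- names(x$perCategory)[j]
    if (is.null(nm) || is.na(nm)) nm <- sprintf("category %d", j)
    if (is.na(x$perCategory[j]))
      cat(sprintf("  %s: no reference samples\n", nm))
    else
      cat(sprintf("  %s: %.1f%% (%.1f-%.1f%%)\n", nm, x$perCategory[j],
                  x$perCategoryCI[j, 1], x$perCategoryCI[j, 2]))
  }
  cat(sprintf("  kappa: %.3f (linear %.3f, quadratic %.3f)\n",
              x$kappa, x$kappaLinear, x$kappaQuadratic))
  invisible(x)
}

#' Cross-classify candidate calls against reference concentrations
#'
#' Bins the reference concentrations with the same 20/30 ng/mL clinical
#' thresholds used by the candidate classifier and tabulates candidate
#' level against reference level as a 3x3 contingency table.
#'
#' @param candidateLevel integer candidate calls (1, 2 or 3).
#' @param referenceConc reference-method concentrations (ng/mL), or
#'   already-binned levels when `binned = TRUE`.
#' @param binned set `TRUE` when `referenceConc` already holds levels.
#' @return 3x3 integer matrix with dimnames
#'   `deficient`/`insufficient`/`sufficient`.
#' @export
contingencyFromCalls <- function(candidateLevel, referenceConc,
                                 binned = FALSE) {
  stopifnot(length(candidateLevel) == length(referenceConc))
  ref <- if (binned) as.integer(referenceConc) else classifyLevel(referenceConc)
  stopifnot(all(candidateLevel %in% 1:3), all(ref %in% 1:3))
  tab <- matrix(0L, 3, 3,
                dimnames = list(candidate = .LEVEL_LABELS,
                                reference = .LEVEL_LABELS))
  for (i in seq_along(ref))
    tab[candidateLevel[i], ref[i]] <- tab[candidateLevel[i], ref[i]] + 1L
  tab
}

#' Bundled method-comparison contingency tables
#'
#' 3x3 cross-classifications of the strip reader's clinical calls against
#' a laboratory immunoassay analyzer, shipped as plain CSV: a 100-sample
#' residual-serum comparison and a 22-sample paired capillary-vs-serum
#' comparison, each captured on two phone platforms (`"aos"` = Android,
#' `"ios"`).
#'
#' @param study `"serum"` or `"capillary"`.
#' @param platform `"aos"` (default) or `"ios"`.
#' @return 3x3 integer matrix (rows = strip reader, cols = reference).
#' @examples
#' percentAgreement(exampleComparisonTable("serum"))$overall
#' @export
exampleComparisonTable <- function(study = c("serum", "capillary"),
                                   platform = c("aos", "ios")) {
  study <- match.arg(study)
  platform <- match.arg(platform)
  path <- system.file("extdata",
                      sprintf("%s_comparison_%s.csv", study, platform),
                      package = "LFAreader", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  tab <- as.matrix(df)
  dimnames(tab) <- list(candidate = rownames(df), reference = rownames(df))
  checkContingency(tab)
}
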