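#' @include AllClasses.R
NULL

#' Postural drop in forced vital capacity
#'
#' Difference between upright and supine FVC (% predicted); a clinical
#' marker of diaphragmatic weakness.
#'
#' @param uprightPct,supinePct FVC as % of predicted.
#' @return upright minus supine, same units.
#' @export
deltaFVC <- function(uprightPct, supinePct) uprightPct - supinePct

#' Classify spirometry subgroup
#'
#' Patients are split into a normal-spirometry subgroup (supine FVC >= 80%
#' predicted and z-score >= -1.64) and a decreased-spirometry subgroup
#' (everything else). Vectorized.
#'
#' @param fvcSupinePct supine FVC, % predicted.
#' @param z corresponding z-score.
#' @return factor with levels `normal_spiro`, `decreased_spiro`.
#' @export
classifySubgroup <- function(fvcSupinePct, z) {
  normal <- fvcSupinePct >= 80 & z >= -1.64
  factor(ifelse(normal, "normal_spiro", "decreased_spiro"),
         levels = c("normal_spiro", "decreased_spiro"))
}

#' Bonferroni pairwise significance level
#'
#' The pairwise threshold for `k` comparisons at family level 0.05,
#' rounded to three decimals; for the three pairwise group contrasts this
#' is 0.017.
#'
#' @param k number of pairwise comparisons.
#' @return numeric threshold.
#' @export
bonferroniAlpha <- function(k = 3) round(0.05 / k, 3)

#' Intraclass correlation, two-way mixed, absolute agreement
#'
#' Single-measurement absolute-agreement ICC from the two-way mean
#' squares,
#' `(MSS - MSE) / (MSS + (k-1) MSE + (k/n)(MSR - MSE))`,
#' where MSS, MSR and MSE are the subject, rater and error mean squares of
#' the complete subjects x raters layout with one observation per cell.
#'
#' @param m numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, >= 2 subjects and >= 2 raters.
#' @return an [ICCResult-class]; a constant matrix yields `NaN` with
#'   `defined = FALSE`.
#' @export
iccAbsoluteAgreement <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  if (any(!is.finite(m))) stop("missing cells are not supported")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msS <- ssr / (n - 1)
  msR <- ssc / (k - 1)
  msE <- sse / ((n - 1) * (k - 1))
  denom <- msS + (k - 1) * msE + (k / n) * (msR - msE)
  icc <- if (denom == 0) NaN else (msS - msE) / denom
  new("ICCResult", icc = icc,
      modelTag = "two-way mixed, absolute agreement, single measurement",
      nSubjects = as.integer(n), nRaters = as.integer(k),
      msSubject = msS, msRater = msR, msError = msE,
      defined = is.finite(icc))
}

#' Bland-Altman agreement summary
#'
#' Mean difference (bias) and 1.96-sd limits of agreement between two
#' paired measurement series.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `bias`, `loaLow`, `loaHigh`, `sdDiff`.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("measurement series differ in length")
  if (length(a) < 2) stop("need at least 2 paired measurements")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       sdDiff = s)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Constant input has no
#' rank ordering; the result is `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or `NA` if undefined.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("inputs differ in length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Covariate-adjusted group comparison of one outcome
#'
#' Ordinary least squares of the outcome on group indicators plus
#' covariates. The overall group effect is the joint F test comparing the
#' model against the covariate-only model; pairwise group contrasts are
#' tested from the coefficient covariance and judged at the Bonferroni
#' pairwise level for the number of pairs (0.017 for three groups).
#' Residual summaries (sd, Shapiro-Wilk p for up to 5000 residuals, max
#' absolute standardized residual) support the linearity/normality check.
#'
#' @param data data.frame holding the columns named below.
#' @param outcome name of the numeric outcome column.
#' @param group name of the group column (coerced to factor).
#' @param covariates character vector of covariate column names (default
#'   none; a typical adjustment is age).
#' @return a [GroupComparisonResult-class].
#' @export
adjustedGroupComparison <- function(data, outcome, group = "group",
                                    covariates = character()) {
  need <- c(outcome, group, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  df[[group]] <- factor(df[[group]])
  lv <- levels(df[[group]])
  if (length(lv) < 2) stop("need at least 2 groups")
  if (any(table(df[[group]]) < 2)) stop("each group needs n >= 2")
  covTerm <- if (length(covariates)) paste(covariates, collapse = " + ") else NULL
  fullF <- stats::reformulate(c(group, covariates), response = outcome)
  redF <- stats::reformulate(if (is.null(covTerm)) "1" else covariates,
                             response = outcome)
  full <- stats::lm(fullF, data = df)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("singular design; collinear terms: ", paste(bad, collapse = ", "))
  }
  red <- stats::lm(redF, data = df)
  overallP <- stats::anova(red, full)[2, "Pr(>F)"]
  V <- stats::vcov(full)
  beta <- stats::coef(full)
  cn <- names(beta)
  gcoef <- function(l) {
    v <- numeric(length(beta))
    if (l != lv[1]) v[match(paste0(group, l), cn)] <- 1
    v
  }
  pairs <- utils::combn(lv, 2)
  alpha <- bonferroniAlpha(ncol(pairs))
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cv <- gcoef(b) - gcoef(a)
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    t <- est / se
    p <- 2 * stats::pt(-abs(t), df = full$df.residual)
    data.frame(group_a = a, group_b = b, estimate = est, se = se, p = p,
               significant = p <= alpha)
  }))
  res <- stats::residuals(full)
  std <- res / stats::sd(res)
  shp <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  new("GroupComparisonResult", outcomeName = outcome, overallP = overallP,
      pairwise = pw, alphaPairwise = alpha,
      covariates = as.character(covariates),
      diagnostics = list(residual_sd = stats::sd(res),
                         max_abs_std_residual = max(abs(std)),
                         shapiro_p = shp, n = nrow(df)))
}

.mriOutcomeCols <- c("cc_ratio", "ap_ratio", "area_ratio", "cc_ap_ratio",
                     "da_ratio", "dh_ratio", "ant_displacement_mm",
                     "post_displacement_mm")
.pftCols <- c("fvc_upright_pct", "fvc_supine_pct", "delta_fvc_pct",
              "mip_pct", "mep_pct")

#' Correlation table of MRI outcomes against pulmonary function
#'
#' Spearman correlations between the eight MRI outcomes and the five
#' pulmonary-function values, starred at p < 0.05 / < 0.01 / < 0.001.
#' Rows are matched by `subject_id`; unmatched ids are an error.
#'
#' @param outcomes data.frame with `subject_id` and the outcome columns
#'   (`cc_ratio`, `ap_ratio`, `area_ratio`, `cc_ap_ratio`, `da_ratio`,
#'   `dh_ratio`, `ant_displacement_mm`, `post_displacement_mm`).
#' @param pfts data.frame with `subject_id` and `fvc_upright_pct`,
#'   `fvc_supine_pct`, `delta_fvc_pct`, `mip_pct`, `mep_pct`.
#' @return list with matrices `estimate`, `p`, and character matrices
#'   `stars` and `formatted` (coefficient with stars).
#' @export
correlationTable <- function(outcomes, pfts) {
  un <- c(setdiff(outcomes$subject_id, pfts$subject_id),
          setdiff(pfts$subject_id, outcomes$subject_id))
  if (length(un))
    stop("unmatched subject ids: ", paste(unique(un), collapse = ", "))
  m <- merge(outcomes, pfts, by = "subject_id")
  ocols <- intersect(.mriOutcomeCols, names(m))
  est <- p <- matrix(NA_real_, length(ocols), length(.pftCols),
                     dimnames = list(ocols, .pftCols))
  for (i in ocols) for (j in .pftCols) {
    ok <- stats::complete.cases(m[[i]], m[[j]])
    if (stats::sd(m[[i]][ok]) == 0 || stats::sd(m[[j]][ok]) == 0) {
      warning("constant column: correlation with ", j, " undefined")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(m[[i]][ok], m[[j]][ok], method = "spearman",
                      exact = FALSE))
    est[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
            ifelse(p < 0.05, "*", "")))
  formatted <- matrix(paste0(sprintf("%.3f", est), stars), nrow(est),
                      dimnames = dimnames(est))
  list(estimate = est, p = p, stars = stars, formatted = formatted)
}
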